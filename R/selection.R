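#' Trim partial codons and translate an exon-2 allele set
#'
#' Class II exon 2 starts and ends mid-codon (a codon begins on exon 1 and
#' ends on exon 2), so the first two and the last one nucleotide are
#' removed before translation: a 249 nt DQA exon yields 246 nt / 82 aa, a
#' 270 nt DQB exon 267 nt / 89 aa.
#'
#' @param alleles named character vector of equal-length exon sequences.
#' @param trim_5p,trim_3p nucleotides removed at each end (defaults 2 and 1).
#' @return a \code{coding_alignment}: in-frame nucleotide alleles, peptides,
#'   variable nucleotide and amino-acid columns.
#' @export
exon_to_peptides <- function(alleles, trim_5p = 2, trim_3p = 1) {
  if (length(unique(nchar(alleles))) != 1) stop("alleles must have equal length")
  L <- nchar(alleles[[1]])
  trimmed <- substr(alleles, trim_5p + 1L, L - trim_3p)
  if (nchar(trimmed[[1]]) %% 3 != 0) {
    stop("post-trim length ", nchar(trimmed[[1]]), " not divisible by 3")
  }
  peptides <- vapply(trimmed, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, "")
  names(trimmed) <- names(alleles)
  names(peptides) <- names(alleles)
  nt_mat <- seq_matrix(trimmed)
  aa_mat <- seq_matrix(peptides)
  var_nt <- which(apply(nt_mat, 2, function(x) length(unique(x)) > 1))
  var_aa <- which(apply(aa_mat, 2, function(x) length(unique(x)) > 1))
  structure(list(alleles = trimmed, peptides = peptides,
                 variable_nt = var_nt, variable_aa = var_aa,
                 has_stop = grepl("\\*", peptides)),
            class = "coding_alignment")
}

# trim + translate a single haplotype (stop-codon screening in the catalogue)
translate_trimmed <- function(seq, trim_5p = 2, trim_3p = 1) {
  s <- substr(seq, trim_5p + 1L, nchar(seq) - trim_3p)
  s <- substr(s, 1, 3 * (nchar(s) %/% 3))
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

#' Load a binding-pocket residue mask
#'
#' Pocket residues ship as editable configuration (TSV: locus, pocket,
#' aa_pos) because published reports give pocket sizes and labels rather
#' than coordinates; the packaged defaults follow human-homology DQ pocket
#' assignments and are validated against the expected totals (DQA: 15
#' residues over pockets P1/P6/P9; DQB: 19 over P1/P4/P6/P7/P9).
#'
#' @param locus "DQA" or "DQB" (any locus present in the file).
#' @param path optional TSV path; default: packaged mask.
#' @return a \code{pocket_mask}: locus, positions (1-based aa), pockets.
#' @export
load_pocket_mask <- function(locus, path = NULL) {
  default <- is.null(path)
  if (default) path <- system.file("extdata", "pocket_masks.tsv", package = "mhctyper")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$locus == locus, , drop = FALSE]
  if (!nrow(tab)) stop("no pocket mask for locus ", locus)
  if (any(duplicated(tab$aa_pos))) stop("pocket mask has duplicate positions")
  if (default) {
    expected <- c(DQA = 15L, DQB = 19L)
    if (locus %in% names(expected) && nrow(tab) != expected[[locus]]) {
      stop("packaged ", locus, " mask must have ", expected[[locus]], " residues")
    }
  }
  structure(list(locus = locus, positions = sort(tab$aa_pos),
                 pockets = tab$pocket[order(tab$aa_pos)]),
            class = "pocket_mask")
}

#' Test enrichment of amino-acid variation inside binding pockets
#'
#' Two-cell goodness-of-fit of the variable-residue counts (in-pocket vs
#' out-of-pocket) against expectations proportional to the class sizes:
#' G = 2 sum O_i ln(O_i / E_i) (zero cells contribute 0), with the
#' chi-square analogue reported alongside. Uncorrected by default; the
#' Williams small-sample correction is available as a flag.
#'
#' @param variable_sites 1-based aa positions that vary, or an integer
#'   count of variable sites (then \code{n_in_pocket} is required).
#' @param mask a [load_pocket_mask()] (or integer vector of positions).
#' @param total_aa number of residues in the peptide.
#' @param n_in_pocket count of variable sites inside the mask (only when
#'   \code{variable_sites} is a plain count).
#' @param williams apply the Williams correction to G.
#' @return an \code{enrichment_result}: G, chisq, df, p_g, p_chisq,
#'   observed and expected counts.
#' @export
pocket_enrichment_test <- function(variable_sites, mask, total_aa,
                                   n_in_pocket = NULL, williams = FALSE) {
  positions <- if (inherits(mask, "pocket_mask")) mask$positions else mask
  if (any(positions < 1 | positions > total_aa)) {
    stop("mask positions outside [1, total_aa]")
  }
  if (length(variable_sites) == 1 && !is.null(n_in_pocket)) {
    n_var <- variable_sites
    n_in <- n_in_pocket
  } else {
    n_var <- length(variable_sites)
    n_in <- sum(variable_sites %in% positions)
  }
  m <- length(positions)
  O <- c(pocket = n_in, outside = n_var - n_in)
  E <- n_var * c(m, total_aa - m) / total_aa
  if (n_var == 0) {
    return(structure(list(G = 0, chisq = 0, df = 1L, p_g = 1, p_chisq = 1,
                          observed = O, expected = E), class = "enrichment_result"))
  }
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  if (williams) G <- G / (1 + (length(O) + 1) / (6 * n_var))
  chisq <- sum((O - E)^2 / E)
  structure(list(G = G, chisq = chisq, df = 1L,
                 p_g = stats::pchisq(G, 1, lower.tail = FALSE),
                 p_chisq = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 observed = O, expected = E), class = "enrichment_result")
}

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

# per-pair transition/transversion proportions over non-gap columns
.pq_counts <- function(s1, s2) {
  b1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  ok <- b1 %in% DNA_BASES & b2 %in% DNA_BASES
  b1 <- b1[ok]; b2 <- b2[ok]
  diff <- b1 != b2
  ts <- sum(diff & .TRANSITIONS[b1] == b2)
  c(ts = ts, tv = sum(diff) - ts, n = length(b1))
}

#' Transition/transversion rate-ratio estimate R
#'
#' K2P-style estimate per sequence pair (ratio of corrected transition to
#' transversion distances), averaged over pairs; the random expectation is
#' R = 0.5 (one transition vs two transversion types per site). When
#' divergence is too small for the K2P correction (or \code{mode =
#' "count"}), the raw count ratio transitions/transversions is used.
#'
#' @param seqs character vector of aligned equal-length sequences (>= 2).
#' @param mode "auto" (K2P when mean pairwise differences >= 10, else
#'   counting), "k2p", or "count".
#' @return list: R (NA with \code{undefined = TRUE} when no transversions
#'   or no differences), mode used, ts/tv totals.
#' @export
titv_ratio <- function(seqs, mode = c("auto", "k2p", "count")) {
  mode <- match.arg(mode)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  pairs <- utils::combn(length(seqs), 2)
  pq <- apply(pairs, 2, function(ij) .pq_counts(seqs[ij[1]], seqs[ij[2]]))
  ts_tot <- sum(pq["ts", ]); tv_tot <- sum(pq["tv", ])
  if (ts_tot + tv_tot == 0) {
    return(list(R = NA_real_, undefined = TRUE, mode = mode,
                ts = 0L, tv = 0L))
  }
  mean_diff <- mean(pq["ts", ] + pq["tv", ])
  use_k2p <- mode == "k2p" || (mode == "auto" && mean_diff >= 10)
  if (use_k2p) {
    Rs <- apply(pq, 2, function(x) {
      P <- x["ts"] / x["n"]; Q <- x["tv"] / x["n"]
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0 || Q == 0) return(NA_real_)
      s <- -0.5 * log(w1) + 0.25 * log(w2)
      v <- -0.5 * log(w2)
      if (v <= 0) NA_real_ else s / v
    })
    Rs <- Rs[is.finite(Rs)]
    if (length(Rs)) {
      return(list(R = mean(Rs), undefined = FALSE, mode = "k2p",
                  ts = ts_tot, tv = tv_tot))
    }
    # fall through to counting when K2P is unusable
  }
  if (tv_tot == 0) {
    return(list(R = Inf, undefined = TRUE, mode = "count",
                ts = ts_tot, tv = tv_tot))
  }
  list(R = ts_tot / tv_tot, undefined = FALSE, mode = "count",
       ts = ts_tot, tv = tv_tot)
}

.GC <- Biostrings::GENETIC_CODE

.codon_split <- function(seq) {
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# weights for the 3 possible changes at one codon position:
# transition gets 2R, each transversion 1 (pooled ts:tv rate ratio R)
.site_fractions <- function(codon, R = 0.5) {
  aa <- .GC[[codon]]
  s <- 0; tot <- 0
  bases <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- numeric(3)
  for (i in 1:3) {
    si <- 0; ti <- 0
    for (b in setdiff(DNA_BASES, bases[i])) {
      w <- if (.TRANSITIONS[bases[i]] == b) 2 * R else 1
      alt <- bases; alt[i] <- b
      alt_c <- paste(alt, collapse = "")
      aa2 <- .GC[[alt_c]]
      # mutations to stop codons count as nonsynonymous
      if (aa2 == aa && aa2 != "*") si <- si + w
      ti <- ti + w
    }
    out[i] <- si / ti
  }
  out
}

# pathway-averaged synonymous/nonsynonymous difference counts for a codon
# pair; paths through stop codons are excluded unless all are blocked
.codon_path_counts <- function(c1, c2) {
  b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(b1 != b2)
  nd <- length(dpos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(dpos) else {
    if (nd == 2) list(dpos, rev(dpos)) else {
      idx <- expand.grid(1:3, 1:3, 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3), ]
      lapply(seq_len(nrow(idx)), function(r) dpos[unlist(idx[r, ])])
    }
  }
  eval_path <- function(ord) {
    cur <- b1; sd <- 0; nds <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b2[p]
      aa1 <- .GC[[paste(cur, collapse = "")]]
      aa2 <- .GC[[paste(nxt, collapse = "")]]
      if (aa2 == "*") blocked <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nds <- nds + 1
      cur <- nxt
    }
    c(sd = sd, nd = nds, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, eval_path, c(sd = 0, nd = 0, blocked = 0))
  open <- res["blocked", ] == 0
  if (any(open)) res <- res[, open, drop = FALSE]
  c(sd = mean(res["sd", ]), nd = mean(res["nd", ]))
}

#' Pairwise dN/dS by the Nei-Gojobori method
#'
#' NG86 counting with equal-path averaging and Jukes-Cantor correction;
#' \code{method = "tstv"} weights the site counting by the estimated
#' transition/transversion ratio R (transitions weighted 2R against 1 per
#' transversion), which discounts synonymous opportunity when transitions
#' are favoured. The summary ratio w is mean dN over mean dS across all
#' sequence pairs.
#'
#' @param coding a \code{coding_alignment} (or named character vector of
#'   in-frame sequences).
#' @param method "NG86" or "tstv".
#' @param R transition/transversion ratio used by \code{method = "tstv"};
#'   NULL estimates it from the alignment via [titv_ratio()].
#' @return a \code{selection_result}: mean_dn, mean_ds, w (NA with
#'   \code{w_undefined} when mean dS = 0), per-pair table, method, R.
#' @export
pairwise_dnds <- function(coding, method = c("NG86", "tstv"), R = NULL) {
  method <- match.arg(method)
  seqs <- if (inherits(coding, "coding_alignment")) coding$alleles else coding
  if (length(seqs) < 2) stop("need at least 2 alleles")
  if (any(nchar(seqs) %% 3 != 0)) stop("sequences must be in frame")
  Rw <- if (method == "NG86") 0.5 else {
    if (is.null(R)) {
      tt <- titv_ratio(unname(seqs), mode = "auto")
      if (is.na(tt$R) || !is.finite(tt$R)) 0.5 else tt$R
    } else R
  }
  codons <- lapply(seqs, .codon_split)
  site_S <- lapply(codons, function(cs) {
    vapply(cs, function(c) sum(.site_fractions(c, Rw)), 0)
  })
  pairs <- utils::combn(length(seqs), 2)
  per_pair <- apply(pairs, 2, function(ij) {
    c1 <- codons[[ij[1]]]; c2 <- codons[[ij[2]]]
    S <- mean(c(sum(site_S[[ij[1]]]), sum(site_S[[ij[2]]])))
    N <- 3 * length(c1) - S
    d <- vapply(seq_along(c1), function(k) {
      .codon_path_counts(c1[k], c2[k])
    }, c(sd = 0, nd = 0))
    Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
    jc <- function(p) {
      if (p >= 0.75) return(NA_real_)
      -0.75 * log(1 - 4 * p / 3)
    }
    c(S = S, N = N, Sd = Sd, Nd = Nd,
      dS = if (S > 0) jc(Sd / S) else NA, dN = if (N > 0) jc(Nd / N) else NA)
  })
  per_pair <- as.data.frame(t(per_pair))
  per_pair$i <- pairs[1, ]; per_pair$j <- pairs[2, ]
  mean_dn <- mean(per_pair$dN, na.rm = TRUE)
  mean_ds <- mean(per_pair$dS, na.rm = TRUE)
  undef <- !is.finite(mean_ds) || mean_ds == 0
  structure(list(mean_dn = mean_dn, mean_ds = mean_ds,
                 w = if (undef) NA_real_ else mean_dn / mean_ds,
                 w_undefined = undef, pairs = per_pair,
                 method = method, R = Rw), class = "selection_result")
}

#' Approximate per-codon selection scan
#'
#' A counting-based alternative to codon-model site tests: per codon
#' column, synonymous and nonsynonymous changes are tallied against the
#' majority (star-tree ancestral) codon with pathway averaging, and a
#' one-sided binomial test asks whether nonsynonymous changes exceed the
#' neutral expectation set by the ancestral codon's site composition.
#' Columns are labelled w<1 / w~1 / w>1 by the direction of the deviation;
#' this is an approximation to likelihood site models, not a posterior.
#'
#' @param coding a \code{coding_alignment}.
#' @param alpha significance level for the positive-selection flag.
#' @return data.frame: codon, n_syn, n_nonsyn, expected_nonsyn_frac,
#'   class ("no_signal" | "w<1" | "w~1" | "w>1"), p_value (one-sided
#'   excess-nonsynonymous), significant.
#' @export
site_dnds_scan <- function(coding, alpha = 0.05) {
  seqs <- if (inherits(coding, "coding_alignment")) coding$alleles else coding
  codons <- lapply(seqs, .codon_split)
  ncod <- length(codons[[1]])
  out <- lapply(seq_len(ncod), function(k) {
    col <- vapply(codons, `[`, "", k)
    anc <- names(sort(table(col), decreasing = TRUE))[1]
    sd <- 0; nd <- 0
    for (c2 in col[col != anc]) {
      d <- .codon_path_counts(anc, c2)
      sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
    }
    n <- round(sd + nd)
    # neutral nonsynonymous fraction of the inferred ancestral codon
    p0 <- (3 - sum(.site_fractions(anc, 0.5))) / 3
    if (n == 0) {
      return(data.frame(codon = k, n_syn = 0, n_nonsyn = 0,
                        expected_nonsyn_frac = p0, class = "no_signal",
                        p_value = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    x <- round(nd)
    p <- stats::binom.test(x, n, p0, alternative = "greater")$p.value
    obs_frac <- nd / (sd + nd)
    class <- if (abs(obs_frac - p0) < 1e-9) "w~1" else
      if (obs_frac > p0) "w>1" else "w<1"
    data.frame(codon = k, n_syn = sd, n_nonsyn = nd,
               expected_nonsyn_frac = p0, class = class, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
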