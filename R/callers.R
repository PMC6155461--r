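#' Tunable parameters for the dual-caller pipeline
#'
#' The ratio caller mirrors allele-ratio-sensitive callers: a site is
#' heterozygous only when the minor base sits near 50% of reads, homozygous
#' only when the minor base is near 0%, and anything in between is flagged
#' as ratio distortion (the signature PCR chimeras leave). The likelihood
#' caller maximises a standard diploid per-read likelihood and is the more
#' sensitive route. Both emit Phred-scaled confidences gated at
#' \code{min_qual}.
#'
#' @param min_minor_frac minimum minor-base fraction (of the top two bases)
#'   for a heterozygous call; the het band is [min_minor_frac, 0.5].
#' @param max_minor_frac_hom maximum minor-base fraction for a homozygous
#'   call.
#' @param min_qual Phred-scaled confidence cutoff (default 40).
#' @param min_identity alignment identity below which reads are discarded.
#' @param hp_min_len homopolymer-context run length.
#' @param dominant_frac fraction of sample reads a haplotype cluster needs
#'   to count as dominant (chimera testing; default 0.05).
#' @param strand_min_opp minimum opposing-strand coverage before a
#'   one-strand variant is treated as strand-biased misalignment.
#' @param ambiguity_frac competing-phasing support ratio that triggers a
#'   phase_ambiguous error (default 0.1 = within 10%).
#' @return a named list of parameters.
#' @export
caller_params <- function(min_minor_frac = 0.35, max_minor_frac_hom = 0.05,
                          min_qual = 40, min_identity = 0.8, hp_min_len = 4,
                          dominant_frac = 0.05, strand_min_opp = 10,
                          ambiguity_frac = 0.1) {
  stopifnot(min_minor_frac > max_minor_frac_hom, min_minor_frac <= 0.5)
  list(min_minor_frac = min_minor_frac,
       max_minor_frac_hom = max_minor_frac_hom,
       min_qual = min_qual, min_identity = min_identity,
       hp_min_len = hp_min_len, dominant_frac = dominant_frac,
       strand_min_opp = strand_min_opp, ambiguity_frac = ambiguity_frac)
}

# effective per-column counts after an optional strand mask
# mask: NULL or 2 x L logical matrix (rows fwd, rev); FALSE = strand excluded
.effective_counts <- function(pileup, mask = NULL) {
  if (is.null(mask)) return(pileup$counts_fwd + pileup$counts_rev)
  cf <- pileup$counts_fwd
  cr <- pileup$counts_rev
  cf[, !mask[1, ]] <- 0L
  cr[, !mask[2, ]] <- 0L
  cf + cr
}

.empty_calls <- function() {
  data.frame(pos = integer(0), ref = character(0), a1 = character(0),
             a2 = character(0), caller = character(0), qual = numeric(0),
             flag = character(0), stringsAsFactors = FALSE)
}

#' Allele-ratio variant caller
#'
#' Calls genotypes from base-count ratios: heterozygote when the minor
#' fraction of the top two bases lies in [min_minor_frac, 0.5], homozygote
#' when it is at most max_minor_frac_hom, and a flagged no-call otherwise.
#' Calls are biallelic per site per sample and depth-0 sites are skipped.
#'
#' @param pileup a \code{site_pileup}.
#' @param params [caller_params()].
#' @param strand_mask optional 2 x L logical matrix excluding a strand at
#'   chosen columns.
#' @return data.frame pos (0-based), ref, a1, a2, caller = "ratio", qual,
#'   flag ("" | "ratio_distortion" | "low_confidence"); no-calls have NA
#'   genotypes.
#' @export
call_ratio <- function(pileup, params = caller_params(), strand_mask = NULL) {
  cnt <- .effective_counts(pileup, strand_mask)
  L <- ncol(cnt)
  ref_bases <- strsplit(pileup$reference, "", fixed = TRUE)[[1]]
  depth <- colSums(cnt)
  out <- list()
  for (p in which(depth > 0)) {
    o <- order(cnt[, p], decreasing = TRUE)
    n1 <- cnt[o[1], p]; n2 <- cnt[o[2], p]
    b1 <- DNA_BASES[o[1]]; b2 <- DNA_BASES[o[2]]
    f <- if (n1 + n2 > 0) n2 / (n1 + n2) else 0
    e <- max(pileup$err[p], 1e-6)
    if (f >= params$min_minor_frac) {
      qual <- abs((n1 + n2) * log(0.5) - (n1 * log(1 - e) + n2 * log(e / 3))) *
        10 / log(10)
      if (qual < params$min_qual) {
        out[[length(out) + 1]] <- data.frame(
          pos = p - 1L, ref = ref_bases[p], a1 = NA_character_,
          a2 = NA_character_, caller = "ratio", qual = qual,
          flag = "low_confidence", stringsAsFactors = FALSE)
      } else {
        g <- sort(c(b1, b2))
        out[[length(out) + 1]] <- data.frame(
          pos = p - 1L, ref = ref_bases[p], a1 = g[1], a2 = g[2],
          caller = "ratio", qual = qual, flag = "", stringsAsFactors = FALSE)
      }
    } else if (f <= params$max_minor_frac_hom) {
      if (b1 != ref_bases[p]) {
        qual <- abs((n1 + n2) * log(0.5) - (n1 * log(1 - e) + n2 * log(e / 3))) *
          10 / log(10)
        out[[length(out) + 1]] <- data.frame(
          pos = p - 1L, ref = ref_bases[p], a1 = b1, a2 = b1,
          caller = "ratio", qual = qual, flag = "", stringsAsFactors = FALSE)
      }
    } else {
      out[[length(out) + 1]] <- data.frame(
        pos = p - 1L, ref = ref_bases[p], a1 = NA_character_,
        a2 = NA_character_, caller = "ratio", qual = 0,
        flag = "ratio_distortion", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_calls())
  do.call(rbind, out)
}

# the ten unordered diploid genotypes over ACGT
.GENOTYPES <- {
  g <- expand.grid(a = DNA_BASES, b = DNA_BASES, stringsAsFactors = FALSE)
  g <- g[g$a <= g$b, ]
  rownames(g) <- paste0(g$a, g$b)
  g
}

#' Genotype-likelihood variant caller
#'
#' Maximises a standard diploid likelihood per site: each read base is
#' generated from one of the two genotype alleles with error probability
#' taken from the base qualities, with a uniform prior over the ten
#' unordered base pairs. Genotypes where both bases differ from the
#' reference are supported. Confidence is the Phred-scaled ratio of the
#' best to second-best genotype; calls below \code{min_qual} are
#' suppressed (flagged no-call).
#'
#' @inheritParams call_ratio
#' @return data.frame like [call_ratio()] with caller = "likelihood".
#' @export
call_likelihood <- function(pileup, params = caller_params(),
                            strand_mask = NULL) {
  cnt <- .effective_counts(pileup, strand_mask)
  ref_bases <- strsplit(pileup$reference, "", fixed = TRUE)[[1]]
  depth <- colSums(cnt)
  out <- list()
  for (p in which(depth > 0)) {
    n <- cnt[, p]
    e <- min(max(pileup$err[p], 1e-6), 0.5)
    # P(base b | allele a): (1-e) if b==a else e/3
    pm <- matrix(e / 3, 4, 4)
    diag(pm) <- 1 - e
    ll <- vapply(seq_len(nrow(.GENOTYPES)), function(k) {
      pa <- pm[, match(.GENOTYPES$a[k], DNA_BASES)]
      pb <- pm[, match(.GENOTYPES$b[k], DNA_BASES)]
      sum(n * log((pa + pb) / 2))
    }, 0)
    o <- order(ll, decreasing = TRUE)
    best <- .GENOTYPES[o[1], ]
    qual <- (ll[o[1]] - ll[o[2]]) * 10 / log(10)
    hom_ref <- best$a == ref_bases[p] && best$b == ref_bases[p]
    if (hom_ref) next
    if (qual < params$min_qual) {
      out[[length(out) + 1]] <- data.frame(
        pos = p - 1L, ref = ref_bases[p], a1 = NA_character_,
        a2 = NA_character_, caller = "likelihood", qual = qual,
        flag = "low_confidence", stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <- data.frame(
        pos = p - 1L, ref = ref_bases[p], a1 = best$a, a2 = best$b,
        caller = "likelihood", qual = qual, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_calls())
  do.call(rbind, out)
}
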