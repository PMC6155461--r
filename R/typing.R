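#' Collapse phased haplotypes into a named allele catalogue
#'
#' Identical haplotypes across samples are merged into allele records named
#' \code{<prefix>*NN} in descending frequency order (NN zero-padded). For
#' coding loci the haplotypes are translated (after partial-codon trimming,
#' see [exon_to_peptides()]) and any stop-codon-bearing haplotype is
#' excluded and flagged: it cannot encode a functional molecule. An allele
#' is \code{confirmed} when seen in at least two individuals or
#' independently confirmed by another method, otherwise \code{provisional}.
#'
#' @param phased_pairs named list (by sample id) of \code{phased_pair}
#'   objects (or two-element character vectors of haplotypes).
#' @param prefix allele-name prefix, e.g. "Tutr-DQA1" (Klein-style
#'   formatting convention).
#' @param coding if TRUE, screen translated haplotypes for stop codons.
#' @param cross_confirmed character vector of sequences confirmed by an
#'   independent method (e.g. Sanger-typed alleles).
#' @return an \code{allele_catalogue} data.frame: name, seq, support
#'   (individuals), status; excluded stop-codon haplotypes are kept in
#'   attribute "excluded".
#' @export
build_catalogue <- function(phased_pairs, prefix = "Allele",
                            coding = FALSE, cross_confirmed = character(0)) {
  if (!length(phased_pairs)) stop("no phased pairs supplied")
  haps <- lapply(phased_pairs, function(p) {
    if (inherits(p, "phased_pair")) p$haplotypes else p
  })
  haps <- haps[!vapply(haps, is.null, TRUE)]
  if (!length(haps)) stop("no phased haplotypes available")
  if (length(unique(nchar(unlist(haps)))) > 1) {
    stop("haplotypes must have equal length per locus")
  }
  # support = number of distinct individuals carrying the haplotype
  seq_support <- table(unlist(lapply(haps, unique)))
  seqs <- names(seq_support)

  excluded <- character(0)
  if (coding) {
    stops <- vapply(seqs, function(s) {
      aa <- translate_trimmed(s)
      grepl("\\*", aa)
    }, TRUE)
    excluded <- seqs[stops]
    seqs <- seqs[!stops]
  }
  if (!length(seqs)) stop("all haplotypes carried stop codons")
  support <- as.integer(seq_support[seqs])
  ord <- order(-support, seqs)
  seqs <- seqs[ord]; support <- support[ord]
  status <- ifelse(support >= 2 | seqs %in% cross_confirmed,
                   "confirmed", "provisional")
  cat <- data.frame(
    name = sprintf("%s*%02d", prefix, seq_along(seqs)),
    seq = seqs, support = support, status = status,
    stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  attr(cat, "excluded") <- excluded
  class(cat) <- c("allele_catalogue", "data.frame")
  cat
}

#' Genotype samples against an allele catalogue
#'
#' @param catalogue an [build_catalogue()] result.
#' @param phased_pairs named list of phased pairs (by sample id).
#' @param strata optional named character vector sample -> stratum.
#' @param locus locus label for the output table.
#' @return genotype data.frame: sample_id, stratum, locus, allele1, allele2
#'   (allele1 <= allele2 by name). Samples with haplotypes absent from the
#'   catalogue raise an error.
#' @export
genotype_samples <- function(catalogue, phased_pairs, strata = NULL,
                             locus = NA_character_) {
  lookup <- stats::setNames(catalogue$name, catalogue$seq)
  rows <- lapply(names(phased_pairs), function(sid) {
    p <- phased_pairs[[sid]]
    h <- if (inherits(p, "phased_pair")) p$haplotypes else p
    if (is.null(h)) return(NULL)
    nm <- lookup[h]
    if (any(is.na(nm))) {
      stop("sample '", sid, "' carries a haplotype absent from the catalogue")
    }
    nm <- sort(unname(nm))
    data.frame(sample_id = sid,
               stratum = if (!is.null(strata)) strata[[sid]] else NA_character_,
               locus = locus, allele1 = nm[1], allele2 = nm[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# position-wise IUPAC union of two equal-length sequences
.iupac_union <- function(s1, s2) {
  b1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  paste(iupac_pair(b1, b2), collapse = "")
}

# is known base compatible with the consensus code at every position?
.compatible <- function(known, consensus_bases) {
  kb <- strsplit(known, "", fixed = TRUE)[[1]]
  all(vapply(seq_along(kb), function(i) {
    kb[i] %in% iupac_expand(consensus_bases[i])
  }, TRUE))
}

#' Resolve a Sanger IUPAC consensus into an allele pair
#'
#' Enumerates unordered pairs of known alleles whose position-wise IUPAC
#' union reproduces the consensus exactly. If exactly one pair matches it
#' is returned; among several matches the pair with the highest summed
#' catalogue support wins (frequency-weighted preference; ties are
#' ambiguous). If no pair of known alleles works, each known allele
#' compatible with the consensus forces a unique complementary sequence
#' (the other base of each two-base code); when all compatible knowns force
#' the same complement, the genotype is (known, novel). Solutions never
#' introduce two novel alleles: parsimony stops at one.
#'
#' @param consensus consensus sequence over ACGT + two-base IUPAC codes.
#' @param known_alleles named character vector (names = allele ids) of
#'   known allele sequences, same length as the consensus.
#' @param support optional numeric vector of catalogue support per known
#'   allele (for frequency-weighted tie-breaking).
#' @return list: allele1, allele2 (ids; novel alleles get id
#'   "novel:<sequence>"), novel (0 or 1), sequences (character(2)).
#'   Errors: "unresolvable, cloning required" when no known allele is
#'   compatible; "ambiguous" when multiple distinct solutions tie.
#' @export
resolve_sanger_genotype <- function(consensus, known_alleles, support = NULL) {
  if (!length(known_alleles)) stop("unresolvable, cloning required")
  if (any(nchar(known_alleles) != nchar(consensus))) {
    stop("consensus length must equal allele length")
  }
  cb <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (any(!cb %in% c(DNA_BASES, unname(IUPAC2)))) {
    stop("consensus restricted to ACGT plus two-base ambiguity codes")
  }
  ids <- names(known_alleles)
  if (is.null(ids)) ids <- paste0("A", seq_along(known_alleles))
  if (is.null(support)) support <- rep(1, length(known_alleles))

  # zero-novel solutions: exhaustive pair enumeration (with replacement)
  hits <- list()
  for (i in seq_along(known_alleles)) {
    for (j in i:length(known_alleles)) {
      if (.iupac_union(known_alleles[[i]], known_alleles[[j]]) == consensus) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (length(hits) == 1) {
    ij <- hits[[1]]
    return(list(allele1 = ids[ij[1]], allele2 = ids[ij[2]], novel = 0L,
                sequences = unname(known_alleles[ij])))
  }
  if (length(hits) > 1) {
    w <- vapply(hits, function(ij) support[ij[1]] + support[ij[2]], 0)
    best <- which(w == max(w))
    if (length(best) > 1) stop("ambiguous")
    ij <- hits[[best]]
    message("multiple zero-novel solutions; picked the frequency-weighted pair")
    return(list(allele1 = ids[ij[1]], allele2 = ids[ij[2]], novel = 0L,
                sequences = unname(known_alleles[ij])))
  }

  # one-novel solutions: a compatible known forces a unique complement
  sols <- list()
  for (i in seq_along(known_alleles)) {
    if (!.compatible(known_alleles[[i]], cb)) next
    kb <- strsplit(known_alleles[[i]], "", fixed = TRUE)[[1]]
    comp <- vapply(seq_along(cb), function(p) {
      exp <- iupac_expand(cb[p])
      if (length(exp) == 1) exp else setdiff(exp, kb[p])
    }, "")
    sols[[length(sols) + 1]] <- list(known = i, novel_seq = paste(comp, collapse = ""))
  }
  if (!length(sols)) stop("unresolvable, cloning required")
  novel_seqs <- unique(vapply(sols, `[[`, "", "novel_seq"))
  keys <- unique(vapply(sols, function(s)
    paste(sort(c(known_alleles[[s$known]], s$novel_seq)), collapse = "|"), ""))
  if (length(keys) > 1) stop("ambiguous")
  s <- sols[[1]]
  list(allele1 = ids[s$known], allele2 = paste0("novel:", s$novel_seq),
       novel = 1L,
       sequences = c(unname(known_alleles[[s$known]]), s$novel_seq))
}
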