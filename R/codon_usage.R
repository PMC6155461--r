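# synonymous families of the standard code (stop codons excluded)
.SYN_FAMILIES <- local({
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
})

#' Codon-usage statistics: RSCU, CBI, Nc and GC content
#'
#' RSCU is observed codon count over the family mean (1 everywhere under
#' uniform synonymous usage; 0 for unused codons of a used family). Nc is
#' Wright's effective number of codons from family homozygosity F,
#' averaged within degeneracy classes (2-, 3-, 4-, 6-fold) with the
#' standard missing-class substitution, clamped to [20, 61]. CBI follows
#' the Bennetzen-Hall form, (Nopt - Eopt) / (Ntot - Eopt), where the
#' optimal codon per amino acid defaults to the most frequent codon in the
#' analysed gene set and Eopt is the expectation under uniform usage.
#'
#' @param coding a \code{coding_alignment} or character vector of in-frame
#'   sequences (pooled).
#' @param optimal_codons optional named character vector (amino acid ->
#'   optimal codon) overriding the in-set default.
#' @return a \code{codon_usage_stats} list: rscu (named numeric over 61
#'   codons), cbi, nc, gc, codon_counts.
#' @export
codon_usage <- function(coding, optimal_codons = NULL) {
  seqs <- if (inherits(coding, "coding_alignment")) coding$alleles else coding
  if (any(nchar(seqs) %% 3 != 0)) stop("sequences must be in frame")
  codons <- unlist(lapply(seqs, .codon_split), use.names = FALSE)
  codons <- codons[codons %in% names(Biostrings::GENETIC_CODE)]
  counts <- table(factor(codons, levels = names(Biostrings::GENETIC_CODE)))
  counts <- counts[Biostrings::GENETIC_CODE[names(counts)] != "*"]
  counts <- stats::setNames(as.numeric(counts), names(counts))

  # RSCU
  rscu <- counts * NA_real_
  for (aa in names(.SYN_FAMILIES)) {
    fam <- .SYN_FAMILIES[[aa]]
    tot <- sum(counts[fam])
    rscu[fam] <- if (tot == 0) 0 else counts[fam] / (tot / length(fam))
  }

  # Nc (Wright): F per amino acid with n >= 2 codons observed
  deg_class <- vapply(.SYN_FAMILIES, length, 0L)
  F_aa <- rep(NA_real_, length(.SYN_FAMILIES))
  names(F_aa) <- names(.SYN_FAMILIES)
  for (aa in names(.SYN_FAMILIES)) {
    fam <- .SYN_FAMILIES[[aa]]
    n <- sum(counts[fam])
    if (length(fam) == 1 || n < 2) next
    p <- counts[fam] / n
    F_aa[aa] <- (n * sum(p^2) - 1) / (n - 1)
  }
  class_mean <- function(k) {
    f <- F_aa[deg_class == k]
    f <- f[!is.na(f) & f > 0]
    if (!length(f)) NA_real_ else mean(f)
  }
  F2 <- class_mean(2); F3 <- class_mean(3); F4 <- class_mean(4); F6 <- class_mean(6)
  if (is.na(F3)) {                        # missing-class correction (Ile only)
    F3 <- if (!is.na(F2) && !is.na(F4)) (F2 + F4) / 2 else F2
  }
  if (is.na(F6)) F6 <- F4                 # 6-fold treated like 4-fold if absent
  n2 <- sum(deg_class == 2); n4 <- sum(deg_class == 4); n6 <- sum(deg_class == 6)
  nc <- if (any(is.na(c(F2, F3, F4, F6)))) NA_real_ else {
    2 + n2 / F2 + 1 / F3 + n4 / F4 + n6 / F6
  }
  if (!is.na(nc)) nc <- min(max(nc, 20), 61)

  # CBI
  if (is.null(optimal_codons)) {
    optimal_codons <- vapply(.SYN_FAMILIES, function(fam) {
      fam[which.max(counts[fam])]
    }, "")
  }
  multi <- names(.SYN_FAMILIES)[deg_class >= 2]
  n_tot <- sum(vapply(multi, function(aa) sum(counts[.SYN_FAMILIES[[aa]]]), 0))
  n_opt <- sum(vapply(multi, function(aa) counts[[optimal_codons[[aa]]]], 0))
  e_opt <- sum(vapply(multi, function(aa) {
    sum(counts[.SYN_FAMILIES[[aa]]]) / length(.SYN_FAMILIES[[aa]])
  }, 0))
  cbi <- if (n_tot - e_opt > 0) (n_opt - e_opt) / (n_tot - e_opt) else NA_real_

  gc_frac <- {
    all_b <- unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE)
    mean(all_b %in% c("G", "C"))
  }
  structure(list(rscu = rscu, cbi = cbi, nc = nc, gc = gc_frac,
                 codon_counts = counts, optimal_codons = optimal_codons),
            class = "codon_usage_stats")
}
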