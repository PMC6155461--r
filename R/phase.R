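#' Phase final variant calls into two haplotype sequences
#'
#' Reads are clustered by their bases at the heterozygous sites of the
#' final call set (read-backed phasing by majority linkage). The most
#' frequent genotype-consistent pattern defines one haplotype; the
#' position-wise complementary pattern (the other genotype base at every
#' het site, which handles tri-allelic sites through co-occurrence
#' counting) defines the second. Both haplotypes are spliced onto the
#' reference with homozygous variants substituted everywhere. Homozygous
#' samples return two identical sequences.
#'
#' @param pileup a \code{site_pileup} (post chimera removal).
#' @param calls final reconciled calls (data.frame pos, ref, a1, a2, ...).
#' @param params [caller_params()]; \code{ambiguity_frac} controls when
#'   competing phasings are declared ambiguous.
#' @return a \code{phased_pair} list: haplotypes (character(2), full
#'   amplicon length), support (reads backing each), phased sites; or an
#'   object with \code{error} set to "phase_ambiguous"/"phase_inconsistent"
#'   when linkage cannot be resolved.
#' @export
phase_haplotypes <- function(pileup, calls, params = caller_params()) {
  ref_bases <- strsplit(pileup$reference, "", fixed = TRUE)[[1]]
  template <- ref_bases
  if (nrow(calls)) {
    hom <- calls[calls$a1 == calls$a2, , drop = FALSE]
    if (nrow(hom)) template[hom$pos + 1L] <- hom$a1
  }
  het <- calls[calls$a1 != calls$a2, , drop = FALSE]
  if (!nrow(het)) {
    hap <- paste(template, collapse = "")
    return(structure(list(haplotypes = c(hap, hap),
                          support = c(pileup$n_reads, pileup$n_reads),
                          het_sites = integer(0), error = NULL),
                     class = "phased_pair"))
  }
  het <- het[order(het$pos), , drop = FALSE]
  sub <- pileup$bases[, het$pos + 1L, drop = FALSE]
  pat <- apply(sub, 1, paste, collapse = "")
  tab <- sort(table(pat), decreasing = TRUE)

  consistent <- vapply(names(tab), function(p) {
    b <- strsplit(p, "", fixed = TRUE)[[1]]
    all(b == het$a1 | b == het$a2)
  }, TRUE)
  ctab <- tab[consistent]
  if (!length(ctab)) {
    return(structure(list(haplotypes = NULL, support = NULL,
                          het_sites = het$pos, error = "phase_inconsistent"),
                     class = "phased_pair"))
  }
  h1_pat <- strsplit(names(ctab)[1], "", fixed = TRUE)[[1]]
  h2_pat <- ifelse(h1_pat == het$a1, het$a2, het$a1)
  h2_key <- paste(h2_pat, collapse = "")
  n1 <- as.integer(ctab[1])
  n2 <- if (h2_key %in% names(ctab)) as.integer(ctab[h2_key]) else 0L
  if (n2 == 0L) {
    return(structure(list(haplotypes = NULL, support = NULL,
                          het_sites = het$pos, error = "phase_inconsistent"),
                     class = "phased_pair"))
  }
  others <- ctab[!(names(ctab) %in% c(names(ctab)[1], h2_key))]
  if (length(others) && max(others) >= (1 - params$ambiguity_frac) * n2) {
    return(structure(list(haplotypes = NULL, support = NULL,
                          het_sites = het$pos, error = "phase_ambiguous"),
                     class = "phased_pair"))
  }
  mk <- function(p) {
    s <- template
    s[het$pos + 1L] <- p
    paste(s, collapse = "")
  }
  structure(list(haplotypes = c(mk(h1_pat), mk(h2_pat)),
                 support = c(n1, n2), het_sites = het$pos, error = NULL),
            class = "phased_pair")
}
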