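# Shared builders for constructed read sets and small panels.

# reads data.frame from raw sequences (constant Q30 qualities)
make_reads <- function(seqs, ids = sprintf("r%04d", seq_along(seqs)),
                       orientation = NULL) {
  d <- data.frame(id = ids, seq = seqs, qual = strrep("?", nchar(seqs)),
                  stringsAsFactors = FALSE)
  if (!is.null(orientation)) d$orientation <- orientation
  d
}

# barcoded read: fwd barcode + amplicon + revcomp(rev barcode)
barcoded <- function(amplicon, fwd, rev) paste0(fwd, amplicon, revcomp(rev))

# mutate positions (1-based) of a sequence to given bases
mutate_seq <- function(seq, pos, base) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[pos] <- base
  paste(s, collapse = "")
}

# small deterministic two-allele locus: reference plus a het sample's reads
# with substitutions at the given positions on allele 2
two_allele_reads <- function(reference, var_pos, alt_bases,
                             n_per_allele = 50) {
  a1 <- reference
  a2 <- mutate_seq(reference, var_pos, alt_bases)
  reads <- make_reads(c(rep(a1, n_per_allele), rep(a2, n_per_allele)),
                      orientation = rep(c("+", "-"),
                                        length.out = 2 * n_per_allele))
  list(reads = reads, a1 = a1, a2 = a2)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
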