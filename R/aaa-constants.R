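#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# two-base IUPAC ambiguity codes (diploid Sanger double peaks)
IUPAC2 <- c(
  "AC" = "M", "AG" = "R", "AT" = "W",
  "CG" = "S", "CT" = "Y", "GT" = "K"
)
IUPAC2_REV <- structure(names(IUPAC2), names = unname(IUPAC2))
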