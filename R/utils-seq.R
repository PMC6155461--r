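#' Expand a one-letter nucleotide or IUPAC code to its base set
#'
#' @param code single character: A/C/G/T or a two-base ambiguity code
#'   (M, R, W, S, Y, K).
#' @return character vector of the one or two bases the code denotes.
#' @keywords internal
iupac_expand <- function(code) {
  if (code %in% DNA_BASES) return(code)
  pair <- IUPAC2_REV[[code]]
  if (is.null(pair)) stop("unsupported IUPAC code: ", code)
  c(substr(pair, 1, 1), substr(pair, 2, 2))
}

#' IUPAC code for an unordered pair of bases
#' @param a,b single bases (A/C/G/T).
#' @return one character: the base itself if \code{a == b}, else the
#'   two-base ambiguity code.
#' @keywords internal
iupac_pair <- function(a, b) {
  ifelse(a == b, a, IUPAC2[paste0(pmin(a, b), pmax(a, b))])
}

#' Reverse complement of character-vector sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] so the
#' rest of the package can stay in plain character space.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split equal-length sequences into a base matrix
#'
#' @param seqs character vector, all the same nchar.
#' @return character matrix, one row per sequence, one column per position.
#' @keywords internal
seq_matrix <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1) stop("sequences must all have equal length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = n, byrow = TRUE)
}

#' Validate that sequences use only permitted characters
#'
#' @param seqs character vector of sequences.
#' @param ids record identifiers used in error messages.
#' @param alphabet permitted characters.
#' @return invisibly TRUE; errors with record id and 1-based position of the
#'   first offending character otherwise.
#' @keywords internal
validate_alphabet <- function(seqs, ids = seq_along(seqs),
                              alphabet = c(DNA_BASES, "N", unname(IUPAC2), "-")) {
  pat <- paste0("[^", paste(alphabet, collapse = ""), "]")
  bad <- regexpr(pat, seqs)
  hit <- which(bad > 0)
  if (length(hit)) {
    i <- hit[1]
    stop(sprintf("record '%s' has invalid character '%s' at position %d",
                 ids[i], substr(seqs[i], bad[i], bad[i]), bad[i]))
  }
  invisible(TRUE)
}

#' Locate homopolymer runs in a sequence
#'
#' @param seq a single sequence.
#' @param min_len minimum run length to report (default 4, the shortest run
#'   the error model treats as homopolymer context).
#' @return data.frame with columns start, end (1-based, inclusive), base,
#'   length.
#' @export
homopolymer_runs <- function(seq, min_len = 4) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1
  keep <- r$lengths >= min_len
  data.frame(start = start[keep], end = end[keep],
             base = r$values[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Per-position homopolymer context flags
#'
#' A position is in homopolymer context when it lies inside, or immediately
#' adjacent to, a run of length >= min_len.
#'
#' @param seq a single sequence.
#' @param min_len minimum run length.
#' @return logical vector, one element per position of \code{seq}.
#' @keywords internal
homopolymer_context <- function(seq, min_len = 4) {
  L <- nchar(seq)
  flag <- logical(L)
  runs <- homopolymer_runs(seq, min_len)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      lo <- max(1L, runs$start[i] - 1L)
      hi <- min(L, runs$end[i] + 1L)
      flag[lo:hi] <- TRUE
    }
  }
  flag
}
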