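#' Align trimmed reads to a locus reference and build strand-aware pileups
#'
#' Reads whose length equals the reference take a fast vectorised path (the
#' amplicon design makes substitutions length-preserving); reads with
#' length differences are aligned glocally with affine gap penalties
#' (match +1, mismatch -2, gap open -4, gap extend -1) via
#' [Biostrings::pairwiseAlignment()] and projected into reference
#' coordinates, with deletions left-aligned inside homopolymer runs.
#' Reads aligning below \code{min_identity} are discarded and counted.
#'
#' @param reads data.frame id, seq, (qual); barcode-trimmed,
#'   forward-oriented. An optional column \code{orientation} ("+"/"-",
#'   the sequencing strand recorded at demultiplexing) drives the strand
#'   bookkeeping; reads without it are treated as "+".
#' @param reference reference sequence string.
#' @param min_identity minimum fraction of matching positions (default 0.8).
#' @param hp_min_len homopolymer-context run length (default 4).
#' @return a \code{site_pileup} object: per-strand base-count matrices
#'   (4 x L), per-strand deletion counts, per-column mean error
#'   probability, homopolymer context flags, the aligned base matrix used
#'   for clustering/phasing, and the discarded-read count.
#' @export
align_reads <- function(reads, reference, min_identity = 0.8, hp_min_len = 4) {
  L <- nchar(reference)
  ref_bases <- strsplit(reference, "", fixed = TRUE)[[1]]
  n <- nrow(reads)
  strand <- if (!is.null(reads$orientation)) reads$orientation else rep("+", n)

  M <- matrix(NA_character_, nrow = n, ncol = L)
  keep <- logical(n)
  len <- nchar(reads$seq)
  eq <- which(len == L)
  if (length(eq)) {
    Me <- seq_matrix(reads$seq[eq])
    mism <- rowSums(Me != matrix(ref_bases, nrow = length(eq), ncol = L, byrow = TRUE))
    ok <- mism <= (1 - min_identity) * L
    M[eq[ok], ] <- Me[ok, , drop = FALSE]
    keep[eq[ok]] <- TRUE
  }
  ne <- which(len != L)
  if (length(ne)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(reads$seq[ne]),
      subject = Biostrings::DNAString(reference),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 1)
    proj <- as.character(Biostrings::aligned(aln))  # ref coords, dels as "-"
    Mi <- seq_matrix(proj)
    refm <- matrix(ref_bases, nrow = length(ne), ncol = L, byrow = TRUE)
    ident <- rowSums(Mi == refm) / L
    ok <- ident >= min_identity
    if (any(ok)) {
      Mi <- Mi[ok, , drop = FALSE]
      # left-align deletions within homopolymer runs
      del <- which(Mi == "-", arr.ind = TRUE)
      if (nrow(del)) {
        for (d in seq_len(nrow(del))) {
          i <- del[d, 1]; p <- del[d, 2]
          while (p > 1 && ref_bases[p - 1] == ref_bases[p] &&
                 !is.na(Mi[i, p - 1]) && Mi[i, p - 1] == ref_bases[p]) {
            Mi[i, p] <- Mi[i, p - 1]
            Mi[i, p - 1] <- "-"
            p <- p - 1L
          }
        }
      }
      M[ne[ok], ] <- Mi
      keep[ne[ok]] <- TRUE
    }
  }

  M <- M[keep, , drop = FALSE]
  strand <- strand[keep]
  ids <- reads$id[keep]

  count_strand <- function(rows) {
    if (!length(rows)) return(matrix(0L, 4, L, dimnames = list(DNA_BASES, NULL)))
    sub <- M[rows, , drop = FALSE]
    base_i <- match(sub, DNA_BASES)             # NA for "-" / N
    col_i <- rep(seq_len(L), each = length(rows))
    okc <- !is.na(base_i)
    cnt <- tabulate((col_i[okc] - 1L) * 4L + base_i[okc], nbins = 4L * L)
    matrix(cnt, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  }
  fwd_rows <- which(strand == "+")
  rev_rows <- which(strand == "-")
  counts_fwd <- count_strand(fwd_rows)
  counts_rev <- count_strand(rev_rows)
  del_count <- function(rows) {
    if (!length(rows)) return(integer(L))
    colSums(M[rows, , drop = FALSE] == "-", na.rm = TRUE)
  }
  del_fwd <- del_count(fwd_rows)
  del_rev <- del_count(rev_rows)

  # per-column mean base error probability from qualities (Phred+33)
  err <- rep(0.001, L)
  if (!is.null(reads$qual)) {
    q <- reads$qual[keep]
    if (length(q)) {
      # constant-quality strings are the common case; use the mean per read
      mean_err <- vapply(q, function(s) {
        ph <- utf8ToInt(s) - 33L
        mean(10^(-ph / 10))
      }, 0, USE.NAMES = FALSE)
      err <- rep(mean(mean_err), L)
    }
  }

  structure(list(
    reference = reference,
    counts_fwd = counts_fwd, counts_rev = counts_rev,
    del_fwd = del_fwd, del_rev = del_rev,
    err = err,
    hp_context = homopolymer_context(reference, hp_min_len),
    bases = M, strand = strand, read_ids = ids,
    n_reads = nrow(M), discarded = n - nrow(M)), class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cat("site_pileup:", x$n_reads, "reads over", ncol(x$counts_fwd),
      "positions (", x$discarded, "discarded )\n")
  invisible(x)
}

#' Drop reads from a pileup (e.g. detected chimeras) and recount
#' @param pileup a \code{site_pileup}.
#' @param drop_rows integer row indices into \code{pileup$bases}.
#' @return a rebuilt \code{site_pileup}.
#' @keywords internal
pileup_drop_reads <- function(pileup, drop_rows) {
  if (!length(drop_rows)) return(pileup)
  keep <- setdiff(seq_len(pileup$n_reads), drop_rows)
  L <- ncol(pileup$bases)
  M <- pileup$bases[keep, , drop = FALSE]
  strand <- pileup$strand[keep]
  count_strand <- function(rows) {
    if (!length(rows)) return(matrix(0L, 4, L, dimnames = list(DNA_BASES, NULL)))
    sub <- M[rows, , drop = FALSE]
    base_i <- match(sub, DNA_BASES)
    col_i <- rep(seq_len(L), each = length(rows))
    okc <- !is.na(base_i)
    cnt <- tabulate((col_i[okc] - 1L) * 4L + base_i[okc], nbins = 4L * L)
    matrix(cnt, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  }
  fwd_rows <- which(strand == "+")
  rev_rows <- which(strand == "-")
  pileup$counts_fwd <- count_strand(fwd_rows)
  pileup$counts_rev <- count_strand(rev_rows)
  pileup$del_fwd <- if (length(fwd_rows)) colSums(M[fwd_rows, , drop = FALSE] == "-", na.rm = TRUE) else integer(L)
  pileup$del_rev <- if (length(rev_rows)) colSums(M[rev_rows, , drop = FALSE] == "-", na.rm = TRUE) else integer(L)
  pileup$bases <- M
  pileup$strand <- strand
  pileup$read_ids <- pileup$read_ids[keep]
  pileup$n_reads <- length(keep)
  pileup
}
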