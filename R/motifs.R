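#' Load regulatory-motif definitions for a locus
#'
#' Motif consensus strings, mismatch tolerances and expected windows ship
#' as editable configuration (TSV: locus, motif, consensus, window_start,
#' window_end, max_mm) rather than code: class II proximal-promoter boxes
#' (W/S, X1, X2, Y; the DQA-specific NF-kB and T boxes; the DQB TTAA box)
#' are defined by cross-species conservation, and users scanning a new
#' species may need to adjust them. Windows are 0-based offsets into the
#' supplied promoter-proximal sequence (5'->3', coding strand); NA bounds
#' disable the window constraint.
#'
#' @param locus locus name as used in the config file.
#' @param path optional TSV path; defaults to the packaged definitions.
#' @return data.frame of motif definitions.
#' @export
load_motif_defs <- function(locus, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_defs.tsv", package = "mhctyper")
  }
  defs <- utils::read.delim(path, stringsAsFactors = FALSE)
  defs <- defs[defs$locus == locus, , drop = FALSE]
  if (!nrow(defs)) stop("no motif definitions for locus ", locus)
  if (any(nchar(defs$consensus) < 4)) stop("motif consensus must be >= 4 bp")
  defs
}

#' Scan a promoter sequence for regulatory motifs
#'
#' Reports every substring within each motif's window at Hamming distance
#' at most \code{max_mm} from the consensus, on the coding strand only.
#' Overlapping hits of the same motif are reported separately, so tandem
#' duplications surface as multiple hits.
#'
#' @param sequence promoter-proximal sequence (coding strand).
#' @param defs motif definitions ([load_motif_defs()] or a compatible
#'   data.frame).
#' @return data.frame: motif, start (0-based), end (exclusive), mismatches,
#'   matched sequence. Empty (with a warning) when the sequence is shorter
#'   than every motif.
#' @export
scan_motifs <- function(sequence, defs) {
  L <- nchar(sequence)
  sb <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- list()
  any_fit <- FALSE
  for (r in seq_len(nrow(defs))) {
    cons <- defs$consensus[r]
    m <- nchar(cons)
    if (m > L) next
    any_fit <- TRUE
    maxmm <- defs$max_mm[r]
    lo <- if (!is.null(defs$window_start) && !is.na(defs$window_start[r]))
      max(0L, defs$window_start[r]) else 0L
    hi <- if (!is.null(defs$window_end) && !is.na(defs$window_end[r]))
      min(L - m, defs$window_end[r]) else L - m
    if (hi < lo) next
    cb <- strsplit(cons, "", fixed = TRUE)[[1]]
    for (s in lo:hi) {
      mm <- sum(sb[(s + 1):(s + m)] != cb)
      if (mm <= maxmm) {
        out[[length(out) + 1]] <- data.frame(
          motif = defs$motif[r], start = s, end = s + m, mismatches = mm,
          sequence = substr(sequence, s + 1, s + m), stringsAsFactors = FALSE)
      }
    }
  }
  if (!any_fit) warning("sequence shorter than every motif window")
  if (!length(out)) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect tandem duplications of short sequence units
#'
#' Finds maximal repeated units of length in [min_unit, max_unit] whose
#' exact copies are separated by at most \code{max_spacer} bp, greedily
#' preferring longer units and suppressing reports contained in an
#' already-reported repeat. Optionally aligns the sequence against an
#' unduplicated homolog to report the net inserted length, and annotates
#' any catalogued motif contained in the unit.
#'
#' @param sequence sequence to scan.
#' @param min_unit,max_unit unit length bounds (defaults 11 and 22, the
#'   size range of promoter motif duplications reported in cetaceans).
#' @param max_spacer maximum spacer between consecutive copies (default 30).
#' @param reference optional unduplicated homolog for net-insertion
#'   estimation.
#' @param motif_defs optional motif definitions; a unit containing (or
#'   contained in) a motif consensus is annotated with its name.
#' @return data.frame: unit, unit_length, copies, starts (comma-joined,
#'   0-based), spacers (comma-joined), contained_motif, net_insertion
#'   (NA without a reference).
#' @export
detect_tandem_duplications <- function(sequence, min_unit = 11, max_unit = 22,
                                       max_spacer = 30, reference = NULL,
                                       motif_defs = NULL) {
  L <- nchar(sequence)
  reports <- list()
  covered <- logical(L)
  for (u in seq(min(max_unit, L %/% 2), min_unit)) {
    if (u < 1) break
    starts <- 0:(L - u)
    units <- substring(sequence, starts + 1, starts + u)
    seen <- new.env(parent = emptyenv())
    for (s in starts) {
      unit <- units[s + 1]
      if (!is.null(seen[[unit]])) next
      seen[[unit]] <- TRUE
      occ <- starts[units == unit]
      if (length(occ) < 2) next
      # chain non-overlapping copies with spacer <= max_spacer; several
      # disjoint chains of the same unit are reported separately
      chains <- list(); cur <- occ[1]
      for (o in occ[-1]) {
        gap <- o - (cur[length(cur)] + u)
        if (gap >= 0 && gap <= max_spacer) cur <- c(cur, o)
        else { chains[[length(chains) + 1]] <- cur; cur <- o }
      }
      chains[[length(chains) + 1]] <- cur
      chains <- Filter(function(ch) length(ch) >= 2, chains)
      if (!length(chains)) next
      for (chain in chains) {
      span <- (chain[1] + 1):(chain[length(chain)] + u)
      if (all(covered[span])) next            # inside an already-found repeat
      covered[span] <- TRUE
      spacers <- diff(chain) - u
      contained <- NA_character_
      if (!is.null(motif_defs)) {
        hit <- vapply(seq_len(nrow(motif_defs)), function(r) {
          grepl(motif_defs$consensus[r], unit, fixed = TRUE) ||
            grepl(unit, motif_defs$consensus[r], fixed = TRUE)
        }, TRUE)
        if (any(hit)) contained <- motif_defs$motif[which(hit)[1]]
      }
      reports[[length(reports) + 1]] <- data.frame(
        unit = unit, unit_length = u, copies = length(chain),
        starts = paste(chain, collapse = ","),
        spacers = paste(spacers, collapse = ","),
        contained_motif = contained, net_insertion = NA_integer_,
        stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(reports)) do.call(rbind, reports) else
    data.frame(unit = character(0), unit_length = integer(0),
               copies = integer(0), starts = character(0),
               spacers = character(0), contained_motif = character(0),
               net_insertion = integer(0), stringsAsFactors = FALSE)
  if (!is.null(reference) && nrow(out)) {
    out$net_insertion <- net_insertion(sequence, reference)
  }
  out
}

#' Net inserted length of a sequence relative to an unduplicated homolog
#'
#' Inserted minus deleted bases, i.e. how much longer the duplicated
#' arrangement is than the homolog (a duplication that also replaced part
#' of the flanking spacer nets less than the full duplicated unit).
#'
#' @param sequence,reference sequences to compare.
#' @return integer net insertion (can be negative).
#' @export
net_insertion <- function(sequence, reference) {
  nchar(sequence) - nchar(reference)
}

#' Per-column Shannon entropy of an alignment
#'
#' H = -sum p log2 p per column. Gap handling: "exclude" renormalises
#' over non-gap states (H bounded by 2 bits for nucleotides);
#' "fifth_state" treats "-" as a fifth character (bound log2 5).
#' All-gap columns yield NA (masked).
#'
#' @param seqs character vector of aligned equal-length sequences.
#' @param gap_mode "exclude" or "fifth_state".
#' @return an \code{entropy_profile} data.frame: column (1-based), H
#'   (bits), coverage (non-gap fraction).
#' @export
column_entropy <- function(seqs, gap_mode = c("exclude", "fifth_state")) {
  gap_mode <- match.arg(gap_mode)
  M <- seq_matrix(toupper(seqs))
  out <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    if (gap_mode == "exclude") col <- col[col != "-"]
    if (!length(col)) return(c(H = NA_real_, coverage = 0))
    p <- table(col) / length(col)
    c(H = -sum(p * log2(p)), coverage = mean(M[, j] != "-"))
  }, c(H = 0, coverage = 0))
  data.frame(column = seq_len(ncol(M)), H = out["H", ],
             coverage = out["coverage", ])
}
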