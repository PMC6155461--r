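#' Length-filter reads before barcode search
#'
#' Reads shorter than the expected amplicon length are unlikely to carry
#' both barcodes; the filter keeps reads with length >= \code{min_len}
#' (deletions make slightly longer-than-minimum reads legitimate, hence a
#' floor rather than an exact length).
#'
#' @param reads data.frame with columns id, seq and optionally qual.
#' @param min_len minimum retained read length (default 350).
#' @return the retained rows of \code{reads}.
#' @export
filter_length <- function(reads, min_len = 350) {
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Build a barcode panel mapping dual-barcode combinations to samples
#'
#' @param sample_barcodes data.frame sample_id, fwd, rev (barcode
#'   sequences, each exactly 10 bp).
#' @param fwd_barcodes,rev_barcodes full sets of barcodes in play (used to
#'   recognise unused combinations); default: those present in
#'   \code{sample_barcodes}.
#' @return a \code{barcode_panel} list.
#' @export
barcode_panel <- function(sample_barcodes,
                          fwd_barcodes = unique(sample_barcodes$fwd),
                          rev_barcodes = unique(sample_barcodes$rev)) {
  if (any(nchar(c(fwd_barcodes, rev_barcodes)) != 10)) {
    stop("barcodes must be exactly 10 bp")
  }
  if (any(duplicated(c(fwd_barcodes, rev_barcodes)))) {
    stop("duplicate barcode sequences in panel")
  }
  key <- paste(sample_barcodes$fwd, sample_barcodes$rev, sep = "+")
  if (any(duplicated(key))) stop("barcode combination assigned twice")
  structure(list(map = stats::setNames(sample_barcodes$sample_id, key),
                 fwd = fwd_barcodes, rev = rev_barcodes),
            class = "barcode_panel")
}

#' Demultiplex reads by exact dual 10-bp barcodes
#'
#' A read is assigned iff its first 10 bp exactly match a forward barcode
#' AND its last 10 bp exactly match the reverse complement of a reverse
#' barcode, testing both orientations (library ligation leaves reads in
#' either orientation). Assigned reads are orientation-normalised to the
#' forward strand and trimmed of exactly 10 bp at each end. Reads whose
#' barcode combination is valid but mapped to no sample accumulate in the
#' unused-combination tally; everything else is unassigned.
#'
#' @param reads data.frame id, seq, (qual); already length-filtered.
#' @param panel a [barcode_panel()].
#' @return list with \code{samples} (named list of per-sample read
#'   data.frames, trimmed and forward-oriented) and \code{report} (a
#'   \code{demux_report}: totals, per-sample counts, unused-combination
#'   counts).
#' @export
demultiplex <- function(reads, panel) {
  n <- nrow(reads)
  if (n == 0) {
    rep0 <- structure(list(total_reads = 0L, assigned = 0L, unassigned = 0L,
                           per_sample = integer(0), unused_combos = integer(0)),
                      class = "demux_report")
    return(list(samples = list(), report = rep0))
  }
  len <- nchar(reads$seq)
  head10 <- substr(reads$seq, 1, 10)
  tail10_rc <- revcomp(substr(reads$seq, len - 9L, len))
  # forward orientation: head in F, rc(tail) in R
  f_ok <- head10 %in% panel$fwd & tail10_rc %in% panel$rev
  # reverse orientation: the read's rc has head = tail10_rc, tail-rc = head10
  r_ok <- !f_ok & tail10_rc %in% panel$fwd & head10 %in% panel$rev

  combo <- rep(NA_character_, n)
  combo[f_ok] <- paste(head10[f_ok], tail10_rc[f_ok], sep = "+")
  combo[r_ok] <- paste(tail10_rc[r_ok], head10[r_ok], sep = "+")

  matched <- f_ok | r_ok
  sample_id <- rep(NA_character_, n)
  sample_id[matched] <- unname(panel$map[combo[matched]])
  assigned <- matched & !is.na(sample_id)
  unused <- matched & is.na(sample_id)

  # orientation-normalise then trim 10 bp at each end
  seq_out <- reads$seq
  if (any(r_ok)) seq_out[r_ok] <- revcomp(seq_out[r_ok])
  seq_trim <- substr(seq_out, 11L, len - 10L)
  qual_trim <- NULL
  if (!is.null(reads$qual)) {
    q <- reads$qual
    if (any(r_ok)) {
      q[r_ok] <- vapply(strsplit(q[r_ok], "", fixed = TRUE),
                        function(x) paste(rev(x), collapse = ""), "")
    }
    qual_trim <- substr(q, 11L, len - 10L)
  }

  samples <- list()
  if (any(assigned)) {
    idx <- which(assigned)
    split_idx <- split(idx, sample_id[idx])
    orientation <- ifelse(r_ok, "-", "+")   # sequencing strand pre-normalisation
    samples <- lapply(split_idx, function(ii) {
      d <- data.frame(id = reads$id[ii], seq = seq_trim[ii],
                      orientation = orientation[ii],
                      stringsAsFactors = FALSE)
      if (!is.null(qual_trim)) d$qual <- qual_trim[ii]
      rownames(d) <- NULL
      d
    })
  }
  unused_tab <- if (any(unused)) {
    t <- table(combo[unused])
    stats::setNames(as.integer(t), names(t))
  } else integer(0)

  report <- structure(list(
    total_reads = n,
    assigned = sum(assigned),
    unassigned = sum(!matched),
    per_sample = vapply(samples, nrow, 0L),
    unused_combos = unused_tab), class = "demux_report")
  stopifnot(report$assigned + report$unassigned + sum(unused_tab) == n)
  list(samples = samples, report = report)
}

#' Apply the per-sample read-count quality-control cutoff
#'
#' Samples with fewer than \code{min_reads} reads are excluded and logged.
#' The maximum read count among unused barcode combinations is reported as
#' a contamination benchmark: genotype calls should only be trusted when a
#' sample's depth clearly exceeds the background a never-used combination
#' can accumulate.
#'
#' @param samples named list of per-sample read sets (from
#'   [demultiplex()]).
#' @param report the matching \code{demux_report}.
#' @param min_reads minimum reads per sample (default 500).
#' @return list: \code{samples} (retained), \code{excluded} (named counts),
#'   \code{background_benchmark} (max unused-combination count, 0 if none).
#' @export
sample_qc <- function(samples, report, min_reads = 500) {
  counts <- vapply(samples, nrow, 0L)
  keep <- counts >= min_reads
  list(samples = samples[keep],
       excluded = counts[!keep],
       background_benchmark = if (length(report$unused_combos)) {
         max(report$unused_combos)
       } else 0L)
}

#' @export
print.demux_report <- function(x, ...) {
  cat("demux report:", x$total_reads, "reads;",
      x$assigned, "assigned to", length(x$per_sample), "samples;",
      sum(x$unused_combos), "in unused combinations;",
      x$unassigned, "unassigned\n")
  invisible(x)
}
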