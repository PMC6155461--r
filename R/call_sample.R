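#' Genotype one sample's reads end to end
#'
#' Orchestrates the per-sample calling stack: align and pile up, cluster
#' haplotypes at candidate variant sites, remove dominant single-crossover
#' chimeric clusters, mask strand-biased one-strand variants (misalignment
#' artifacts), run both callers, reconcile disagreements through the error
#' taxonomy, and phase the final calls into two allele sequences.
#'
#' @param reads per-sample read data.frame (id, seq, qual, optional
#'   orientation) with barcodes already trimmed.
#' @param reference locus reference string.
#' @param params [caller_params()].
#' @return a \code{sample_callset}: final calls, review sites, phased pair,
#'   reconciliation-class log, cluster summary and pileup counters.
#' @export
call_sample <- function(reads, reference, params = caller_params()) {
  pileup <- align_reads(reads, reference,
                        min_identity = params$min_identity,
                        hp_min_len = params$hp_min_len)
  classes <- list()
  log_class <- function(class, detail) {
    classes[[length(classes) + 1]] <<- data.frame(
      class = class, detail = detail, stringsAsFactors = FALSE)
  }

  candidate_sites <- function(pu) {
    cnt <- pu$counts_fwd + pu$counts_rev
    depth <- colSums(cnt)
    second <- apply(cnt, 2, function(x) sort(x, decreasing = TRUE)[2])
    which(depth > 0 & second / pmax(depth, 1) >= params$dominant_frac) - 1L
  }

  sites0 <- candidate_sites(pileup)
  clusters <- haplotype_clusters(pileup, sites0)

  # --- chimera removal: >= 3 dominant clusters, recombinant pattern test
  n_chimera_removed <- 0L
  dominant_n <- ceiling(params$dominant_frac * max(pileup$n_reads, 1))
  dom <- clusters$counts >= dominant_n
  if (sum(dom) >= 3 && length(sites0) >= 2) {
    dom_clusters <- structure(list(sites = clusters$sites,
                                   patterns = clusters$patterns[dom],
                                   counts = clusters$counts[dom],
                                   read_pattern = clusters$read_pattern),
                              class = "haplotype_clusters")
    verdicts <- detect_chimeric_haplotypes(dom_clusters)
    chim_pat <- verdicts$pattern[verdicts$verdict == "chimeric"]
    if (length(chim_pat)) {
      drop_rows <- which(clusters$read_pattern %in% chim_pat)
      n_chimera_removed <- length(drop_rows)
      log_class("chimera", sprintf("%d reads in %d recombinant cluster(s) removed",
                                   n_chimera_removed, length(chim_pat)))
      pileup <- pileup_drop_reads(pileup, drop_rows)
      sites0 <- candidate_sites(pileup)
      clusters <- haplotype_clusters(pileup, sites0)
    }
  }

  # --- strand-bias masking: variant present on one strand only while the
  # other strand has real coverage -> recompute the site on the clean strand
  L <- nchar(reference)
  mask <- matrix(TRUE, 2, L)
  covf <- colSums(pileup$counts_fwd) + pileup$del_fwd
  covr <- colSums(pileup$counts_rev) + pileup$del_rev
  ref_bases <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (p in seq_len(L)) {
    nf <- pileup$counts_fwd[, p]; nr <- pileup$counts_rev[, p]
    biased_fwd <- FALSE; biased_rev <- FALSE
    for (bi in seq_along(DNA_BASES)) {
      if (DNA_BASES[bi] == ref_bases[p]) next
      if (nf[bi] > 0 && covf[p] > 0 && nf[bi] / covf[p] >= params$dominant_frac &&
          nr[bi] == 0 && covr[p] >= params$strand_min_opp) biased_fwd <- TRUE
      if (nr[bi] > 0 && covr[p] > 0 && nr[bi] / covr[p] >= params$dominant_frac &&
          nf[bi] == 0 && covf[p] >= params$strand_min_opp) biased_rev <- TRUE
    }
    if (covf[p] > 0 && pileup$del_fwd[p] / covf[p] >= params$dominant_frac &&
        pileup$del_rev[p] == 0 && covr[p] >= params$strand_min_opp) biased_fwd <- TRUE
    if (covr[p] > 0 && pileup$del_rev[p] / covr[p] >= params$dominant_frac &&
        pileup$del_fwd[p] == 0 && covf[p] >= params$strand_min_opp) biased_rev <- TRUE
    if (biased_fwd && !biased_rev) {
      mask[1, p] <- FALSE
      log_class("strand_bias_misalignment",
                sprintf("pos %d recomputed on reverse strand", p - 1L))
    } else if (biased_rev && !biased_fwd) {
      mask[2, p] <- FALSE
      log_class("strand_bias_misalignment",
                sprintf("pos %d recomputed on forward strand", p - 1L))
    }
  }
  if (all(mask)) mask_arg <- NULL else mask_arg <- mask

  ratio <- call_ratio(pileup, params, mask_arg)
  lik <- call_likelihood(pileup, params, mask_arg)
  rec <- reconcile_calls(ratio, lik, pileup, clusters, params)
  phased <- phase_haplotypes(pileup, rec$calls, params)

  classes_df <- if (length(classes)) do.call(rbind, classes) else
    data.frame(class = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  structure(list(calls = rec$calls, review = rec$review, phased = phased,
                 classes = classes_df, clusters = clusters,
                 n_reads = pileup$n_reads, discarded = pileup$discarded,
                 n_chimera_removed = n_chimera_removed,
                 reference = reference), class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  cat("sample_callset:", x$n_reads, "reads,", nrow(x$calls), "variant calls,",
      nrow(x$review), "review sites,", x$n_chimera_removed,
      "chimeric reads removed\n")
  invisible(x)
}
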