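#' Read sequence records from FASTA or FASTQ
#'
#' Wraps Biostrings readers and adds the validation the pipeline relies on:
#' sequences are uppercased (with a warning when lowercase was present),
#' non-IUPAC characters are rejected with the record name and 1-based
#' position, and FASTQ quality strings must match their sequence lengths.
#'
#' @param path file path.
#' @param format one of "fasta", "fastq", "aligned_fasta". Aligned FASTA
#'   additionally allows "-" and requires equal row lengths.
#' @return data.frame with columns id, seq and, for FASTQ, qual
#'   (Phred+33 strings).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq", "aligned_fasta")) {
  format <- match.arg(format)
  if (format == "fastq") {
    # the reader emits a spurious note about dropped metadata columns
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    rec <- data.frame(id = names(x),
                      seq = as.character(x),
                      qual = as.character(Biostrings::quality(x)),
                      stringsAsFactors = FALSE)
    bad <- which(nchar(rec$seq) != nchar(rec$qual))
    if (length(bad)) {
      stop(sprintf("record '%s': quality length %d != sequence length %d",
                   rec$id[bad[1]], nchar(rec$qual[bad[1]]), nchar(rec$seq[bad[1]])))
    }
  } else {
    # read as B strings so we can report positions of invalid characters
    x <- Biostrings::readBStringSet(path)
    rec <- data.frame(id = names(x), seq = as.character(x),
                      stringsAsFactors = FALSE)
  }
  if (any(grepl("[a-z]", rec$seq))) {
    warning("lowercase bases found; uppercasing")
    rec$seq <- toupper(rec$seq)
  }
  alphabet <- c(DNA_BASES, "N", unname(IUPAC2))
  if (format == "aligned_fasta") alphabet <- c(alphabet, "-")
  validate_alphabet(rec$seq, rec$id, alphabet)
  if (format == "aligned_fasta" && length(unique(nchar(rec$seq))) > 1) {
    stop("aligned FASTA rows must all have equal length")
  }
  rownames(rec) <- NULL
  rec
}

#' Write sequence records to FASTA
#' @param ids,seqs record names and sequences.
#' @param path output path.
#' @export
write_fasta <- function(ids, seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write sequence records to FASTQ (Sanger Phred+33)
#' @param ids,seqs,quals record names, sequences and quality strings.
#' @param path output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  invisible(path)
}

#' Read FASTQ written by this package (or any Sanger-encoded FASTQ)
#' @param path file path.
#' @return data.frame id, seq, qual.
#' @export
read_fastq <- function(path) read_sequences(path, "fastq")

#' Write reconciled variant calls as minimal VCF 4.2
#'
#' Internal coordinates are 0-based half-open; VCF output is 1-based per the
#' standard. INFO carries caller provenance (CALLER) and the reconciliation
#' class (RECON); GT is emitted phased ("|") when a phase is available.
#'
#' @param calls data.frame with columns pos (0-based), ref, allele1, allele2
#'   (genotype bases), caller, status, qual. Optional column phased (logical).
#' @param reference reference sequence string (for bounds checking).
#' @param locus locus name used as CHROM.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants <- function(calls, reference, locus, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", locus, nchar(reference)),
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Calling route: ratio, likelihood or both\">",
    "##INFO=<ID=RECON,Number=1,Type=String,Description=\"Reconciliation status/class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE"), collapse = "\t")
  )
  lines <- character(0)
  if (!is.null(calls) && nrow(calls)) {
    if (any(calls$pos < 0 | calls$pos >= nchar(reference))) {
      stop("call position outside reference")
    }
    for (i in seq_len(nrow(calls))) {
      pos0 <- calls$pos[i]
      ref <- substr(reference, pos0 + 1, pos0 + 1)
      gt_bases <- c(calls$allele1[i], calls$allele2[i])
      alt <- unique(gt_bases[gt_bases != ref])
      if (!length(alt)) next   # homozygous reference: no record
      idx <- match(gt_bases, c(ref, alt)) - 1L
      sep <- if (is.null(calls$phased) || isTRUE(calls$phased[i])) "|" else "/"
      lines <- c(lines, paste(
        locus, pos0 + 1L, ".", ref, paste(alt, collapse = ","),
        format(round(calls$qual[i], 2)), "PASS",
        sprintf("CALLER=%s;RECON=%s", calls$caller[i], calls$status[i]),
        "GT", paste(idx, collapse = sep),
        sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the parameters, seed and input-file hashes of a pipeline run so
#' the outputs can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param params named list of stage parameters.
#' @param seed integer seed used for stochastic stages.
#' @param inputs character vector of input file paths (md5-hashed if they
#'   exist).
#' @export
write_manifest <- function(path, params, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(h)
  } else list()
  params <- lapply(params, function(p) if (is.function(p)) "<function>" else p)
  jsonlite::write_json(
    list(package = "mhctyper", seed = seed, params = params,
         input_md5 = hashes, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load the packaged allele-count table (four locus tables, four strata)
#'
#' The fixture ships the per-stratum allele copy counts for the DQA/DQB
#' promoter and exon-2 loci of the bottlenose dolphin study populations
#' (ATL, ML, NIRL, SIRL). Dashes in the published table are zeros here.
#'
#' @param path optional path to a TSV with columns locus, allele,
#'   ATL, ML, NIRL, SIRL; defaults to the packaged fixture.
#' @return a population_table data.frame (see [allele_freq_table()]).
#' @export
read_population_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_counts.tsv", package = "mhctyper")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "allele")
  if (!all(need %in% names(tab))) stop("population table needs locus/allele columns")
  strata <- setdiff(names(tab), need)
  for (s in strata) {
    if (any(is.na(tab[[s]])) || any(tab[[s]] < 0)) stop("counts must be non-negative")
  }
  class(tab) <- c("population_table", "data.frame")
  tab
}
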