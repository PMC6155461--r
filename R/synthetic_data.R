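#' Generate a synthetic allele panel for one amplicon locus
#'
#' Builds \code{n_alleles} distinct equal-length sequences that differ only
#' at up to \code{n_variable_sites} columns of a random backbone, optionally
#' forcing some columns to be tri-allelic. The backbone doubles as the locus
#' reference for alignment, so every allele variant is a substitution
#' relative to it. Uses the global RNG: call \code{set.seed()} (or
#' [simulate_dataset()]) for reproducibility.
#'
#' @param locus locus name (e.g. "DQAE").
#' @param n_alleles number of distinct alleles (>= 1).
#' @param length amplicon length in bp.
#' @param n_variable_sites maximum number of variable columns.
#' @param n_triallelic number of columns forced to carry three distinct
#'   bases across the panel (requires \code{n_alleles >= 3}).
#' @return an \code{allele_set}: list with locus, names, sequences (named
#'   character vector) and reference (the backbone).
#' @export
gen_allele_set <- function(locus, n_alleles, length, n_variable_sites,
                           n_triallelic = 0) {
  stopifnot(n_alleles >= 1, length >= 1, n_variable_sites >= 0,
            n_variable_sites <= length, n_triallelic >= 0,
            n_triallelic <= n_variable_sites)
  backbone <- sample(DNA_BASES, length, replace = TRUE)
  nm <- sprintf("%s*%02d", locus, seq_len(n_alleles))
  if (n_alleles == 1) {
    seqs <- paste(backbone, collapse = "")
    return(structure(list(locus = locus, names = nm,
                          sequences = stats::setNames(seqs, nm),
                          reference = seqs),
                     class = "allele_set"))
  }
  if (n_triallelic > 0 && n_alleles < 3) {
    stop("tri-allelic columns need at least 3 alleles")
  }
  n_states <- rep(2L, n_variable_sites)
  if (n_triallelic) n_states[seq_len(n_triallelic)] <- 3L
  if (prod(n_states) < n_alleles) {
    stop("infeasible: ", n_variable_sites, " variable sites cannot yield ",
         n_alleles, " distinct alleles")
  }
  cols <- sort(sample.int(length, n_variable_sites))
  states <- lapply(seq_len(n_variable_sites), function(i) {
    ref_b <- backbone[cols[i]]
    c(ref_b, sample(setdiff(DNA_BASES, ref_b), n_states[i] - 1L))
  })

  draw_row <- function() vapply(states, function(s) sample(s, 1), "")
  for (attempt in 1:200) {
    pat <- matrix("", n_alleles, n_variable_sites)
    pat[1, ] <- vapply(states, `[`, "", 1)   # allele 1 carries the backbone
    seen <- paste(pat[1, ], collapse = "")
    ok <- TRUE
    for (a in 2:n_alleles) {
      placed <- FALSE
      for (try in 1:500) {
        row <- draw_row()
        key <- paste(row, collapse = "")
        if (!key %in% seen) { pat[a, ] <- row; seen <- c(seen, key); placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    # force tri-allelic columns to actually show all three states
    if (n_triallelic) {
      for (j in seq_len(n_triallelic)) {
        missing <- setdiff(states[[j]], unique(pat[, j]))
        for (b in missing) {
          cand <- sample(2:n_alleles)
          done <- FALSE
          for (a in cand) {
            old <- pat[a, j]
            pat[a, j] <- b
            key <- paste(pat[a, ], collapse = "")
            if (sum(apply(pat, 1, paste, collapse = "") == key) == 1) { done <- TRUE; break }
            pat[a, j] <- old
          }
          if (!done) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok && !any(duplicated(apply(pat, 1, paste, collapse = "")))) {
      seqs <- vapply(seq_len(n_alleles), function(a) {
        s <- backbone
        s[cols] <- pat[a, ]
        paste(s, collapse = "")
      }, "")
      return(structure(list(locus = locus, names = nm,
                            sequences = stats::setNames(seqs, nm),
                            reference = paste(backbone, collapse = "")),
                       class = "allele_set"))
    }
  }
  stop("could not construct a distinct allele panel; relax the constraints")
}

# fixed dual-barcode panel: 10 forward x 10 reverse, each exactly 10 bp,
# combinations assigned to samples in row-major order
DEFAULT_FWD_BARCODES <- c(
  "CTAAGGTAAC", "TAAGGAGAAC", "AAGAGGATTC", "TACCAAGATC", "CAGAAGGAAC",
  "CTGCAAGTTC", "TTCGTGATTC", "TTCCGATAAC", "TGAGCGGAAC", "CTGACCGAAC")
DEFAULT_REV_BARCODES <- c(
  "TCCTCGAATC", "TAGGTGGTTC", "TCTAACGGAC", "TTGGAGTGTC", "TCTAGAGGTC",
  "TCTGGATGAC", "TCTATTCGTC", "AGGCAATTGC", "TTAGTCGGAC", "CAGATCCATC")

#' Construct and validate a simulation configuration
#'
#' Defaults are the study conditions the simulator emulates: ~350 bp dual
#' 10-bp-barcoded amplicons read in random orientation, per-base substitution
#' errors, strand-biased single-base homopolymer deletions, and
#' single-crossover PCR chimeras formed between the two true alleles of a
#' sample.
#'
#' @param n_individuals named integer vector: individuals per stratum.
#' @param allele_freqs named list (one element per stratum) of allele
#'   frequency vectors; each must sum to 1 within 1e-9.
#' @param inbreeding_f heterozygote-deficit parameter F in [0,1];
#'   P(homozygote for allele i) = p_i^2 + F p_i (1 - p_i).
#' @param reads_per_sample integer (fixed depth) or a function(n) returning
#'   n depths.
#' @param substitution_error_rate per-base substitution error probability.
#' @param chimera_rate probability a read is a single-crossover chimera of
#'   the sample's two alleles.
#' @param homopolymer_indel_rate per-run probability that a homopolymer run
#'   (length >= \code{homopolymer_min_len}) acquires a strand-restricted
#'   single-base deletion in a sample.
#' @param homopolymer_min_len minimum run length for the indel error model.
#' @param read_orientation_prob probability a read is emitted
#'   reverse-complemented.
#' @param fwd_barcodes,rev_barcodes barcode panel (each exactly 10 bp).
#' @param rng_seed integer seed consumed by [simulate_dataset()].
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(n_individuals, allele_freqs, inbreeding_f = 0,
                       reads_per_sample = 600,
                       substitution_error_rate = 0.001,
                       chimera_rate = 0.05,
                       homopolymer_indel_rate = 0.005,
                       homopolymer_min_len = 4,
                       read_orientation_prob = 0.5,
                       fwd_barcodes = DEFAULT_FWD_BARCODES,
                       rev_barcodes = DEFAULT_REV_BARCODES,
                       rng_seed = 1L) {
  stopifnot(is.numeric(n_individuals), all(n_individuals >= 1),
            !is.null(names(n_individuals)),
            is.list(allele_freqs),
            all(names(n_individuals) %in% names(allele_freqs)))
  for (s in names(n_individuals)) {
    p <- allele_freqs[[s]]
    if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies for stratum '", s,
                                     "' must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("negative allele frequency in stratum '", s, "'")
  }
  rates <- c(inbreeding_f, substitution_error_rate, chimera_rate,
             homopolymer_indel_rate, read_orientation_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  bcs <- c(fwd_barcodes, rev_barcodes)
  if (any(nchar(bcs) != 10)) stop("barcodes must be exactly 10 bp")
  if (any(duplicated(bcs))) stop("duplicate barcode sequences in panel")
  structure(list(
    n_individuals = n_individuals, allele_freqs = allele_freqs,
    inbreeding_f = inbreeding_f, reads_per_sample = reads_per_sample,
    substitution_error_rate = substitution_error_rate,
    chimera_rate = chimera_rate,
    homopolymer_indel_rate = homopolymer_indel_rate,
    homopolymer_min_len = homopolymer_min_len,
    read_orientation_prob = read_orientation_prob,
    fwd_barcodes = fwd_barcodes, rev_barcodes = rev_barcodes,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' Draw diploid genotypes from per-stratum allele frequencies
#'
#' With inbreeding coefficient F, each individual is, with probability F,
#' homozygous for a single allele drawn from the frequency vector; otherwise
#' its two allele copies are drawn independently. This realises
#' P(homozygote i) = p_i^2 + F p_i (1 - p_i). Uses the global RNG.
#'
#' @param allele_set an [gen_allele_set()] result.
#' @param config a [sim_config()].
#' @return truth data.frame: sample_id, stratum, locus, allele1, allele2.
#' @export
gen_population_genotypes <- function(allele_set, config) {
  out <- list()
  for (s in names(config$n_individuals)) {
    n <- config$n_individuals[[s]]
    if (n < 1) stop("stratum '", s, "' has zero individuals")
    p <- config$allele_freqs[[s]]
    alleles <- if (!is.null(names(p))) names(p) else allele_set$names[seq_along(p)]
    if (!all(alleles %in% allele_set$names)) {
      stop("frequencies must be defined over allele-set names")
    }
    inbred <- stats::runif(n) < config$inbreeding_f
    a1 <- sample(alleles, n, replace = TRUE, prob = p)
    a2 <- ifelse(inbred, a1, sample(alleles, n, replace = TRUE, prob = p))
    out[[s]] <- data.frame(
      sample_id = sprintf("%s_%03d", s, seq_len(n)),
      stratum = s, locus = allele_set$locus,
      allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, out)
  rownames(truth) <- NULL
  truth
}

# delete one base at the start of a homopolymer run (positions are 1-based
# in the un-deleted amplicon); runs applied right-to-left by the caller
.delete_at <- function(seqs, pos) {
  paste0(substr(seqs, 1, pos - 1L), substr(seqs, pos + 1L, nchar(seqs)))
}

#' Simulate barcoded amplicon reads with ground truth
#'
#' Each read is forward-barcode + amplicon + reverse-complemented reverse
#' barcode, reverse-complemented as a whole with probability
#' \code{read_orientation_prob}. Chimeric reads join the sample's allele A
#' left of a uniform crossover to allele B right of it. Homopolymer
#' deletions affect only reads of one (randomly chosen) orientation per run
#' per sample, mimicking strand-restricted flow-space errors. Substitution
#' errors are applied per base independently of the written quality (Q30).
#' Uses the global RNG.
#'
#' @param truth genotype truth from [gen_population_genotypes()].
#' @param allele_set the allele panel.
#' @param config a [sim_config()].
#' @return list with \code{reads} (data.frame id, seq, qual),
#'   \code{read_info} (per-read provenance: read id, sample, source allele,
#'   chimera crossover or NA, error counts), and \code{sample_barcodes}
#'   (sample to barcode-pair map).
#' @export
gen_amplicon_reads <- function(truth, allele_set, config) {
  if (!nrow(truth)) stop("truth is empty")
  n_samp <- nrow(truth)
  n_combo <- length(config$fwd_barcodes) * length(config$rev_barcodes)
  if (n_samp > n_combo) stop("more samples than barcode combinations")
  fwd_i <- ((seq_len(n_samp) - 1L) %% length(config$fwd_barcodes)) + 1L
  rev_i <- ((seq_len(n_samp) - 1L) %/% length(config$fwd_barcodes)) + 1L
  sample_barcodes <- data.frame(
    sample_id = truth$sample_id,
    fwd = config$fwd_barcodes[fwd_i],
    rev = config$rev_barcodes[rev_i], stringsAsFactors = FALSE)
  rev_bc_rc <- stats::setNames(revcomp(config$rev_barcodes), config$rev_barcodes)

  ref_runs <- homopolymer_runs(allele_set$reference, config$homopolymer_min_len)
  all_reads <- vector("list", n_samp)
  all_info <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    a1 <- allele_set$sequences[[truth$allele1[i]]]
    a2 <- allele_set$sequences[[truth$allele2[i]]]
    if (is.null(a1) || is.null(a2)) stop("sample with no allele pair")
    L <- nchar(a1)
    n <- if (is.function(config$reads_per_sample)) {
      config$reads_per_sample(1)
    } else config$reads_per_sample
    n <- as.integer(n)

    src <- sample(1:2, n, replace = TRUE)
    seqs <- ifelse(src == 1L, a1, a2)
    chim <- stats::runif(n) < config$chimera_rate
    xover <- rep(NA_integer_, n)
    if (any(chim)) {
      k <- sample.int(L - 1L, sum(chim), replace = TRUE)
      xover[chim] <- k
      left <- ifelse(src[chim] == 1L, a1, a2)
      right <- ifelse(src[chim] == 1L, a2, a1)
      seqs[chim] <- paste0(substr(left, 1, k), substr(right, k + 1L, L))
    }

    orient_rev <- stats::runif(n) < config$read_orientation_prob
    has_del <- logical(n)
    if (nrow(ref_runs)) {
      fire <- stats::runif(nrow(ref_runs)) < config$homopolymer_indel_rate
      for (r in rev(which(fire))) {          # right-to-left keeps positions valid
        bad_strand_rev <- stats::runif(1) < 0.5
        hit <- if (bad_strand_rev) orient_rev else !orient_rev
        if (any(hit)) {
          seqs[hit] <- .delete_at(seqs[hit], ref_runs$start[r])
          has_del <- has_del | hit
        }
      }
    }

    nerr <- stats::rbinom(n, nchar(seqs), config$substitution_error_rate)
    for (j in which(nerr > 0)) {
      pos <- sample.int(nchar(seqs[j]), nerr[j])
      s <- strsplit(seqs[j], "", fixed = TRUE)[[1]]
      for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
      seqs[j] <- paste(s, collapse = "")
    }

    full <- paste0(sample_barcodes$fwd[i], seqs,
                   rev_bc_rc[[sample_barcodes$rev[i]]])
    if (any(orient_rev)) full[orient_rev] <- revcomp(full[orient_rev])
    ids <- sprintf("%s_r%05d", truth$sample_id[i], seq_len(n))
    all_reads[[i]] <- data.frame(id = ids, seq = full,
                                 qual = strrep("?", nchar(full)),  # Q30
                                 stringsAsFactors = FALSE)
    all_info[[i]] <- data.frame(
      read_id = ids, sample_id = truth$sample_id[i],
      source_allele = ifelse(src == 1L, truth$allele1[i], truth$allele2[i]),
      chimera = chim, crossover = xover, n_subst = nerr,
      homopolymer_del = has_del, orientation = ifelse(orient_rev, "-", "+"),
      stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, all_reads),
       read_info = do.call(rbind, all_info),
       sample_barcodes = sample_barcodes)
}

#' Sanger-style IUPAC consensus of each diploid sample
#'
#' Position-wise merge of the sample's two alleles: identical bases are
#' emitted verbatim, differing bases as the two-base IUPAC ambiguity code,
#' mirroring double chromatogram peaks.
#'
#' @param truth genotype truth data.frame.
#' @param allele_set the allele panel.
#' @return data.frame sample_id, seq (over ACGT + ambiguity codes).
#' @export
gen_sanger_consensus <- function(truth, allele_set) {
  seqs <- vapply(seq_len(nrow(truth)), function(i) {
    a1 <- allele_set$sequences[[truth$allele1[i]]]
    a2 <- allele_set$sequences[[truth$allele2[i]]]
    if (nchar(a1) != nchar(a2)) stop("alleles of unequal length")
    b1 <- strsplit(a1, "", fixed = TRUE)[[1]]
    b2 <- strsplit(a2, "", fixed = TRUE)[[1]]
    paste(iupac_pair(b1, b2), collapse = "")
  }, "")
  data.frame(sample_id = truth$sample_id, seq = seqs, stringsAsFactors = FALSE)
}

#' Run the whole generator under one seed
#'
#' Seeds the RNG from \code{config$rng_seed}, draws genotypes and reads, and
#' optionally writes FASTQ (Phred+33), a truth TSV and the allele FASTA.
#' Identical config and seed give byte-identical FASTQ.
#'
#' @param allele_set the allele panel.
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list: truth, reads, read_info, sample_barcodes, allele_set and
#'   (when written) file paths.
#' @export
simulate_dataset <- function(allele_set, config, dir = NULL) {
  set.seed(config$rng_seed)
  truth <- gen_population_genotypes(allele_set, config)
  sim <- gen_amplicon_reads(truth, allele_set, config)
  out <- c(list(truth = truth, allele_set = allele_set), sim)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq <- file.path(dir, "reads.fastq")
    write_fastq(sim$reads$id, sim$reads$seq, sim$reads$qual, fq)
    tr <- file.path(dir, "truth.tsv")
    utils::write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
    fa <- file.path(dir, "alleles.fasta")
    write_fasta(allele_set$names, unname(allele_set$sequences), fa)
    write_manifest(file.path(dir, "manifest.json"),
                   params = config[setdiff(names(config), c("allele_freqs"))],
                   seed = config$rng_seed, inputs = character(0))
    out$files <- c(fastq = fq, truth = tr, alleles = fa)
  }
  out
}
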