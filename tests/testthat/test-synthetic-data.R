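test_that("allele panels respect variable-site and distinctness constraints", {
  set.seed(11)
  single <- gen_allele_set("L", 1, 40, 5)
  expect_length(single$sequences, 1)

  panel <- gen_allele_set("DQAE", 10, 350, 18, n_triallelic = 2)
  expect_false(any(duplicated(panel$sequences)))
  expect_true(all(nchar(panel$sequences) == 350))
  M <- do.call(rbind, strsplit(unname(panel$sequences), ""))
  n_states <- apply(M, 2, function(x) length(unique(x)))
  expect_lte(sum(n_states > 1), 18)
  expect_equal(sum(n_states == 3), 2)

  # brute-force column census on the forced tri-allelic case
  quad <- gen_allele_set("L", 4, 30, 2, n_triallelic = 1)
  Mq <- do.call(rbind, strsplit(unname(quad$sequences), ""))
  census <- apply(Mq, 2, function(x) length(unique(x)))
  expect_equal(sum(census == 3), 1)
  expect_lte(sum(census > 1), 2)

  expect_error(gen_allele_set("L", 10, 30, 2), "infeasible")
})

test_that("genotype sampling honours frequencies and inbreeding", {
  set.seed(21)
  as2 <- gen_allele_set("L", 2, 30, 4)
  cfg_f1 <- sim_config(n_individuals = c(S = 200),
                       allele_freqs = list(S = c(0.5, 0.5)),
                       inbreeding_f = 1)
  t1 <- gen_population_genotypes(as2, cfg_f1)
  expect_true(all(t1$allele1 == t1$allele2))

  cfg_f0 <- sim_config(n_individuals = c(S = 10000),
                       allele_freqs = list(S = c(0.5, 0.5)))
  t0 <- gen_population_genotypes(as2, cfg_f0)
  het <- mean(t0$allele1 != t0$allele2)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)

  # frequencies drawn from the published Atlantic DQA exon counts
  tab <- read_population_table()
  counts <- tab$ATL[tab$locus == "DQAE"]
  p <- counts / sum(counts)
  as10 <- gen_allele_set("DQAE", 10, 60, 18)
  cfg <- sim_config(n_individuals = c(ATL = 5000),
                    allele_freqs = list(ATL = p))
  tt <- gen_population_genotypes(as10, cfg)
  obs <- table(factor(c(tt$allele1, tt$allele2), levels = as10$names))
  obs_p <- as.numeric(obs) / sum(obs)
  se_p <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(obs_p - p) <= 3 * se_p + 1e-12))
})

test_that("read generation is faithful at zero noise and at stated rates", {
  set.seed(31)
  as2 <- gen_allele_set("L", 4, 60, 8)
  cfg0 <- sim_config(n_individuals = c(S = 5),
                     allele_freqs = list(S = rep(0.25, 4)),
                     reads_per_sample = 40,
                     substitution_error_rate = 0, chimera_rate = 0,
                     homopolymer_indel_rate = 0, rng_seed = 5)
  sim <- simulate_dataset(as2, cfg0)
  # strip barcodes and orientation: every read equals one of the two alleles
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ri <- sim$read_info[sim$read_info$sample_id == tr$sample_id, ]
    rd <- sim$reads[sim$reads$id %in% ri$read_id, ]
    core <- ifelse(ri$orientation == "-", revcomp(rd$seq), rd$seq)
    core <- substr(core, 11, nchar(core) - 10)
    expect_true(all(core %in% c(as2$sequences[[tr$allele1]],
                                as2$sequences[[tr$allele2]])))
  }
  # conservation: reads emitted = sum of per-sample counts
  expect_equal(nrow(sim$reads), 5 * 40)
  expect_equal(sum(table(sim$read_info$sample_id)), nrow(sim$reads))

  # chimera fraction within 3 binomial SD
  cfg_c <- sim_config(n_individuals = c(S = 20),
                      allele_freqs = list(S = rep(0.25, 4)),
                      reads_per_sample = 500,
                      substitution_error_rate = 0, chimera_rate = 0.1,
                      homopolymer_indel_rate = 0, rng_seed = 6)
  simc <- simulate_dataset(as2, cfg_c)
  n <- nrow(simc$read_info)
  frac <- mean(simc$read_info$chimera)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # a het sample's chimeric reads create a third haplotype among the reads
  het_ids <- simc$truth$sample_id[simc$truth$allele1 != simc$truth$allele2]
  found_third <- FALSE
  for (sid in het_ids) {
    tr <- simc$truth[simc$truth$sample_id == sid, ]
    ri <- simc$read_info[simc$read_info$sample_id == sid & simc$read_info$chimera, ]
    if (!nrow(ri)) next
    rd <- simc$reads[simc$reads$id %in% ri$read_id, ]
    core <- ifelse(ri$orientation == "-", revcomp(rd$seq), rd$seq)
    core <- substr(core, 11, nchar(core) - 10)
    novel <- setdiff(core, c(simc$allele_set$sequences[[tr$allele1]],
                             simc$allele_set$sequences[[tr$allele2]]))
    if (length(novel)) { found_third <- TRUE; break }
  }
  expect_true(found_third)
})

test_that("homopolymer deletions are strand-restricted", {
  set.seed(41)
  # backbone with a guaranteed long run
  repeat {
    as1 <- gen_allele_set("L", 2, 80, 4)
    if (nrow(homopolymer_runs(as1$reference)) > 0) break
  }
  cfg <- sim_config(n_individuals = c(S = 30),
                    allele_freqs = list(S = c(0.5, 0.5)),
                    reads_per_sample = 60, substitution_error_rate = 0,
                    chimera_rate = 0, homopolymer_indel_rate = 0.8,
                    rng_seed = 9)
  sim <- simulate_dataset(as1, cfg)
  ri <- sim$read_info
  per_sample <- split(ri, ri$sample_id)
  for (s in per_sample) {
    if (!any(s$homopolymer_del)) next
    # all deletion-bearing reads of one sample share one orientation per run
    expect_length(unique(s$orientation[s$homopolymer_del]), 1)
  }
  expect_true(any(ri$homopolymer_del))
})

test_that("identical config and seed give byte-identical FASTQ", {
  as2 <- gen_allele_set("L", 3, 50, 6)
  cfg <- sim_config(n_individuals = c(S = 4),
                    allele_freqs = list(S = c(0.5, 0.3, 0.2)),
                    reads_per_sample = 25, rng_seed = 123)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_dataset(as2, cfg, dir = d1)
  simulate_dataset(as2, cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
})

test_that("Sanger consensus applies IUPAC codes position-wise", {
  as1 <- list(locus = "L", names = c("A1", "A2"),
              sequences = c(A1 = "ACGTAC", A2 = "ACGTAC"),
              reference = "ACGTAC")
  class(as1) <- "allele_set"
  hom <- data.frame(sample_id = "s1", stratum = "S", locus = "L",
                    allele1 = "A1", allele2 = "A2")
  expect_equal(gen_sanger_consensus(hom, as1)$seq, "ACGTAC")

  as2 <- as1
  as2$sequences <- c(A1 = "ACGTAC", A2 = "ATGTAC")   # C/T at position 2
  cons <- gen_sanger_consensus(hom, as2)$seq
  expect_equal(substr(cons, 2, 2), "Y")

  # a pair differing at 18 sites shows exactly 18 ambiguity codes
  set.seed(51)
  base <- random_dna(350)
  pos <- sort(sample(350, 18))
  b <- strsplit(base, "")[[1]]
  alt <- vapply(b[pos], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
  as18 <- as1
  as18$sequences <- c(A1 = base, A2 = mutate_seq(base, pos, alt))
  cons <- gen_sanger_consensus(hom, as18)$seq
  n_ambig <- sum(strsplit(cons, "")[[1]] %in% c("M","R","W","S","Y","K"))
  expect_equal(n_ambig, 18)
})

test_that("sim_config validates frequencies, rates and barcodes", {
  expect_error(sim_config(c(S = 5), list(S = c(0.5, 0.4))), "sum to 1")
  expect_error(sim_config(c(S = 5), list(S = c(0.5, 0.5)), chimera_rate = 1.5),
               "rates")
  expect_error(sim_config(c(S = 5), list(S = c(0.5, 0.5)),
                          fwd_barcodes = c("ACGT")), "10 bp")
  expect_error(sim_config(c(S = 5), list(S = c(0.5, 0.5)),
                          fwd_barcodes = rep("ACGTACGTAC", 2)), "duplicate")
})
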