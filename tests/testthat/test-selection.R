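test_that("partial-codon trimming yields the expected peptide lengths", {
  set.seed(131)
  dqa <- vapply(1:3, function(i) random_dna(249), "")
  names(dqa) <- paste0("a", 1:3)
  ca <- exon_to_peptides(dqa)
  expect_equal(nchar(ca$alleles[[1]]), 246)
  expect_equal(nchar(ca$peptides[[1]]), 82)

  dqb <- c(b1 = random_dna(270))
  cb <- exon_to_peptides(dqb)
  expect_equal(nchar(cb$alleles[[1]]), 267)
  expect_equal(nchar(cb$peptides[[1]]), 89)

  expect_error(exon_to_peptides(c(x = random_dna(250))), "divisible by 3")
})

test_that("pocket enrichment G matches the published censuses within 1%", {
  dqa <- pocket_enrichment_test(12, load_pocket_mask("DQA"), 82,
                                n_in_pocket = 8)
  expect_lt(abs(dqa$G - 13.487) / 13.487, 0.01)
  expect_lt(dqa$p_g, 0.001)
  dqb <- pocket_enrichment_test(31, load_pocket_mask("DQB"), 89,
                                n_in_pocket = 18)
  expect_lt(abs(dqb$G - 19.700) / 19.700, 0.01)
  expect_lt(dqb$p_g, 0.001)

  # variation proportional to class sizes: G exactly 0
  prop <- pocket_enrichment_test(97, seq_len(15), 97, n_in_pocket = 15)
  expect_equal(prop$G, 0)
  # no variable sites: G = 0, p = 1
  none <- pocket_enrichment_test(0, seq_len(15), 82, n_in_pocket = 0)
  expect_equal(none$G, 0); expect_equal(none$p_g, 1)
})

test_that("G and chi-square agree asymptotically on well-filled tables", {
  # agreement is asymptotic: relative difference shrinks like |O-E|/E, so
  # the check uses null tables with large expected counts in both cells
  set.seed(141)
  for (i in 1:50) {
    total <- sample(1500:3000, 1)
    mask_n <- round(total * runif(1, 0.2, 0.5))
    n_var <- round(total * runif(1, 0.3, 0.6))
    n_in <- rbinom(1, n_var, mask_n / total)
    r <- pocket_enrichment_test(n_var, seq_len(mask_n), total,
                                n_in_pocket = n_in)
    if (any(r$expected < 10) || r$chisq < 1e-8) next
    expect_lt(abs(r$G - r$chisq) / r$chisq, 0.1)
  }
})

test_that("ts/tv ratio: counting mode, undefined flag, K2P recovery", {
  # 1 transition + 2 transversions
  s1 <- "AACCGG"
  s2 <- "GACAGT"   # pos1 A->G ts; pos4 C->A tv; pos6 G->T tv
  r <- titv_ratio(c(s1, s2), mode = "count")
  expect_equal(r$R, 0.5)

  # only transitions: undefined/infinite flag
  r2 <- titv_ratio(c("AACC", "GGTT"), mode = "count")
  expect_true(r2$undefined)

  # no differences at all
  r3 <- titv_ratio(c("AAAA", "AAAA"))
  expect_true(r3$undefined)

  # parameter recovery: pair evolved with ts:tv = 1 (kappa = 2), 10 kb
  set.seed(151)
  L <- 10000
  anc <- strsplit(random_dna(L), "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  der <- anc
  n_events <- rpois(L, 0.3)
  for (i in which(n_events > 0)) {
    for (e in seq_len(n_events[i])) {
      if (runif(1) < 0.5) der[i] <- ts_map[[der[i]]]
      else der[i] <- sample(tv_map[[der[i]]], 1)
    }
  }
  rk <- titv_ratio(c(paste(anc, collapse = ""), paste(der, collapse = "")),
                   mode = "k2p")
  expect_lt(abs(rk$R - 1), 0.1)
})

test_that("NG86 equals the exhaustive codon-path oracle on all 2-difference pairs", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  checked <- 0
  for (c1 in sense) {
    b1 <- strsplit(c1, "")[[1]]
    for (i in 1:2) for (j in (i + 1):3) {
      for (bi in setdiff(c("A","C","G","T"), b1[i])) {
        for (bj in setdiff(c("A","C","G","T"), b1[j])) {
          b2 <- b1; b2[i] <- bi; b2[j] <- bj
          c2 <- paste(b2, collapse = "")
          if (gc[[c2]] == "*") next
          got <- mhctyper:::.codon_path_counts(c1, c2)
          want <- oracle_path_counts(c1, c2)
          expect_equal(unname(got), unname(want), tolerance = 1e-12)
          checked <- checked + 1
        }
      }
    }
  }
  expect_gt(checked, 1000)
})

test_that("pairwise dN/dS behaves on degenerate and simple inputs", {
  r <- pairwise_dnds(c(a = "TTTAAAGGG", b = "TTTAAAGGG"))
  expect_true(r$w_undefined)
  expect_equal(r$mean_dn, 0)
  expect_equal(r$mean_ds, 0)

  # TTT -> TTC is synonymous only: dN = 0
  r2 <- pairwise_dnds(c(a = "TTTAAA", b = "TTCAAA"))
  expect_equal(r2$mean_dn, 0)

  # positive-selection signal is detectable: many nonsynonymous changes
  set.seed(161)
  base <- random_dna(300)
  base <- paste0(substr(base, 1, 297), "TGG")      # avoid in-frame stops? keep simple
  alleles <- c(a = base)
  # w > 1 on an alignment with mostly nonsynonymous differences
  b2 <- base
  cod <- mhctyper:::.codon_split(base)
  gcm <- Biostrings::GENETIC_CODE
  changed <- 0
  for (k in seq_along(cod)) {
    if (changed >= 20) break
    cb <- strsplit(cod[k], "")[[1]]
    for (alt in setdiff(c("A","C","G","T"), cb[2])) {
      nb <- cb; nb[2] <- alt                      # position 2: mostly nonsyn
      nc <- paste(nb, collapse = "")
      if (gcm[[nc]] != "*" && gcm[[nc]] != gcm[[cod[k]]]) {
        substr(b2, 3 * k - 2, 3 * k) <- nc
        changed <- changed + 1
        break
      }
    }
  }
  r3 <- pairwise_dnds(c(a = base, b = b2))
  expect_gt(r3$mean_dn, 0)
})

test_that("per-site scan classifies columns and has power at dN/dS = 5", {
  # a column with only synonymous changes sits on the w<1 side
  syn_col <- c("TTT", "TTC", "TTT", "TTC")
  inv_col <- rep("ATG", 4)
  alleles <- vapply(seq_along(syn_col), function(i)
    paste0(syn_col[i], inv_col[i]), "")
  names(alleles) <- paste0("a", 1:4)
  scan <- site_dnds_scan(alleles)
  expect_equal(scan$class[1], "w<1")
  expect_equal(scan$class[2], "no_signal")

  # power: 5 positively-selected codons among 45 neutral-invariant ones,
  # 20 alleles, each selected codon accumulating nonsynonymous changes
  set.seed(171)
  gcm <- Biostrings::GENETIC_CODE
  anc_codons <- rep("CTG", 50)
  sel_sites <- c(5, 15, 25, 35, 45)
  mutate_once <- function(codon) {
    cb <- strsplit(codon, "")[[1]]
    repeat {
      pos <- sample(1:3, 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), cb[pos]), 1)
      nb <- cb; nb[pos] <- alt
      ncod <- paste(nb, collapse = "")
      if (gcm[[ncod]] == "*") next
      is_nonsyn <- gcm[[ncod]] != gcm[[codon]]
      # accept nonsynonymous changes 5x as readily as synonymous ones
      if (is_nonsyn || runif(1) < 1 / 5) return(ncod)
    }
  }
  alleles <- vapply(1:20, function(a) {
    cods <- anc_codons
    for (k in sel_sites) {
      n_mut <- sample(0:2, 1)    # moderate divergence per allele and codon
      for (m in seq_len(n_mut)) cods[k] <- mutate_once(cods[k])
    }
    paste(cods, collapse = "")
  }, "")
  names(alleles) <- paste0("al", 1:20)
  scan2 <- site_dnds_scan(alleles)
  flagged <- scan2$codon[scan2$significant & scan2$class == "w>1"]
  expect_gte(sum(sel_sites %in% flagged), 4)
  expect_equal(scan2$class[1], "no_signal")       # invariant codon
})
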