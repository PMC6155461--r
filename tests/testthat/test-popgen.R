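test_that("the packaged allele-count table has the published shape", {
  tab <- read_population_table()
  expect_equal(nrow(tab), 33)
  expect_equal(sum(tab$locus == "DQAE"), 10)
  expect_equal(sum(tab$locus == "DQBE"), 10)
  expect_equal(sum(tab$locus == "DQAP"), 6)
  expect_equal(sum(tab$locus == "DQBP"), 7)
  # ATL gene-copy totals match the published sample sizes (2n)
  expect_equal(sum(tab$ATL[tab$locus == "DQAE"]), 44)
  expect_equal(sum(tab$ATL[tab$locus == "DQBE"]), 30)
  expect_equal(sum(tab$ATL[tab$locus == "DQAP"]), 40)
  expect_equal(sum(tab$ATL[tab$locus == "DQBP"]), 44)
})

test_that("expected heterozygosity matches the closed form and Table values", {
  tab <- read_population_table()
  he <- function(locus, stratum) {
    heterozygosity(tab[[stratum]][tab$locus == locus])$He
  }
  expect_equal(round(he("DQAE", "ATL"), 3), 0.866)
  expect_equal(round(he("DQBE", "ATL"), 3), 0.883)
  expect_equal(round(he("DQAP", "ATL"), 3), 0.706)
  expect_equal(round(he("DQBP", "ATL"), 3), 0.726)
  expect_equal(round(he("DQAE", "ML"), 3), 0.738)

  # oracle identity on random tables: He == [2n/(2n-1)](1 - sum p^2)
  set.seed(191)
  for (i in 1:50) {
    counts <- rmultinom(1, sample(20:120, 1), prob = runif(sample(2:10, 1)))[, 1]
    counts <- counts[counts >= 0]
    if (sum(counts) < 2) next
    n2 <- sum(counts); p <- counts / n2
    expect_equal(heterozygosity(counts)$He,
                 (n2 / (n2 - 1)) * (1 - sum(p^2)), tolerance = 1e-12)
  }

  # monomorphic column
  expect_equal(heterozygosity(c(10, 0, 0))$He, 0)
})

test_that("allele frequency tables sum to 2x individuals and union strata", {
  g <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    stratum = rep(c("ATL", "ML", "NIRL", "SIRL"), each = 3),
    locus = "L1",
    allele1 = rep(c("a", "b", "a", "c"), 3),
    allele2 = rep(c("b", "b", "c", "c"), 3),
    stringsAsFactors = FALSE)
  tab <- allele_freq_table(g, stratum_scheme())
  expect_equal(sum(tab$ATL), 6)                      # 2 copies x 3 individuals
  expect_equal(tab$IRL, tab$NIRL + tab$SIRL)
  expect_equal(tab$EST, tab$ML + tab$NIRL + tab$SIRL)

  # missing genotypes are dropped for that locus only
  g$allele1[1] <- NA
  expect_message(tab2 <- allele_freq_table(g, stratum_scheme()), "dropped")
  expect_equal(sum(tab2$ATL), 4)
})

test_that("allelic representation reproduces the published percentages", {
  tab <- read_population_table()
  rep_pct <- allelic_representation(tab)
  expect_equal(unname(rep_pct["ATL"]), 97L)
  expect_equal(unname(rep_pct["NIRL"]), 52L)
  expect_equal(unname(rep_pct["SIRL"]), 52L)
  # all-zero stratum
  tab$EMPTY <- 0L
  expect_equal(unname(allelic_representation(tab)["EMPTY"]), 0L)
})

test_that("HWE exact test: enumeration on canonical 2-allele tables", {
  # balanced table at HW proportions: observed is the most probable state
  p1 <- hwe_exact(matrix(c(25, 50, 0, 25), 2, 2, byrow = TRUE))
  expect_equal(p1$method, "enumeration")
  expect_gte(p1$p_value, 0.9)

  # extreme heterozygote deficit
  p2 <- hwe_exact(matrix(c(20, 0, 0, 20), 2, 2, byrow = TRUE))
  expect_lt(p2$p_value, 0.001)

  # monomorphic data
  g <- data.frame(allele1 = rep("a", 5), allele2 = rep("a", 5))
  expect_equal(hwe_exact(g)$p_value, 1)

  # enumeration is a true probability distribution (sums to 1 internally):
  # p of the union of all outcomes is 1
  g3 <- matrix(c(3, 4, 0, 5), 2, 2, byrow = TRUE)
  expect_lte(hwe_exact(g3)$p_value, 1)
})

test_that("MCMC agrees with enumeration within 0.02 on spot-check tables", {
  set.seed(201)
  tables <- list(
    matrix(c(10, 5, 0, 10), 2, 2, byrow = TRUE),
    matrix(c(4, 12, 0, 8), 2, 2, byrow = TRUE),
    matrix(c(2, 2, 0, 2), 2, 2, byrow = TRUE),
    # a 3-allele table
    {
      m <- matrix(0L, 3, 3)
      m[1, 1] <- 3; m[1, 2] <- 4; m[2, 2] <- 2; m[2, 3] <- 3; m[3, 3] <- 2
      m
    })
  for (tb in tables) {
    p_enum <- hwe_exact(tb, method = "enumeration")$p_value
    p_mcmc <- hwe_exact(tb, method = "mcmc", steps = 60000, burnin = 2000)$p_value
    expect_lt(abs(p_mcmc - p_enum), 0.02)
  }
})

test_that("Weir-Cockerham theta matches hand-computed variance components", {
  gt <- data.frame(sample_id = paste0("s", 1:20),
                   stratum = rep(c("P1", "P2"), each = 10), locus = "L1",
                   allele1 = c(rep("A", 10), rep("A", 5), rep("a", 5)),
                   allele2 = c(rep("A", 10), rep("A", 5), rep("a", 5)),
                   stringsAsFactors = FALSE)
  f <- fst_wc(gt, c("P1", "P2"), n_perm = 0)
  # hand evaluation: a = 1/9, a+b+c = 1/4 per allele -> theta = 4/9
  expect_equal(f$theta, 4 / 9, tolerance = 1e-12)

  # strata fixed for different alleles: theta = 1
  gt2 <- gt
  gt2$allele1 <- rep(c("A", "a"), each = 10)
  gt2$allele2 <- gt2$allele1
  f2 <- fst_wc(gt2, c("P1", "P2"), n_perm = 0)
  expect_equal(f2$theta, 1)

  # identical frequencies: theta near 0, permutation p not extreme
  set.seed(211)
  n <- 60
  gt3 <- data.frame(sample_id = paste0("x", 1:n),
                    stratum = rep(c("P1", "P2"), each = n / 2), locus = "L1",
                    allele1 = sample(c("A", "a"), n, replace = TRUE),
                    allele2 = sample(c("A", "a"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  f3 <- fst_wc(gt3, c("P1", "P2"), n_perm = 300)
  expect_lt(abs(f3$theta), 0.05)
  expect_gt(f3$p_value, 0.01)
})

test_that("multi-locus theta is the ratio of summed components", {
  set.seed(221)
  mk <- function(locus, p1, p2) {
    draw <- function(p, n) sample(c("A", "a"), n, replace = TRUE, prob = c(p, 1 - p))
    data.frame(sample_id = paste0(locus, "_", 1:30),
               stratum = rep(c("P1", "P2"), each = 15), locus = locus,
               allele1 = c(draw(p1, 15), draw(p2, 15)),
               allele2 = c(draw(p1, 15), draw(p2, 15)),
               stringsAsFactors = FALSE)
  }
  gt <- rbind(mk("L1", 0.9, 0.2), mk("L2", 0.5, 0.5))
  f <- fst_wc(gt, c("P1", "P2"), n_perm = 0)
  expect_equal(f$theta,
               sum(f$per_locus$a) / sum(f$per_locus$abc), tolerance = 1e-12)
})
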