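#' Stratum scheme with derived unions
#'
#' @param base character vector of base strata.
#' @param derived named list: derived stratum -> base strata it pools.
#'   The default mirrors the study design: IRL = NIRL + SIRL and
#'   EST (estuarine) = ML + NIRL + SIRL alongside base strata
#'   ATL/ML/NIRL/SIRL.
#' @return a \code{stratum_scheme} list.
#' @export
stratum_scheme <- function(base = c("ATL", "ML", "NIRL", "SIRL"),
                           derived = list(IRL = c("NIRL", "SIRL"),
                                          EST = c("ML", "NIRL", "SIRL"))) {
  for (d in names(derived)) {
    if (!all(derived[[d]] %in% base)) stop("derived stratum '", d,
                                           "' references unknown base strata")
  }
  structure(list(base = base, derived = derived), class = "stratum_scheme")
}

#' Tabulate allele copies per stratum from genotype calls
#'
#' Counts allele copies (2 per genotyped individual) per locus and
#' stratum; derived strata are element-wise sums of their base strata.
#' Individuals missing a locus are dropped for that locus only.
#'
#' @param genotypes data.frame sample_id, stratum, locus, allele1, allele2
#'   (NA alleles = missing).
#' @param scheme a [stratum_scheme()] (NULL: base strata observed in the
#'   data, no derived unions).
#' @return a \code{population_table} data.frame: locus, allele, one count
#'   column per stratum.
#' @export
allele_freq_table <- function(genotypes, scheme = NULL) {
  g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ,
                 drop = FALSE]
  n_drop <- nrow(genotypes) - nrow(g)
  if (n_drop) message(n_drop, " individual-locus records dropped (missing genotype)")
  base <- if (is.null(scheme)) sort(unique(g$stratum)) else scheme$base
  long <- rbind(
    data.frame(locus = g$locus, stratum = g$stratum, allele = g$allele1),
    data.frame(locus = g$locus, stratum = g$stratum, allele = g$allele2))
  tab <- as.data.frame(table(locus = long$locus, allele = long$allele,
                             stratum = long$stratum),
                       stringsAsFactors = FALSE)
  wide <- stats::reshape(tab, idvar = c("locus", "allele"),
                         timevar = "stratum", direction = "wide")
  names(wide) <- sub("^Freq\\.", "", names(wide))
  for (s in base) if (!s %in% names(wide)) wide[[s]] <- 0L
  wide <- wide[, c("locus", "allele", base)]
  # keep only alleles seen at their locus
  wide <- wide[rowSums(wide[, base, drop = FALSE]) > 0, , drop = FALSE]
  if (!is.null(scheme)) {
    for (d in names(scheme$derived)) {
      wide[[d]] <- rowSums(wide[, scheme$derived[[d]], drop = FALSE])
    }
  }
  wide <- wide[order(wide$locus, wide$allele), ]
  rownames(wide) <- NULL
  class(wide) <- c("population_table", "data.frame")
  wide
}

#' Observed and Nei's unbiased expected heterozygosity
#'
#' He uses Nei's small-sample correction with 2n = allele copies:
#' He = \[2n/(2n-1)\] (1 - sum p_i^2). Ho (fraction of genotyped
#' individuals carrying two distinct alleles) requires genotype records.
#'
#' @param counts numeric vector of allele copy counts (one stratum, one
#'   locus).
#' @param genotypes optional genotype data.frame restricted to the same
#'   stratum/locus, used for Ho.
#' @return a \code{het_result} list: n (individuals, when known), copies,
#'   Ho (NA without genotypes), He.
#' @export
heterozygosity <- function(counts, genotypes = NULL) {
  counts <- counts[!is.na(counts)]
  copies <- sum(counts)
  if (copies < 2) stop("need at least 2 allele copies")
  p <- counts / copies
  he <- (copies / (copies - 1)) * (1 - sum(p^2))
  ho <- NA_real_; n <- NA_integer_
  if (!is.null(genotypes) && nrow(genotypes)) {
    n <- nrow(genotypes)
    ho <- mean(genotypes$allele1 != genotypes$allele2)
  }
  structure(list(n = n, copies = copies, Ho = ho, He = he),
            class = "het_result")
}

# log-probability kernel of a genotype table under HWE conditional on
# allele counts: H log 2 - sum log g_ij! (constant terms dropped)
.hwe_lp <- function(g) {
  H <- sum(g[upper.tri(g)])
  H * log(2) - sum(lgamma(g[upper.tri(g, diag = TRUE)] + 1))
}

# genotype data.frame -> symmetric genotype count matrix (upper storage)
.geno_matrix <- function(genotypes) {
  alleles <- sort(unique(c(genotypes$allele1, genotypes$allele2)))
  k <- length(alleles)
  g <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (i in seq_len(nrow(genotypes))) {
    a <- match(genotypes$allele1[i], alleles)
    b <- match(genotypes$allele2[i], alleles)
    lo <- min(a, b); hi <- max(a, b)
    g[lo, hi] <- g[lo, hi] + 1L
  }
  g
}

# enumerate all genotype tables with the allele counts of g0; returns
# list(lp = vector of kernels, cap_hit = logical)
.hwe_enumerate <- function(g0, max_tables = 2e5) {
  k <- nrow(g0)
  a_target <- integer(k)
  for (i in 1:k) for (j in i:k) {
    a_target[i] <- a_target[i] + g0[i, j] + (i == j) * g0[i, j]
    if (j > i) a_target[j] <- a_target[j] + g0[i, j]
  }
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  lps <- numeric(0); count <- 0L; cap_hit <- FALSE
  g <- matrix(0L, k, k)
  rec <- function(ci, rem) {
    if (cap_hit) return()
    if (ci > nrow(cells)) {
      if (all(rem == 0)) {
        count <<- count + 1L
        if (count > max_tables) { cap_hit <<- TRUE; return() }
        lps[count] <<- .hwe_lp(g)
      }
      return()
    }
    i <- cells[ci, 1]; j <- cells[ci, 2]
    per <- if (i == j) 2L else 1L
    hi <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:hi) {
      r2 <- rem
      r2[i] <- r2[i] - per * v
      if (j > i) r2[j] <- r2[j] - v
      if (any(r2 < 0)) next
      # prune: remaining cells must be able to absorb what's left
      g[i, j] <<- v
      rec(ci + 1L, r2)
      if (cap_hit) break
    }
    g[i, j] <<- 0L
  }
  rec(1L, a_target)
  list(lp = lps[seq_len(min(count, max_tables))], cap_hit = cap_hit)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Complete enumeration of genotype tables conditional on the allele
#' counts when the state space is small; otherwise the Guo-Thompson
#' Markov-chain switch algorithm (Metropolis on partner swaps). The
#' p-value is the probability mass (or chain fraction) of tables no more
#' probable than the observed one. Uses the global RNG for the chain.
#'
#' @param genotypes genotype data.frame (allele1/allele2 columns) or a
#'   square genotype count matrix (upper triangle + diagonal used).
#' @param method "auto", "enumeration" or "mcmc".
#' @param steps Markov-chain steps after burn-in (default 10000).
#' @param burnin discarded initial steps (default 1000).
#' @param max_tables enumeration cap before auto falls back to MCMC.
#' @return list: p_value, method, and n_tables (enumeration) or steps.
#' @export
hwe_exact <- function(genotypes, method = c("auto", "enumeration", "mcmc"),
                      steps = 10000, burnin = 1000, max_tables = 2e5) {
  method <- match.arg(method)
  g0 <- if (is.matrix(genotypes)) {
    gm <- genotypes                       # fold any lower-triangle counts up
    gm[upper.tri(gm)] <- gm[upper.tri(gm)] + t(gm)[upper.tri(gm)]
    gm[lower.tri(gm)] <- 0L
    gm
  } else .geno_matrix(genotypes)
  k <- nrow(g0)
  n <- sum(g0)
  if (n < 2) stop("need at least 2 individuals")
  if (k < 2) return(list(p_value = 1, method = "monomorphic"))
  lp_obs <- .hwe_lp(g0)
  tol <- 1e-9

  if (method != "mcmc") {
    enum <- .hwe_enumerate(g0, max_tables)
    if (!enum$cap_hit) {
      w <- exp(enum$lp - max(enum$lp))
      p <- sum(w[enum$lp <= lp_obs + tol]) / sum(w)
      return(list(p_value = p, method = "enumeration",
                  n_tables = length(enum$lp)))
    }
    if (method == "enumeration") stop("state space exceeds max_tables")
  }

  # Guo-Thompson switch chain: draw two individuals weighted by genotype
  # counts, re-pair their four alleles, and Metropolis-Hastings-correct for
  # the count-weighted proposal (including degenerate re-pairings).
  # The state lives in a flat vector over upper-triangle cells and the
  # log-probability is updated incrementally for speed.
  cells <- which(upper.tri(g0, diag = TRUE), arr.ind = TRUE)
  ord <- order(cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]
  ci <- cells[, 1]; cj <- cells[, 2]
  ncell <- nrow(cells)
  idx_of <- matrix(0L, k, k)
  for (c in seq_len(ncell)) {
    idx_of[ci[c], cj[c]] <- c
    idx_of[cj[c], ci[c]] <- c
  }
  cell_idx <- function(a, b) idx_of[a, b]
  het <- as.numeric(ci != cj)
  gv <- g0[cbind(ci, cj)]
  lp <- lp_obs
  log2c <- log(2); loghalf <- log(0.5)
  hits <- 0L; total <- 0L
  runifs <- stats::runif(burnin + steps)       # pairing choices
  raccept <- log(stats::runif(burnin + steps)) # acceptance draws
  for (step in seq_len(burnin + steps)) {
    c1 <- sample.int(ncell, 1L, prob = gv)
    gv[c1] <- gv[c1] - 1
    c2 <- sample.int(ncell, 1L, prob = gv)
    gv[c1] <- gv[c1] + 1
    i <- ci[c1]; j <- cj[c1]; kk <- ci[c2]; l <- cj[c2]
    # the two re-pairings of alleles {i,j} x {kk,l} as cell-index pairs
    a1 <- cell_idx(i, kk); a2 <- cell_idx(j, l)
    b1 <- cell_idx(i, l);  b2 <- cell_idx(j, kk)
    pA_lo <- min(a1, a2); pA_hi <- max(a1, a2)
    pB_lo <- min(b1, b2); pB_hi <- max(b1, b2)
    deg_fwd <- pA_lo == pB_lo && pA_hi == pB_hi
    if (deg_fwd || runifs[step] < 0.5) { e1 <- a1; e2 <- a2 }
    else { e1 <- b1; e2 <- b2 }
    src_lo <- min(c1, c2); src_hi <- max(c1, c2)
    if (min(e1, e2) == src_lo && max(e1, e2) == src_hi) {
      if (step > burnin) { total <- total + 1L
        if (lp <= lp_obs + tol) hits <- hits + 1L }
      next                                   # identity move
    }
    # incremental state update on a scratch copy of the <= 4 touched cells
    dlp <- (het[e1] + het[e2] - het[c1] - het[c2]) * log2c
    w1 <- gv[c1]; dlp <- dlp + log(w1); gv[c1] <- w1 - 1
    w2 <- gv[c2]; dlp <- dlp + log(w2); gv[c2] <- w2 - 1
    m1 <- gv[e1]; dlp <- dlp - log(m1 + 1); gv[e1] <- m1 + 1
    m2 <- gv[e2]; dlp <- dlp - log(m2 + 1); gv[e2] <- m2 + 1
    # proposal terms: forward selection from the old state (w2 was read
    # after c1's removal, so it already carries the same-cell correction)
    lq_fwd <- log(w1) + log(w2) + (if (c1 != c2) log2c else 0) +
      (if (deg_fwd) 0 else loghalf)
    # reverse re-pairings of the new pair (e1, e2) are (c1, c2) and the
    # other pairing; degenerate iff both coincide
    ri <- ci[e1]; rj <- cj[e1]; rk <- ci[e2]; rl <- cj[e2]
    r1 <- cell_idx(ri, rk); r2 <- cell_idx(rj, rl)
    s1 <- cell_idx(ri, rl); s2 <- cell_idx(rj, rk)
    deg_rev <- min(r1, r2) == min(s1, s2) && max(r1, r2) == max(s1, s2)
    n1 <- gv[e1]; n2 <- gv[e2]
    lq_rev <- log(n1) + log(n2 - (e1 == e2)) +
      (if (e1 != e2) log2c else 0) + (if (deg_rev) 0 else loghalf)
    if (raccept[step] < dlp + (lq_rev - lq_fwd)) {
      lp <- lp + dlp                          # accept: keep updated gv
    } else {                                  # reject: roll back
      gv[e2] <- gv[e2] - 1; gv[e1] <- gv[e1] - 1
      gv[c2] <- gv[c2] + 1; gv[c1] <- gv[c1] + 1
    }
    if (step > burnin) {
      total <- total + 1L
      if (lp <= lp_obs + tol) hits <- hits + 1L
    }
  }
  list(p_value = hits / max(total, 1), method = "mcmc", steps = steps)
}

#' Weir-Cockerham FST (theta) with permutation test
#'
#' Per-locus theta from the WC84 variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), summed over alleles; the multi-locus estimate is the
#' ratio of summed components. The permutation test reassigns individuals
#' (genotype pairs) between the two strata and reports the fraction of
#' permuted theta values at least as large as the observed one. Uses the
#' global RNG.
#'
#' @param genotypes genotype data.frame (sample_id, stratum, locus,
#'   allele1, allele2).
#' @param strata character(2): the two strata to compare.
#' @param n_perm number of permutations (default 10100; 0 skips the test).
#' @return an \code{fst_result}: per_locus data.frame (locus, theta, a,
#'   abc), theta (multi-locus), p_value, n_perm.
#' @export
fst_wc <- function(genotypes, strata, n_perm = 10100) {
  stopifnot(length(strata) == 2)
  g <- genotypes[genotypes$stratum %in% strata &
                   !is.na(genotypes$allele1) & !is.na(genotypes$allele2), ,
                 drop = FALSE]
  loci <- unique(g$locus)
  # precompute per locus: integer allele codes per individual
  prep <- lapply(loci, function(lc) {
    gl <- g[g$locus == lc, , drop = FALSE]
    al <- sort(unique(c(gl$allele1, gl$allele2)))
    if (length(al) < 2) return(NULL)              # monomorphic: excluded
    list(locus = lc, k = length(al),
         a1 = match(gl$allele1, al), a2 = match(gl$allele2, al),
         stratum = match(gl$stratum, strata))
  })
  prep <- Filter(Negate(is.null), prep)
  if (!length(prep)) stop("no polymorphic locus shared by both strata")
  for (pp in prep) {
    if (min(tabulate(pp$stratum, 2)) < 2) {
      stop("both strata need >= 2 genotyped individuals at locus ", pp$locus)
    }
  }

  components <- function(pp, stratum) {
    n_i <- tabulate(stratum, 2)
    r <- 2
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    abc <- vapply(seq_len(pp$k), function(al) {
      cnt1 <- (pp$a1 == al) + (pp$a2 == al)        # copies per individual
      het <- (pp$a1 == al) != (pp$a2 == al)
      p_i <- vapply(1:2, function(s) sum(cnt1[stratum == s]) / (2 * n_i[s]), 0)
      h_i <- vapply(1:2, function(s) mean(het[stratum == s]), 0)
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      c(a, a + b + cc)
    }, c(0, 0))
    c(a = sum(abc[1, ]), abc = sum(abc[2, ]))
  }

  theta_of <- function(assignments) {
    comp <- vapply(seq_along(prep), function(ix) {
      components(prep[[ix]], assignments[[ix]])
    }, c(a = 0, abc = 0))
    sum(comp["a", ]) / sum(comp["abc", ])
  }

  obs_assign <- lapply(prep, `[[`, "stratum")
  theta_obs <- theta_of(obs_assign)
  per_locus <- do.call(rbind, lapply(seq_along(prep), function(ix) {
    cmp <- components(prep[[ix]], prep[[ix]]$stratum)
    data.frame(locus = prep[[ix]]$locus, theta = cmp[["a"]] / cmp[["abc"]],
               a = cmp[["a"]], abc = cmp[["abc"]], stringsAsFactors = FALSE)
  }))

  p <- NA_real_
  if (n_perm > 0) {
    ge <- sum(vapply(seq_len(n_perm), function(it) {
      perm <- lapply(obs_assign, sample)
      theta_of(perm) >= theta_obs
    }, TRUE))
    p <- ge / n_perm
  }
  structure(list(per_locus = per_locus, theta = theta_obs, p_value = p,
                 n_perm = n_perm), class = "fst_result")
}

#' Allelic representation per stratum
#'
#' Percentage of the distinct alleles in the catalogue (all loci of the
#' table pooled) with a nonzero count in each stratum, rounded to whole
#' percent.
#'
#' @param pop_table a \code{population_table}.
#' @return named integer vector of percentages per stratum column.
#' @export
allelic_representation <- function(pop_table) {
  strata <- setdiff(names(pop_table), c("locus", "allele"))
  total <- nrow(pop_table)
  if (!total) stop("empty catalogue")
  out <- vapply(strata, function(s) {
    as.integer(round(100 * sum(pop_table[[s]] > 0) / total))
  }, 0L)
  out
}
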