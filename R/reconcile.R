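#' Cluster reads by their bases at candidate variant sites
#'
#' @param pileup a \code{site_pileup}.
#' @param sites0 0-based candidate variant positions.
#' @return a \code{haplotype_clusters} list: sites, patterns (descending
#'   count), counts, and the per-read pattern vector.
#' @export
haplotype_clusters <- function(pileup, sites0) {
  if (!length(sites0) || pileup$n_reads == 0) {
    return(structure(list(sites = sites0, patterns = character(0),
                          counts = integer(0), read_pattern = character(0)),
                     class = "haplotype_clusters"))
  }
  sub <- pileup$bases[, sites0 + 1L, drop = FALSE]
  pat <- apply(sub, 1, paste, collapse = "")
  tab <- sort(table(pat), decreasing = TRUE)
  structure(list(sites = sites0,
                 patterns = names(tab),
                 counts = as.integer(tab),
                 read_pattern = pat), class = "haplotype_clusters")
}

#' Test dominant haplotype clusters for single-crossover chimerism
#'
#' With the two largest clusters as parents A and B, any further cluster is
#' chimeric iff some crossover index k makes its variant-site pattern equal
#' A's pattern before k and B's pattern at/after k (either parent order).
#' Fewer than two variant sites make chimerism undetectable
#' ("indeterminate"); fewer than three clusters yield no verdicts.
#'
#' @param clusters a [haplotype_clusters()] result, already restricted to
#'   dominant clusters (each holding at least ~5% of reads).
#' @return data.frame pattern, count, verdict
#'   ("chimeric" | "negative" | "indeterminate"), crossover (1-based index
#'   of the first position taken from the second parent, NA otherwise).
#' @export
detect_chimeric_haplotypes <- function(clusters) {
  k <- length(clusters$patterns)
  if (k < 3) {
    return(data.frame(pattern = character(0), count = integer(0),
                      verdict = character(0), crossover = integer(0),
                      stringsAsFactors = FALSE))
  }
  nsites <- nchar(clusters$patterns[1])
  A <- strsplit(clusters$patterns[1], "", fixed = TRUE)[[1]]
  B <- strsplit(clusters$patterns[2], "", fixed = TRUE)[[1]]
  out <- lapply(3:k, function(i) {
    C <- strsplit(clusters$patterns[i], "", fixed = TRUE)[[1]]
    if (nsites < 2) {
      return(data.frame(pattern = clusters$patterns[i],
                        count = clusters$counts[i],
                        verdict = "indeterminate", crossover = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    verdict <- "negative"; xk <- NA_integer_
    for (kk in 2:nsites) {       # first position drawn from the second parent
      left <- seq_len(kk - 1L); right <- kk:nsites
      if ((all(C[left] == A[left]) && all(C[right] == B[right])) ||
          (all(C[left] == B[left]) && all(C[right] == A[right]))) {
        verdict <- "chimeric"; xk <- kk; break
      }
    }
    data.frame(pattern = clusters$patterns[i], count = clusters$counts[i],
               verdict = verdict, crossover = xk, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# fraction of dominantly-clustered reads whose pattern carries `base` at
# variant-site index `site_idx`
.cluster_base_support <- function(clusters, site_idx, base, dominant_n) {
  if (!length(clusters$patterns) || is.na(site_idx)) return(0)
  dom <- clusters$counts >= dominant_n
  if (!any(dom)) return(0)
  has <- substr(clusters$patterns[dom], site_idx, site_idx) == base
  sum(clusters$counts[dom][has]) / sum(clusters$counts[dom])
}

#' Reconcile ratio-caller and likelihood-caller variant calls
#'
#' Concordant calls pass through. Disagreements are classified through an
#' evidence-based error taxonomy and resolved:
#' \itemize{
#'   \item \code{sequencing_error}: a likelihood-only variant whose extra
#'     base falls below the het band and has no dominant-cluster support is
#'     rejected in favour of the ratio call.
#'   \item \code{tri_allelic}: both-non-reference genotypes are accepted
#'     from the likelihood caller when both bases have het-band support.
#'   \item \code{homopolymer}: in homopolymer context the
#'     fraction-consistent (ratio) call is accepted when its minor fraction
#'     is consistent on both strands.
#'   \item Sites where no rule fires are flagged for manual review and the
#'     sample is not genotyped there.
#' }
#' Chimera removal and strand-bias masking happen upstream in
#' [call_sample()]; their classes are recorded there.
#'
#' @param ratio_calls,likelihood_calls outputs of the two callers over the
#'   same pileup.
#' @param pileup the \code{site_pileup} both callers saw.
#' @param clusters optional [haplotype_clusters()] for cluster-support
#'   checks.
#' @param params [caller_params()].
#' @return list: \code{calls} (final genotypes with status
#'   "concordant" | "reconciled:<class>") and \code{review} (sites flagged
#'   rejected:<class> or manual_review, not genotyped).
#' @export
reconcile_calls <- function(ratio_calls, likelihood_calls, pileup,
                            clusters = NULL, params = caller_params()) {
  cnt <- pileup$counts_fwd + pileup$counts_rev
  dominant_n <- ceiling(params$dominant_frac * max(pileup$n_reads, 1))
  geno_key <- function(df) ifelse(is.na(df$a1), NA, paste(df$a1, df$a2))
  rk <- stats::setNames(geno_key(ratio_calls), ratio_calls$pos)
  lk <- stats::setNames(geno_key(likelihood_calls), likelihood_calls$pos)
  positions <- sort(unique(c(ratio_calls$pos, likelihood_calls$pos)))

  final <- list(); review <- list()
  add_final <- function(pos, ref, g, caller, qual, status) {
    final[[length(final) + 1]] <<- data.frame(
      pos = pos, ref = ref, a1 = g[1], a2 = g[2], caller = caller,
      qual = qual, status = status, stringsAsFactors = FALSE)
  }
  add_review <- function(pos, ref, status) {
    review[[length(review) + 1]] <<- data.frame(
      pos = pos, ref = ref, status = status, stringsAsFactors = FALSE)
  }

  frac_of <- function(pos, base) {
    n <- cnt[, pos + 1L]
    d <- sum(n)
    if (d == 0) 0 else n[match(base, DNA_BASES)] / d
  }
  strand_consistent <- function(pos, base) {
    nf <- pileup$counts_fwd[, pos + 1L]; nr <- pileup$counts_rev[, pos + 1L]
    df <- sum(nf); dr <- sum(nr)
    ff <- if (df > 0) nf[match(base, DNA_BASES)] / df else NA
    fr <- if (dr > 0) nr[match(base, DNA_BASES)] / dr else NA
    # fraction-consistent on both strands: present well above error level
    # on each strand that has coverage
    all(stats::na.omit(c(ff, fr)) >= params$min_minor_frac / 2)
  }

  for (p in positions) {
    r_row <- ratio_calls[ratio_calls$pos == p, , drop = FALSE]
    l_row <- likelihood_calls[likelihood_calls$pos == p, , drop = FALSE]
    r_g <- if (nrow(r_row)) rk[[as.character(p)]] else NULL
    l_g <- if (nrow(l_row)) lk[[as.character(p)]] else NULL
    ref <- if (nrow(r_row)) r_row$ref[1] else l_row$ref[1]

    r_valid <- !is.null(r_g) && !is.na(r_g)
    l_valid <- !is.null(l_g) && !is.na(l_g)

    if (r_valid && l_valid && r_g == l_g) {
      g <- c(r_row$a1, r_row$a2)
      add_final(p, ref, g, "both", max(r_row$qual, l_row$qual), "concordant")
      next
    }

    # likelihood-only (or conflicting) variant; the baseline the extra
    # bases are judged against is the ratio call, or the reference when
    # the ratio caller saw a homozygous-reference site
    if (l_valid) {
      g <- c(l_row$a1, l_row$a2)
      extra <- setdiff(unique(g), if (r_valid) c(r_row$a1, r_row$a2) else ref)
      nonref <- unique(g[g != ref])
      both_nonref <- length(nonref) == 2

      if (both_nonref && all(vapply(nonref, function(b)
            frac_of(p, b) >= params$min_minor_frac, TRUE))) {
        add_final(p, ref, g, "likelihood", l_row$qual, "reconciled:tri_allelic")
        next
      }
      low_extra <- length(extra) &&
        all(vapply(extra, function(b) frac_of(p, b) < params$min_minor_frac, TRUE))
      site_idx <- if (!is.null(clusters)) match(p, clusters$sites) else NA
      no_cluster <- !length(extra) || all(vapply(extra, function(b)
        .cluster_base_support(clusters, site_idx, b, dominant_n) == 0, TRUE))
      if (low_extra && no_cluster) {
        if (r_valid) {
          add_final(p, ref, c(r_row$a1, r_row$a2), "ratio", r_row$qual,
                    "reconciled:sequencing_error")
        } else {
          add_review(p, ref, "rejected:sequencing_error")
        }
        next
      }
    }

    # ratio-only call (likelihood absent or suppressed)
    if (r_valid && !l_valid) {
      g <- c(r_row$a1, r_row$a2)
      var_bases <- unique(g[g != ref])
      consistent <- all(vapply(var_bases, function(b) strand_consistent(p, b), TRUE))
      if (pileup$hp_context[p + 1L] && consistent) {
        add_final(p, ref, g, "ratio", r_row$qual, "reconciled:homopolymer")
        next
      }
      if (consistent) {
        add_final(p, ref, g, "ratio", r_row$qual, "reconciled:ratio_only")
        next
      }
      add_review(p, ref, "manual_review")
      next
    }

    if (r_valid && l_valid) {   # both confident but different, no rule fired
      add_review(p, ref, "manual_review")
      next
    }
    # only flags/no-calls at this site: nothing to genotype
    flagged <- c(if (nrow(r_row)) r_row$flag, if (nrow(l_row)) l_row$flag)
    if (any(flagged == "ratio_distortion")) add_review(p, ref, "manual_review")
  }

  calls <- if (length(final)) do.call(rbind, final) else
    data.frame(pos = integer(0), ref = character(0), a1 = character(0),
               a2 = character(0), caller = character(0), qual = numeric(0),
               status = character(0), stringsAsFactors = FALSE)
  review <- if (length(review)) do.call(rbind, review) else
    data.frame(pos = integer(0), ref = character(0), status = character(0),
               stringsAsFactors = FALSE)
  list(calls = calls, review = review)
}
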