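# brute-force NG86 oracle: enumerate mutation orders explicitly
oracle_path_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  perms <- if (length(dpos) == 1) matrix(dpos) else
    t(do.call(rbind, combinat_perms(dpos)))
  res <- matrix(0, nrow = 3, ncol = ncol(perms))
  for (pi in seq_len(ncol(perms))) {
    cur <- b1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perms[, pi]) {
      nxt <- cur; nxt[p] <- b2[p]
      if (gc[[paste(nxt, collapse = "")]] == "*") blocked <- TRUE
      if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[, pi] <- c(sd, nd, blocked)
  }
  open <- res[3, ] == 0
  if (any(open)) res <- res[, open, drop = FALSE]
  c(sd = mean(res[1, ]), nd = mean(res[2, ]))
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}
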