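# independent sliding-window oracle for motif scanning
oracle_scan <- function(sequence, consensus, max_mm) {
  L <- nchar(sequence); m <- nchar(consensus)
  hits <- integer(0)
  if (m > L) return(hits)
  for (s in 0:(L - m)) {
    win <- substr(sequence, s + 1, s + m)
    mm <- sum(strsplit(win, "")[[1]] != strsplit(consensus, "")[[1]])
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

test_that("motif scanning finds planted motifs and respects thresholds", {
  defs <- load_motif_defs("DQA")
  ybox <- defs$consensus[defs$motif == "Y"]
  set.seed(231)
  seq <- paste0(random_dna(40), ybox, random_dna(60))
  hits <- scan_motifs(seq, defs[defs$motif == "Y", ])
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40)
  expect_equal(hits$mismatches, 0)

  # duplicated T-box: two separate hits
  tbox <- defs$consensus[defs$motif == "T"]
  seq2 <- paste0(random_dna(20), tbox, "ACGT", tbox, random_dna(30))
  hits2 <- scan_motifs(seq2, defs[defs$motif == "T", ])
  expect_equal(nrow(hits2), 2)
  expect_equal(hits2$start, c(20, 20 + nchar(tbox) + 4))

  # too many mismatches: no hit
  broken <- ybox
  substr(broken, 1, 3) <- "NNN"
  seq3 <- paste0(random_dna(40), broken, random_dna(40))
  seq3 <- gsub("N", "A", seq3)   # keep alphabet clean; 3 mismatches vs Y box
  hits3 <- scan_motifs(seq3, defs[defs$motif == "Y", ])
  expect_true(all(hits3$start != 40) || nrow(hits3) == 0)
})

test_that("scanning is position-complete against the sliding-window oracle", {
  set.seed(241)
  for (i in 1:25) {
    seq <- random_dna(150)
    cons <- random_dna(sample(6:12, 1))
    defs <- data.frame(locus = "X", motif = "m", consensus = cons,
                       window_start = NA, window_end = NA,
                       max_mm = sample(0:3, 1), stringsAsFactors = FALSE)
    got <- scan_motifs(seq, defs)$start
    want <- oracle_scan(seq, cons, defs$max_mm)
    expect_equal(got, want)
  }
})

test_that("tandem duplications: printed unit cases are recovered", {
  unit <- "TCATCTAATGA"                       # 11 bp, three copies
  set.seed(251)
  # boundary characters around the copies are pairwise distinct so the
  # repeated unit cannot be extended into the spacers
  seq <- paste0(random_dna(24), "A", unit, "GATTC", unit, "CCAGTAAGG", unit,
                "T", random_dna(24))
  rep1 <- detect_tandem_duplications(seq)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$unit, unit)
  expect_equal(rep1$unit_length, 11)
  expect_equal(rep1$copies, 3)
  expect_equal(rep1$spacers, "5,9")

  # duplicated 14-bp T-box with net 18 bp insertion vs the unduplicated
  # homolog: the second copy replaced part of the spacer
  tbox <- "TCATCTAATGACCA"                    # 14 bp
  left <- paste0(random_dna(29), "G"); right <- random_dna(30)
  homolog <- paste0(left, tbox, "ACGTTGCAAG", right)          # one T-box
  # duplication inserted the 14 bp T-box plus 4 bp while replacing/extending
  # the 10 bp spacer: net insertion 18 bp
  dup <- paste0(left, tbox, "ACGT", tbox, "TGCAAGGTAC", right)
  expect_equal(nchar(dup) - nchar(homolog), 18)
  rep2 <- detect_tandem_duplications(dup, reference = homolog)
  row <- rep2[rep2$unit == tbox, ]
  expect_equal(row$unit_length, 14)
  expect_equal(row$copies, 2)
  expect_equal(row$net_insertion, 18)
})

test_that("repeat-free random sequences yield no duplication reports", {
  set.seed(261)
  # independent brute-force repeat checker
  has_repeat <- function(seq, min_unit = 11, max_spacer = 30) {
    L <- nchar(seq)
    for (s in 0:(L - 2 * min_unit)) {
      unit <- substr(seq, s + 1, s + min_unit)
      lim <- min(L - min_unit, s + min_unit + max_spacer)
      for (t in (s + min_unit):lim) {
        if (substr(seq, t + 1, t + min_unit) == unit) return(TRUE)
      }
    }
    FALSE
  }
  n_checked <- 0; fp <- 0
  for (i in 1:400) {
    seq <- random_dna(200)
    if (has_repeat(seq)) next
    n_checked <- n_checked + 1
    if (nrow(detect_tandem_duplications(seq)) > 0) fp <- fp + 1
  }
  expect_gt(n_checked, 350)
  expect_equal(fp, 0)
})

test_that("planted repeats are recovered with unit, copy count and positions", {
  set.seed(271)
  for (i in 1:30) {
    u_len <- sample(11:22, 1)
    unit <- random_dna(u_len)
    copies <- sample(2:3, 1)
    sp_len <- sample(2:30, 2, replace = TRUE)
    # boundary characters around each copy are pairwise distinct so the
    # planted unit cannot be accidentally extended left or right
    sp1 <- paste0("A", substr(random_dna(30), 1, sp_len[1] - 2), "T")
    sp2 <- paste0("C", substr(random_dna(30), 1, sp_len[2] - 2), "C")
    prefix <- paste0(random_dna(39), "G")
    suffix <- paste0("G", random_dna(39))
    spacers <- c(nchar(sp1), nchar(sp2))[seq_len(copies - 1)]
    parts <- prefix
    starts <- integer(0)
    pos <- 40
    for (cpy in seq_len(copies)) {
      starts <- c(starts, pos)
      parts <- paste0(parts, unit)
      pos <- pos + u_len
      if (cpy < copies) {
        sp <- if (cpy == 1) sp1 else sp2
        parts <- paste0(parts, sp)
        pos <- pos + nchar(sp)
      }
    }
    seq <- paste0(parts, suffix)
    rep <- detect_tandem_duplications(seq)
    row <- rep[rep$unit == unit, ]
    expect_equal(nrow(row), 1, info = paste("iter", i))
    expect_equal(row$copies, copies)
    expect_equal(as.integer(strsplit(row$starts, ",")[[1]]), starts)
  }
})

test_that("column entropy matches hand values and bounds", {
  prof <- column_entropy(c("AAAA", "AAAC", "AACC", "ACCC"))
  # column 1: all A -> 0; column 4: 1 A / 3 C
  expect_equal(prof$H[1], 0)
  expect_equal(prof$H[2], -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4))

  p2 <- column_entropy(c("A", "C"))
  expect_equal(p2$H, 1)

  p3 <- column_entropy(c("A", "A", "C", "G"))
  expect_equal(p3$H, 1.5)

  # gap handling
  pg <- column_entropy(c("A", "-", "-", "A"), gap_mode = "exclude")
  expect_equal(pg$H, 0)
  expect_equal(pg$coverage, 0.5)
  pg5 <- column_entropy(c("A", "-", "-", "A"), gap_mode = "fifth_state")
  expect_equal(pg5$H, 1)
  pall <- column_entropy(c("-", "-"), gap_mode = "exclude")
  expect_true(is.na(pall$H))

  # bounds and mixing monotonicity
  set.seed(281)
  for (i in 1:30) {
    col <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    H <- column_entropy(paste(col))$H
    expect_lte(H, 2)
    # replace one majority base by the rarest base: H must not decrease
    tab <- sort(table(col))
    if (length(tab) >= 2 && max(tab) >= min(tab) + 2) {
      maj <- names(tab)[length(tab)]; mino <- names(tab)[1]
      col2 <- col
      col2[which(col2 == maj)[1]] <- mino
      H2 <- column_entropy(paste(col2))$H
      expect_gte(H2 + 1e-12, H)
    }
  }
})
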