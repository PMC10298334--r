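# small synthetic alignments with known structure

make_aln <- function(nGroups = 3, members = 2, ncol = 300, diagCols = 150,
                     noiseRate = 0, flankFree = NULL) {
  anc <- sample(c("A", "C", "G", "T"), ncol, TRUE)
  rows <- list(); groups <- character(0)
  for (g in seq_len(nGroups)) {
    cons <- anc
    for (k in seq_along(diagCols)) {
      bases <- c("A", "C", "G", "T")
      cons[diagCols[k]] <- bases[(g + k - 1) %% 4 + 1]
    }
    for (m in seq_len(members)) {
      id <- sprintf("G%d_m%d", g, m)
      r <- cons
      if (noiseRate > 0) {
        hit <- which(runif(ncol) < noiseRate)
        if (!is.null(flankFree)) hit <- setdiff(hit, flankFree)
        for (i in hit) r[i] <- sample(setdiff(c("A","C","G","T"), r[i]), 1)
      }
      rows[[id]] <- r
      groups[id] <- sprintf("G%d", g)
    }
  }
  list(aln = do.call(rbind, rows), groups = groups)
}

test_that("groups identical everywhere yield no candidates, with tallies", {
  set.seed(101)
  x <- make_aln(nGroups = 2, diagCols = integer(0))
  got <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 80,
                               flankLen = 18)
  expect_equal(nrow(got), 0L)
  tally <- attr(got, "failure_tally")
  expect_gt(tally[["no_pair_separation"]], 0)
})

test_that("a planted diagnostic SNP is recovered by exactly the right windows", {
  set.seed(103)
  x <- make_aln(nGroups = 2, ncol = 500, diagCols = 250)
  got <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 70,
                               flankLen = 20, maxFlankMismatch = 0)
  # every returned window must strictly contain column 250 in its interior
  expect_gt(nrow(got), 0)
  expect_true(all(got$start + 20 <= 250 & got$end - 20 >= 250))
  expect_true(all(got$n_diagnostic == 1))
  # and the full set matches the brute-force enumeration
  want <- brute_windows(x$aln, x$groups, 60, 70, 20, 0)
  key <- function(d) paste(d$start, d$end)
  expect_setequal(key(got), key(want))
})

test_that("scan agrees with the brute-force validator on noisy alignments", {
  set.seed(107)
  for (rep in 1:6) {
    x <- make_aln(nGroups = 3, members = 2, ncol = 220,
                  diagCols = c(100, 120), noiseRate = 0.01)
    got <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 75,
                                 flankLen = 15, maxFlankMismatch = 1)
    want <- brute_windows(x$aln, x$groups, 60, 75, 15, 1)
    key <- function(d) paste(d$start, d$end)
    expect_setequal(key(got), key(want))
  }
})

test_that("tightening constraints never adds candidates", {
  set.seed(109)
  x <- make_aln(nGroups = 3, members = 2, ncol = 260,
                diagCols = c(120, 140), noiseRate = 0.008)
  key <- function(d) paste(d$start, d$end)
  broad <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 90,
                                 flankLen = 15, maxFlankMismatch = 2)
  narrow <- scanDiagnosticWindows(x$aln, x$groups, minLen = 65, maxLen = 80,
                                  flankLen = 15, maxFlankMismatch = 2)
  strict <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 90,
                                  flankLen = 15, maxFlankMismatch = 0)
  expect_true(all(key(narrow) %in% key(broad)))
  expect_true(all(key(strict) %in% key(broad)))
})

test_that("primer proposals read the flank consensus with IUPAC degeneracy", {
  set.seed(113)
  x <- make_aln(nGroups = 2, ncol = 200, diagCols = 100)
  cand <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 60,
                                flankLen = 18, maxFlankMismatch = 0)
  cand <- cand[1, ]
  pp <- proposePrimerPairs(cand, x$aln, flankLen = 18,
                           tmRange = c(30, 90), maxTmDiff = 50)
  expect_equal(nrow(pp), 1L)
  expect_true(grepl("^[ACGT]+$", pp$fwd))      # conserved flank: concrete
  expect_equal(pp$fwd, paste(x$aln[1, cand$start:(cand$start + 17)],
                             collapse = ""))
  # one variable flank column becomes an ambiguity code
  aln2 <- x$aln
  aln2[1, cand$start + 3] <- "A"; aln2[2, cand$start + 3] <- "A"
  aln2[3, cand$start + 3] <- "G"; aln2[4, cand$start + 3] <- "G"
  pp2 <- proposePrimerPairs(cand, aln2, flankLen = 18,
                            tmRange = c(30, 90), maxTmDiff = 50)
  expect_equal(substr(pp2$fwd, 4, 4), "R")
  # heavily degenerate flanks are rejected with a reason
  aln3 <- x$aln
  for (k in 0:4) aln3[1, cand$start + k] <- "T"
  for (k in 0:4) aln3[2, cand$start + k] <- "G"
  pp3 <- proposePrimerPairs(cand, aln3, flankLen = 18,
                            tmRange = c(30, 90), maxTmDiff = 50)
  expect_equal(nrow(pp3), 0L)
  expect_match(attr(pp3, "reason"), "degenerate")
})

test_that("separation prediction tracks identity, dTm sign and indels", {
  set.seed(127)
  x <- make_aln(nGroups = 2, ncol = 200, diagCols = integer(0))
  # plant a single A -> G difference (GC gain in group 2)
  x$aln[c(3, 4), 100] <- "G"; x$aln[c(1, 2), 100] <- "A"
  cand <- data.frame(start = 60, end = 172)
  sep <- predictAssaySeparation(cand, x$aln, x$groups)
  expect_equal(nrow(sep), 1L)
  expect_lt(sep$identity_percent, 100)
  expect_gt(sep$delta_tm, 0)
  expect_false(sep$has_indel)

  # identical consensus: identity 100, dTm 0, not separable
  y <- make_aln(nGroups = 2, ncol = 200, diagCols = integer(0))
  sep2 <- predictAssaySeparation(data.frame(start = 60, end = 172),
                                 y$aln, y$groups)
  expect_equal(sep2$identity_percent, 100)
  expect_equal(sep2$delta_tm, 0)
  expect_false(sep2$separable)

  # a one-base insertion in one group is handled and flagged
  z <- make_aln(nGroups = 2, ncol = 200, diagCols = 100)
  zal <- cbind(z$aln[, 1:110, drop = FALSE],
               ifelse(grepl("^G2", rownames(z$aln)), "A", "-"),
               z$aln[, 111:200, drop = FALSE])
  sep3 <- predictAssaySeparation(data.frame(start = 60, end = 173),
                                 zal, z$groups)
  expect_true(sep3$has_indel)
})

test_that("planted markers are recovered across seeded replicates", {
  set.seed(131)
  hits <- 0L
  for (rep in 1:10) {
    x <- make_aln(nGroups = 3, members = 2, ncol = 250,
                  diagCols = c(118, 126), noiseRate = 0.015,
                  flankFree = 80:170)
    got <- scanDiagnosticWindows(x$aln, x$groups, minLen = 60, maxLen = 80,
                                 flankLen = 15, maxFlankMismatch = 1)
    if (nrow(got) && got$start[1] + 15 <= 118 && got$end[1] - 15 >= 126)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
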