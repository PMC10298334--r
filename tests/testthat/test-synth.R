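test_that("panels are bit-identical under a seed and differ across seeds", {
  p1 <- simulateReferencePanel(seed = 42)
  p2 <- simulateReferencePanel(seed = 42)
  p3 <- simulateReferencePanel(seed = 43)
  expect_identical(as.character(refSequences(p1)),
                   as.character(refSequences(p2)))
  expect_identical(refAlignment(p1), refAlignment(p2))
  expect_false(identical(as.character(refSequences(p1)),
                         as.character(refSequences(p3))))
})

test_that("zero intra-group divergence makes group members identical", {
  p <- simulateReferencePanel(intraDivergence = 0, seed = 7)
  seqs <- as.character(refSequences(p))
  for (g in unique(refGroups(p))) {
    members <- seqs[names(refGroups(p))[refGroups(p) == g]]
    expect_length(unique(members), 1L)
  }
})

test_that("divergence rates are realized near their targets", {
  p <- simulateReferencePanel(nGroups = 4, membersPerGroup = 4,
                              seqLen = 2000, interDivergence = 0.05,
                              intraDivergence = 0.01, markerStart = 900,
                              seed = 19)
  aln <- refAlignment(p)
  # intra: member vs member of the same group, outside the marker window
  out <- setdiff(seq_len(ncol(aln)), p@marker$start:p@marker$end)
  d12 <- mean(aln["G1_m1", out] != aln["G1_m2", out])
  # two draws at rate r differ at ~2r(1 - 4r/3) of sites; just band it
  expect_gt(d12, 0.005); expect_lt(d12, 0.05)
  dAB <- mean(aln["G1_m1", out] != aln["G2_m1", out])
  expect_gt(dAB, 0.05); expect_lt(dAB, 0.20)
  expect_error(simulateReferencePanel(interDivergence = 0.6), "0.5")
})

test_that("the planted marker window is recovered by the scanner", {
  p <- simulateReferencePanel(seed = 23)
  mk <- markerWindow(p)
  got <- scanDiagnosticWindows(refAlignment(p), refGroups(p),
                               minLen = 100, maxLen = 120,
                               flankLen = mk$flankLen, maxFlankMismatch = 0)
  expect_gt(nrow(got), 0)
  top <- got[1, ]
  expect_lte(top$start, mk$start + mk$flankLen)
  expect_gte(top$end, mk$end - mk$flankLen)
  # every diagnostic ladder column lies inside the top window's interior
  mkCols <- mk$diagnosticColumns
  expect_true(all(mkCols > top$start & mkCols < top$end))
})

test_that("noiseless flat-baseline curves equal the thermodynamic model", {
  p <- simulateReferencePanel(seed = 29)
  mc <- simulateMeltCurveSet(p, replicates = 1, noiseSd = 0,
                             flatBaseline = TRUE, seed = 29)
  id <- names(refSequences(p))[1]
  mk <- markerWindow(p)
  row <- refAlignment(p)[id, mk$start:mk$end]
  amp <- paste(row[row != "-"], collapse = "")
  want <- curveValues(simulateMeltCurve(amp))[, 1]
  expect_equal(unname(curveValues(mc)[, paste0(id, "_r1")]), want)
})

test_that("the default plate is 6 groups x 3 members x 3 replicates", {
  p <- simulateReferencePanel(seed = 31)
  mc <- simulateMeltCurveSet(p, seed = 31)
  expect_equal(length(sampleIds(mc)), 54L)
  expect_length(temperatures(mc), 151L)
  expect_equal(sort(unique(as.character(mc@sampleData$group))),
               sprintf("G%d", 1:6))
})

test_that("clustering a default simulated plate recovers the planted groups", {
  p <- simulateReferencePanel(seed = 37)
  mc <- simulateMeltCurveSet(p, seed = 37)
  nc <- normalizeCurves(mc)
  truth <- setNames(as.character(mc@sampleData$group), sampleIds(mc))
  cl <- clusterCurves(nc, HRMConfig(), truth)
  lab <- clusterLabels(cl)
  # exact recovery: the label partition coincides with the group partition
  expect_equal(length(unique(lab)), 6L)
  for (g in unique(truth))
    expect_length(unique(lab[names(truth)[truth == g]]), 1L)
  expect_true(all(clusterConfidence(cl)[cbind(seq_along(lab), lab)] > 95))
})

test_that("group amplicons form a Tm ladder with comfortable spacing", {
  p <- simulateReferencePanel(seed = 41)
  mk <- markerWindow(p)
  tms <- vapply(sprintf("G%d_m1", 1:6), function(id) {
    row <- refAlignment(p)[id, mk$start:mk$end]
    amp <- paste(row[row != "-"], collapse = "")
    mc <- simulateMeltCurve(amp)
    v <- curveValues(mc)[, 1]; tt <- temperatures(mc)
    i <- max(which(v >= 50))
    tt[i] + (v[i] - 50) / (v[i] - v[i + 1]) * (tt[i + 1] - tt[i])
  }, numeric(1))
  expect_true(all(diff(sort(tms)) >= 0.4))
})

test_that("the market survey plants mislabeling at the requested rate", {
  p <- simulateReferencePanel(seed = 43)
  s0 <- simulateMarketSurvey(p, nSamples = 30, mislabelRate = 0, seed = 5)
  expect_false(any(s0$samples$mislabeled))
  expect_true(all(s0$samples$true_group == s0$samples$declared_group))
  s1 <- simulateMarketSurvey(p, nSamples = 30, mislabelRate = 1, seed = 5)
  expect_true(all(s1$samples$mislabeled))
  expect_true(all(s1$samples$true_group != s1$samples$declared_group))
  sA <- simulateMarketSurvey(p, nSamples = 100, mislabelRate = 0.3, seed = 9)
  sB <- simulateMarketSurvey(p, nSamples = 100, mislabelRate = 0.3, seed = 9)
  expect_identical(sA$samples, sB$samples)
  expect_gt(sum(sA$samples$mislabeled), 10)
  expect_lt(sum(sA$samples$mislabeled), 50)
})

test_that("an indel group yields a gap column and shifted amplicon length", {
  p <- simulateReferencePanel(indelGroup = 2, seed = 47)
  aln <- refAlignment(p)
  gapCols <- which(colSums(aln == "-") > 0)
  expect_length(gapCols, 1L)
  mk <- markerWindow(p)
  lenOf <- function(id) {
    row <- aln[id, mk$start:mk$end]
    sum(row != "-")
  }
  expect_equal(lenOf("G2_m1") - lenOf("G1_m1"), 1L)
})
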