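# curves here are built directly from the two-state formula in the helper,
# independent of the thermo module

make_set <- function(tms, noise = 0, baselined = FALSE, reps = 1,
                     prefix = "s") {
  temps <- seq(65, 95, by = 0.2)
  cols <- list()
  for (i in seq_along(tms)) for (r in seq_len(reps)) {
    b <- if (baselined) c(runif(1, 8, 15), runif(1, -0.15, -0.05)) else c(0, 0)
    cols[[sprintf("%s%02d_r%d", prefix, i, r)]] <-
      synth_curve(tms[i], temps, noise = noise, baseline = b)
  }
  MeltCurveSet(temps, do.call(cbind, cols))
}

test_that("normalization rescales plateaus to 100/0 and recovers Tm", {
  mc <- make_set(80.0)
  nc <- normalizeCurves(mc)
  v <- curveValues(nc)[, 1]
  tt <- temperatures(nc)
  expect_equal(mean(v[tt <= 68]), 100, tolerance = 1e-6)
  expect_equal(mean(v[tt >= 92]), 0, tolerance = 1e-6)
  expect_equal(unname(tmEstimates(nc)), 80.0, tolerance = 0.1)
})

test_that("normalization strips a linear baseline and is idempotent", {
  set.seed(83)
  mc <- make_set(c(80, 81), baselined = TRUE)
  nc <- normalizeCurves(mc)
  expect_equal(unname(tmEstimates(nc)), c(80, 81), tolerance = 0.1)
  # renormalizing an already-normalized set changes nothing (flat baselines)
  mc2 <- MeltCurveSet(temperatures(nc), pmax(curveValues(nc), 0))
  nc2 <- normalizeCurves(mc2)
  expect_equal(curveValues(nc2), pmax(curveValues(nc), 0), tolerance = 1e-6)
})

test_that("normalization arithmetic matches a hand-computed small case", {
  # 8-point grid; baselines fitted on the first and last two points
  t <- seq(1, 8)
  f <- c(100, 98, 90, 60, 30, 10, 4, 2)
  cfg <- HRMConfig(preMeltWindow = c(1, 2), postMeltWindow = c(7, 8),
                   grid = c(1, 8, 1))
  nc <- normalizeCurves(MeltCurveSet(t, matrix(f, ncol = 1,
                                               dimnames = list(NULL, "x"))),
                        cfg)
  # upper(T) = 102 - 2T (through (1,100),(2,98)); lower(T) = 18 - 2T
  upper <- 102 - 2 * t; lower <- 18 - 2 * t
  expect_equal(curveValues(nc)[, 1], 100 * (f - lower) / (upper - lower),
               tolerance = 1e-9)
})

test_that("degenerate baselines error; crossing-less curves cluster by shape", {
  t <- seq(65, 95, by = 0.2)
  rising <- matrix(seq(0, 100, length.out = length(t)), ncol = 1,
                   dimnames = list(NULL, "r"))
  flat <- matrix(rep(50, length(t)), ncol = 1, dimnames = list(NULL, "f"))
  expect_error(normalizeCurves(MeltCurveSet(t, rising)), "degenerate")
  expect_error(normalizeCurves(MeltCurveSet(t, flat)), "degenerate")
  # a flagged crossing-less curve is pooled into a shape-only cluster
  nc <- normalizeCurves(make_set(c(80, 80, 81)))
  odd <- matrix(rep(75, length(temperatures(nc))), ncol = 1,
                dimnames = list(NULL, "odd"))
  comb <- new("NormalizedCurveSet", temperature = temperatures(nc),
              values = cbind(curveValues(nc), odd),
              tmEst = c(tmEstimates(nc), odd = NA_real_),
              noCrossing = c(nc@noCrossing, odd = TRUE), sampleData = NULL)
  cl <- clusterCurves(comb)
  expect_equal(cl@shapeOnly, "odd")
  expect_true(is.na(cl@clusterTm[clusterLabels(cl)[["odd"]]]))
})

test_that("difference curves vanish for the reference and scale with dTm", {
  mc <- make_set(c(80, 80, 80.5))
  nc <- normalizeCurves(mc)
  d <- differenceCurves(nc, sampleIds(nc)[1])
  expect_true(all(d[, 1] == 0))
  expect_equal(max(abs(d[, 2])), 0, tolerance = 1e-9)   # identical sample
  expect_gt(max(abs(d[, 3])), 10)                        # half-degree shift
  expect_error(differenceCurves(nc, "nope"), "not found")
})

test_that("identical curves form one cluster at full confidence", {
  mc <- make_set(rep(80, 6))
  nc <- normalizeCurves(mc)
  cl <- clusterCurves(nc)
  expect_equal(unname(max(clusterLabels(cl))), 1L)
  expect_equal(unname(clusterConfidence(cl)[, 1]), rep(100, 6))
  expect_error(clusterCurves(normalizeCurves(make_set(80))), "2 curves")
})

test_that("a 0.5 degree Tm split at noise sd 0.3 yields two clean clusters", {
  set.seed(89)
  mc <- make_set(c(80, 80, 80, 80.5, 80.5, 80.5), noise = 0.3)
  nc <- normalizeCurves(mc)
  cl <- clusterCurves(nc, HRMConfig(tmDiffThreshold = 0.2))
  lab <- clusterLabels(cl)
  expect_equal(unname(max(lab)), 2L)
  expect_equal(unname(table(lab)), c(3L, 3L), ignore_attr = TRUE)
  # every cross-cluster Tm gap respects the threshold (brute check)
  tms <- tmEstimates(nc)
  for (i in names(lab)) for (j in names(lab))
    if (lab[i] != lab[j]) expect_gte(abs(tms[i] - tms[j]), 0.2)
  # confidences are a per-sample distribution over clusters
  expect_equal(unname(rowSums(clusterConfidence(cl))), rep(100, 6))
})

test_that("clustering is invariant to sample order", {
  set.seed(91)
  mc <- make_set(c(80, 80, 81, 81, 82, 82), noise = 0.2)
  nc <- normalizeCurves(mc)
  cl1 <- clusterCurves(nc)
  perm <- c(5, 3, 1, 6, 2, 4)
  ncp <- new("NormalizedCurveSet", temperature = temperatures(nc),
             values = curveValues(nc)[, perm], tmEst = tmEstimates(nc)[perm],
             noCrossing = nc@noCrossing[perm], sampleData = NULL)
  cl2 <- clusterCurves(ncp)
  ids <- sampleIds(nc)
  expect_equal(clusterLabels(cl1)[ids], clusterLabels(cl2)[ids])
})

test_that("the two stringency knobs act monotonically", {
  set.seed(93)
  mc <- make_set(c(80, 80.3, 80.6, 81.2), noise = 0.1)
  nc <- normalizeCurves(mc)
  kAt <- function(sens, thr) max(clusterLabels(
    clusterCurves(nc, HRMConfig(shapeSensitivity = sens,
                                tmDiffThreshold = thr))))
  # raising shape sensitivity never merges clusters
  ks <- vapply(c(0, 25, 50, 75, 100), kAt, numeric(1), thr = 0.2)
  expect_true(all(diff(ks) >= 0))
  # raising the Tm threshold never splits stage 1 further
  kt <- vapply(c(0.1, 0.3, 0.5, 1), function(th) kAt(75, th), numeric(1))
  expect_true(all(diff(kt) <= 0))
})

test_that("an unknown identical to a reference joins its cluster", {
  mc <- make_set(c(80, 80, 81, 81))
  nc <- normalizeCurves(mc)
  labels <- setNames(c("A", "A", "B", "B"), sampleIds(nc))
  u <- normalizeCurves(make_set(81, prefix = "u"))
  call <- assignUnknown(u, nc, labels)
  expect_equal(call@call, "B")
  expect_gte(call@confidence, 95)
})

test_that("a shifted variant is returned unassigned as a possible new variant", {
  mc <- make_set(c(80, 80, 81, 81))
  nc <- normalizeCurves(mc)
  labels <- setNames(c("A", "A", "B", "B"), sampleIds(nc))
  u <- normalizeCurves(make_set(80.5, prefix = "u"))
  call <- assignUnknown(u, nc, labels)
  expect_match(call@call, "unassigned")
  expect_false(is.null(call@evidence$nearest_label))
})

test_that("a curve equal to the midpoint of two clusters is low-confidence", {
  mc <- make_set(c(80, 80, 81, 81), noise = 0)
  nc <- normalizeCurves(mc)
  labels <- setNames(c("A", "A", "B", "B"), sampleIds(nc))
  mid <- (curveValues(nc)[, 1] + curveValues(nc)[, 3]) / 2
  temps <- temperatures(nc)
  v <- matrix(mid, ncol = 1, dimnames = list(NULL, "mid"))
  i <- max(which(mid >= 50))
  tmMid <- temps[i] + (mid[i] - 50) / (mid[i] - mid[i + 1]) *
    (temps[i + 1] - temps[i])
  u <- new("NormalizedCurveSet", temperature = temps, values = v,
           tmEst = c(mid = tmMid), noCrossing = c(mid = FALSE),
           sampleData = NULL)
  call <- assignUnknown(u, nc, labels)
  expect_match(call@call, "unassigned")
  expect_lt(call@confidence, 95)
})

test_that("grid mismatches between unknown and reference are an error", {
  nc <- normalizeCurves(make_set(c(80, 81)))
  labels <- setNames(c("A", "B"), sampleIds(nc))
  u <- normalizeCurves(
    MeltCurveSet(seq(60, 95, by = 0.2),
                 matrix(synth_curve(80, seq(60, 95, by = 0.2)), ncol = 1,
                        dimnames = list(NULL, "u"))),
    HRMConfig(preMeltWindow = c(60, 63)))
  expect_error(assignUnknown(u, nc, labels), "grid mismatch")
})
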