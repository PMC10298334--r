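#' @include AllClasses.R accessors.R
NULL

# RMS distance between curve columns of a matrix: Euclidean scaled by
# sqrt(number of grid points).
.rmsDist <- function(m) {
  stats::dist(t(m)) / sqrt(nrow(m))
}

.rmsTo <- function(m, center) {
  sqrt(colMeans((m - center)^2))
}

#' Normalize melt curves between pre- and post-melt baselines
#'
#' Fits straight baselines by least squares to the fluorescence inside the
#' pre-melt and post-melt windows and rescales each curve to
#' `100 (F - lower) / (upper - lower)` percent, restricted to the range from
#' the start of the pre-melt window to the end of the post-melt window. The
#' per-sample melting temperature `tm_est` is the linear interpolation of
#' the 50% downward crossing; curves that never cross 50% are flagged and
#' carry `NA`.
#'
#' @param curves a [MeltCurveSet-class] whose grid covers both windows with
#'   at least two points each.
#' @param config an [HRMConfig-class]; its windows drive the fit.
#' @return a [NormalizedCurveSet-class].
#' @export
normalizeCurves <- function(curves, config = HRMConfig()) {
  t <- temperatures(curves)
  f <- curveValues(curves)
  pre <- config@preMeltWindow; post <- config@postMeltWindow
  preIdx <- which(t >= pre[1] & t <= pre[2])
  postIdx <- which(t >= post[1] & t <= post[2])
  if (length(preIdx) < 2L || length(postIdx) < 2L)
    stop("each baseline window must contain at least 2 grid points",
         call. = FALSE)
  keep <- which(t >= pre[1] & t <= post[2])
  tt <- t[keep]
  vals <- matrix(NA_real_, length(keep), ncol(f),
                 dimnames = list(NULL, colnames(f)))
  tmEst <- setNames(rep(NA_real_, ncol(f)), colnames(f))
  noCross <- setNames(logical(ncol(f)), colnames(f))
  for (j in seq_len(ncol(f))) {
    upperFit <- stats::lm.fit(cbind(1, t[preIdx]), f[preIdx, j])$coefficients
    lowerFit <- stats::lm.fit(cbind(1, t[postIdx]), f[postIdx, j])$coefficients
    upper <- upperFit[1] + upperFit[2] * tt
    lower <- lowerFit[1] + lowerFit[2] * tt
    if (min(upper - lower) <= 1e-6 * max(abs(f[, j]), 1))
      stop("degenerate baselines: upper <= lower inside the analyzed range",
           call. = FALSE)
    v <- 100 * (f[keep, j] - lower) / (upper - lower)
    vals[, j] <- v
    # first downward 50% crossing
    below <- which(v[-1L] < 50 & v[-length(v)] >= 50)
    if (length(below)) {
      i <- below[1L]
      tmEst[j] <- tt[i] + (v[i] - 50) / (v[i] - v[i + 1L]) * (tt[i + 1L] - tt[i])
    } else {
      noCross[j] <- TRUE
    }
  }
  new("NormalizedCurveSet", temperature = tt, values = vals, tmEst = tmEst,
      noCrossing = noCross, sampleData = curves@sampleData)
}

#' Difference curves against a reference sample
#'
#' Standard HRM reporting view: each normalized curve minus the reference
#' curve, so the reference plots as the zero line and variant curves show
#' signed lobes whose magnitude grows with the Tm/shape difference.
#'
#' @param curves a [NormalizedCurveSet-class].
#' @param referenceId sample id of the reference curve.
#' @return matrix of differences, one column per sample (reference column is
#'   identically zero).
#' @export
differenceCurves <- function(curves, referenceId) {
  v <- curveValues(curves)
  if (!referenceId %in% colnames(v))
    stop("reference sample '", referenceId, "' not found", call. = FALSE)
  v - v[, referenceId]
}

# Stage-1 grouping: single-linkage on the 1-D Tm estimates; groups split
# wherever the sorted adjacent gap reaches the threshold.
.tmGroups <- function(tm, threshold) {
  ord <- order(tm)
  gaps <- diff(tm[ord])
  grp <- cumsum(c(1L, as.integer(gaps >= threshold)))
  out <- integer(length(tm))
  out[ord] <- grp
  out
}

#' Two-stage clustering of normalized melt curves
#'
#' Reconstruction of the two documented knobs of HRM cluster analysis.
#' Stage 1 groups samples by melting temperature: single-linkage on the
#' 1-D Tm estimates, split wherever the gap reaches `tmDiffThreshold`, so
#' samples at least that far apart never share a cluster. Stage 2 splits
#' each Tm group by curve shape: average-linkage hierarchical clustering on
#' the RMS distance between normalized curves, cut at
#' `d_cut = (1 - shapeSensitivity/100) d_scale` with `d_scale` the largest
#' pairwise RMS distance in the dataset. Curves without a 50% crossing are
#' excluded from stage 1, clustered by shape only, and flagged.
#'
#' Per-sample confidence for cluster `c` is the softmax
#' `100 exp(-d_ic^2 / 2 sigma^2) / sum_c' exp(-d_ic'^2 / 2 sigma^2)` with
#' `d_ic` the RMS distance to the cluster mean curve and `sigma` the pooled
#' within-cluster RMS deviation (floored at 1e-3). Cluster ids are ordered
#' by increasing cluster mean Tm (shape-only clusters last), so memberships
#' are invariant to input order.
#'
#' @param curves a [NormalizedCurveSet-class] with >= 2 samples.
#' @param config an [HRMConfig-class].
#' @param referenceLabels optional named character (sample id to group
#'   label); clusters inherit the majority label of their labeled members.
#' @return a [ClusterResult-class].
#' @export
clusterCurves <- function(curves, config = HRMConfig(),
                          referenceLabels = NULL) {
  v <- curveValues(curves)
  ids <- colnames(v)
  if (ncol(v) < 2L) stop("need at least 2 curves", call. = FALSE)
  # deterministic processing order
  ord <- order(ids)
  v <- v[, ord, drop = FALSE]
  ids <- ids[ord]
  tm <- tmEstimates(curves)[ids]
  noCross <- curves@noCrossing[ids]
  if (config@tempShift) {
    # superimpose curves on the mean Tm before shape comparison
    shift <- tm - mean(tm, na.rm = TRUE)
    tgrid <- temperatures(curves)
    for (j in which(!is.na(shift)))
      v[, j] <- stats::approx(tgrid - shift[j], v[, j], xout = tgrid,
                              rule = 2)$y
  }
  D <- as.matrix(.rmsDist(v))
  dScale <- max(D)
  dCut <- (1 - config@shapeSensitivity / 100) * dScale

  stage1 <- integer(length(ids))
  hasTm <- !noCross & !is.na(tm)
  if (any(hasTm))
    stage1[hasTm] <- .tmGroups(tm[hasTm], config@tmDiffThreshold)
  if (any(!hasTm)) stage1[!hasTm] <- max(stage1) + 1L  # shape-only pool

  labels <- integer(length(ids))
  nextId <- 0L
  for (g in sort(unique(stage1))) {
    members <- which(stage1 == g)
    if (length(members) == 1L) {
      sub <- 1L
    } else {
      hc <- stats::hclust(stats::as.dist(D[members, members, drop = FALSE]),
                          method = "average")
      sub <- stats::cutree(hc, h = dCut)
    }
    labels[members] <- nextId + sub
    nextId <- max(labels)
  }
  # renumber clusters by increasing mean Tm, shape-only (all-NA Tm) last;
  # ties broken by smallest member id
  k <- max(labels)
  clTm <- vapply(seq_len(k), function(c)
    mean(tm[labels == c & hasTm]), numeric(1))
  minId <- vapply(seq_len(k), function(c) min(ids[labels == c]), character(1))
  newOrder <- order(is.na(clTm), clTm, minId)
  remap <- integer(k); remap[newOrder] <- seq_len(k)
  labels <- remap[labels]
  clTm <- clTm[newOrder]

  centers <- vapply(seq_len(k), function(c)
    rowMeans(v[, labels == c, drop = FALSE]), numeric(nrow(v)))
  dIC <- vapply(seq_len(k), function(c) .rmsTo(v, centers[, c]),
                numeric(ncol(v)))
  dIC <- matrix(dIC, nrow = ncol(v))
  own <- dIC[cbind(seq_along(labels), labels)]
  sigma <- max(sqrt(mean(own^2)), 1e-3)
  logw <- -dIC^2 / (2 * sigma^2)
  w <- exp(logw - apply(logw, 1L, max))
  conf <- 100 * w / rowSums(w)
  dimnames(conf) <- list(ids, NULL)

  clLabel <- rep(NA_character_, k)
  if (!is.null(referenceLabels)) {
    for (c in seq_len(k)) {
      lab <- referenceLabels[ids[labels == c]]
      lab <- lab[!is.na(lab)]
      if (length(lab)) {
        tabu <- sort(table(lab), decreasing = TRUE)
        clLabel[c] <- names(tabu)[1L]
      }
    }
  }
  new("ClusterResult", labels = setNames(labels, ids), confidence = conf,
      clusterTm = clTm, clusterLabel = clLabel,
      shapeOnly = ids[!hasTm])
}

#' Assign an unknown sample against a labeled reference set
#'
#' Re-clusters the reference curves together with the unknown. If the
#' unknown lands in a cluster that carries a reference label and its
#' confidence reaches the configured floor, that label is returned;
#' otherwise the call is `"unassigned — possible new variant"` — the
#' behavior wanted for novel haplotypes, which melt apart from every
#' reference cluster — along with the nearest labeled cluster and the
#' confidence the unknown has in it.
#'
#' @param unknown a one-sample [NormalizedCurveSet-class] on the same grid
#'   as the reference.
#' @param reference a [NormalizedCurveSet-class] of reference curves.
#' @param referenceLabels named character, reference sample id to group.
#' @param config an [HRMConfig-class].
#' @return a [SpeciesCall-class].
#' @export
assignUnknown <- function(unknown, reference, referenceLabels,
                          config = HRMConfig()) {
  if (length(sampleIds(unknown)) != 1L)
    stop("unknown must be a single curve", call. = FALSE)
  if (!isTRUE(all.equal(temperatures(unknown), temperatures(reference),
                        tolerance = 1e-9)))
    stop("grid mismatch between unknown and reference curves", call. = FALSE)
  if (length(unique(referenceLabels)) < 2L)
    stop("reference must carry at least 2 labeled groups", call. = FALSE)
  uid <- sampleIds(unknown)
  qid <- uid
  while (qid %in% sampleIds(reference)) qid <- paste0(qid, "*")  # keep unique
  uv <- curveValues(unknown)
  colnames(uv) <- qid
  comb <- new("NormalizedCurveSet",
              temperature = temperatures(reference),
              values = cbind(curveValues(reference), uv),
              tmEst = c(tmEstimates(reference),
                        setNames(unname(tmEstimates(unknown)), qid)),
              noCrossing = c(reference@noCrossing,
                             setNames(unname(unknown@noCrossing), qid)),
              sampleData = NULL)
  cl <- clusterCurves(comb, config, referenceLabels)
  lab <- clusterLabels(cl)[qid]
  conf <- clusterConfidence(cl)[qid, lab]
  clLab <- cl@clusterLabel[lab]
  if (!is.na(clLab) && conf >= config@confidenceFloor) {
    call <- clLab
  } else {
    call <- "unassigned — possible new variant"
    labeled <- which(!is.na(cl@clusterLabel))
    if (length(labeled)) {
      near <- labeled[which.max(clusterConfidence(cl)[qid, labeled])]
      clLab <- cl@clusterLabel[near]
      conf <- clusterConfidence(cl)[qid, near]
    }
  }
  new("SpeciesCall", sampleId = uid, method = "hrm", call = call,
      confidence = unname(conf),
      evidence = list(cluster = unname(lab),
                      nearest_label = unname(clLab),
                      cluster_tm = cl@clusterTm[lab],
                      tm_est = unname(tmEstimates(unknown))),
      mislabelFlag = NA)
}
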