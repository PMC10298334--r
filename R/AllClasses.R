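#' @include iupac.R
NULL

setClassUnion("DataFrameOrNULL", c("DataFrame", "NULL"))

#' Container for a set of raw melt curves
#'
#' Fluorescence recorded over a shared, strictly increasing, constant-step
#' temperature grid; one column per sample. The grid convention mirrors an
#' HRM dissociation protocol (default 65--95 degrees C in 0.2 degree steps).
#'
#' @slot temperature numeric grid in degrees C, strictly increasing with a
#'   constant step.
#' @slot fluorescence numeric matrix, `length(temperature)` rows, one named
#'   column per sample; values are arbitrary fluorescence units, non-negative.
#' @slot sampleData optional `DataFrame` of per-sample annotation (e.g. a
#'   `group` column with species/stock labels), one row per column.
#' @export
setClass("MeltCurveSet",
  representation(temperature = "numeric",
                 fluorescence = "matrix",
                 sampleData = "DataFrameOrNULL"),
  prototype(sampleData = NULL))

setValidity("MeltCurveSet", function(object) {
  t <- object@temperature
  f <- object@fluorescence
  if (length(t) < 2L) return("temperature grid needs at least 2 points")
  d <- diff(t)
  if (any(d <= 0)) return("temperature grid must be strictly increasing")
  if (max(d) - min(d) > 1e-6) return("temperature grid step must be constant")
  if (nrow(f) != length(t)) return("fluorescence rows must match grid length")
  if (is.null(colnames(f)) || anyDuplicated(colnames(f)))
    return("fluorescence columns need unique sample ids")
  if (any(f < 0)) return("fluorescence must be non-negative")
  if (!is.null(object@sampleData) && nrow(object@sampleData) != ncol(f))
    return("sampleData must have one row per sample")
  TRUE
})

#' Baseline-normalized melt curves
#'
#' Result of [normalizeCurves()]: fluorescence rescaled to percent helicity
#' between straight baselines fitted in the pre- and post-melt windows, with
#' the per-sample melting temperature estimated at the 50% crossing.
#'
#' @slot temperature grid restricted to the analyzed range.
#' @slot values matrix of normalized values (percent), one column per sample.
#' @slot tmEst named numeric, 50% crossing per sample (NA when the curve
#'   never crosses 50%).
#' @slot noCrossing named logical flagging samples without a 50% crossing.
#' @slot sampleData optional per-sample annotation.
#' @export
setClass("NormalizedCurveSet",
  representation(temperature = "numeric",
                 values = "matrix",
                 tmEst = "numeric",
                 noCrossing = "logical",
                 sampleData = "DataFrameOrNULL"),
  prototype(sampleData = NULL))

setValidity("NormalizedCurveSet", function(object) {
  if (nrow(object@values) != length(object@temperature))
    return("values rows must match grid length")
  ids <- colnames(object@values)
  if (is.null(ids) || anyDuplicated(ids)) return("unique sample ids required")
  if (!identical(names(object@tmEst), ids) ||
      !identical(names(object@noCrossing), ids))
    return("tmEst/noCrossing must be named by sample id")
  ok <- !object@noCrossing
  tm <- object@tmEst[ok]
  rng <- range(object@temperature)
  if (any(!is.na(tm) & (tm < rng[1] | tm > rng[2])))
    return("tmEst must lie inside the analyzed range")
  TRUE
})

#' HRM analysis configuration
#'
#' The knobs of the melt-curve analysis: normalization windows, the two
#' clustering stringency controls (curve shape sensitivity in percent and the
#' melting-temperature difference threshold in degrees C), the confidence
#' floor for accepting a species call, and the acquisition grid.
#'
#' @slot preMeltWindow,postMeltWindow two temperatures (degrees C) bounding
#'   the baseline-fitting windows; pre must lie entirely below post.
#' @slot shapeSensitivity percent in 0--100; higher splits clusters more
#'   readily on curve shape.
#' @slot tmDiffThreshold degrees C; samples whose Tm estimates differ by at
#'   least this much are never co-clustered.
#' @slot confidenceFloor percent; minimum cluster confidence for a call.
#' @slot grid `c(start, stop, step)` of the melt acquisition, degrees C.
#' @slot tempShift logical; superimpose curves by Tm before shape
#'   comparison (off by default).
#' @export
setClass("HRMConfig",
  representation(preMeltWindow = "numeric", postMeltWindow = "numeric",
                 shapeSensitivity = "numeric", tmDiffThreshold = "numeric",
                 confidenceFloor = "numeric", grid = "numeric",
                 tempShift = "logical"))

setValidity("HRMConfig", function(object) {
  pre <- object@preMeltWindow; post <- object@postMeltWindow
  if (length(pre) != 2L || length(post) != 2L || diff(pre) <= 0 ||
      diff(post) <= 0)
    return("windows must be increasing length-2 numerics")
  if (pre[2] >= post[1]) return("pre-melt window must lie below post-melt")
  g <- object@grid
  if (length(g) != 3L || g[3] <= 0 || g[2] <= g[1])
    return("grid must be c(start, stop, step) with step > 0")
  if (object@shapeSensitivity < 0 || object@shapeSensitivity > 100)
    return("shapeSensitivity must be in [0, 100]")
  if (object@tmDiffThreshold < 0) return("tmDiffThreshold must be >= 0")
  TRUE
})

#' @param preMeltWindow,postMeltWindow,shapeSensitivity,tmDiffThreshold
#'   see slots.
#' @param confidenceFloor,grid,tempShift see slots.
#' @rdname HRMConfig-class
#' @export
HRMConfig <- function(preMeltWindow = c(65, 68), postMeltWindow = c(92, 95),
                      shapeSensitivity = 75, tmDiffThreshold = 0.2,
                      confidenceFloor = 95, grid = c(65, 95, 0.2),
                      tempShift = FALSE) {
  new("HRMConfig", preMeltWindow = as.numeric(preMeltWindow),
      postMeltWindow = as.numeric(postMeltWindow),
      shapeSensitivity = as.numeric(shapeSensitivity),
      tmDiffThreshold = as.numeric(tmDiffThreshold),
      confidenceFloor = as.numeric(confidenceFloor),
      grid = as.numeric(grid), tempShift = isTRUE(tempShift))
}

#' Melt-curve clustering result
#'
#' @slot labels named integer, cluster id per sample (ids are 1..K, ordered
#'   by increasing cluster mean Tm, Tm-less shape-only clusters last).
#' @slot confidence matrix samples x clusters of percent confidences; each
#'   row sums to 100.
#' @slot clusterTm numeric, mean Tm estimate per cluster (NA for shape-only).
#' @slot clusterLabel character, majority reference label per cluster (NA
#'   where no labeled member).
#' @slot shapeOnly character, ids of samples clustered by shape only because
#'   their curve never crossed 50%.
#' @export
setClass("ClusterResult",
  representation(labels = "integer", confidence = "matrix",
                 clusterTm = "numeric", clusterLabel = "character",
                 shapeOnly = "character"))

setValidity("ClusterResult", function(object) {
  if (is.null(names(object@labels))) return("labels must be named")
  k <- max(object@labels)
  if (ncol(object@confidence) != k || nrow(object@confidence) !=
      length(object@labels))
    return("confidence must be samples x clusters")
  s <- rowSums(object@confidence)
  if (any(abs(s - 100) > 1e-6)) return("confidences must sum to 100 per sample")
  if (length(object@clusterTm) != k || length(object@clusterLabel) != k)
    return("clusterTm/clusterLabel must have one entry per cluster")
  TRUE
})

#' Restriction enzyme definition
#'
#' Only palindromic recognition sites are accepted, so scanning the top
#' strand finds every cut; a non-palindromic site is rejected at construction
#' rather than silently half-scanned.
#'
#' @slot name enzyme name.
#' @slot recognition concrete recognition sequence, 5' to 3'.
#' @slot cutOffset bases from the 5' start of the site to the top-strand cut.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  rec <- object@recognition
  if (!grepl("^[ACGT]+$", rec)) return("recognition site must be concrete DNA")
  if (reverseComplementIUPAC(rec) != rec)
    return(sprintf("recognition site %s is not palindromic; top-strand scanning would miss cuts", rec))
  if (object@cutOffset < 0L || object@cutOffset > nchar(rec))
    return("cutOffset must be within the recognition site")
  TRUE
})

#' Restriction digest pattern
#'
#' @slot enzyme enzyme name.
#' @slot inputLength length of the digested (linear) sequence.
#' @slot fragments fragment lengths, sorted decreasing; they sum to
#'   `inputLength`.
#' @slot cutPositions 1-based positions after which the top strand is cut.
#' @slot subResolution flags fragments under the gel resolution floor
#'   (default 40 bp) that may not resolve on an agarose gel.
#' @export
setClass("DigestPattern",
  representation(enzyme = "character", inputLength = "integer",
                 fragments = "integer", cutPositions = "integer",
                 subResolution = "logical"))

setValidity("DigestPattern", function(object) {
  if (sum(object@fragments) != object@inputLength)
    return("fragments must sum to input length")
  if (any(object@fragments < 1L)) return("fragments must be >= 1")
  if (is.unsorted(rev(object@fragments))) return("fragments must be sorted decreasing")
  TRUE
})

#' Species identification call
#'
#' @slot sampleId sample identifier.
#' @slot method one of "hrm", "rflp", "multiplex", "combined".
#' @slot call assigned group/species label, `"unassigned — possible new
#'   variant"`, or `"no product"` when the marker fails to amplify in silico.
#' @slot confidence percent (HRM) or match score (RFLP/multiplex).
#' @slot evidence structured record: cluster id, digest pattern or product
#'   list supporting the call.
#' @slot mislabelFlag `TRUE` when a declared label exists and conflicts with
#'   a definite call; `NA` when no declared label was given or no definite
#'   call was made.
#' @export
setClass("SpeciesCall",
  representation(sampleId = "character", method = "character",
                 call = "character", confidence = "numeric",
                 evidence = "list", mislabelFlag = "logical"))

#' Synthetic reference panel
#'
#' Output of [simulateReferencePanel()]: a deterministic, fully in silico
#' stand-in for a curated panel of reference specimens. Holds the gap-free
#' member sequences, their alignment, group labels, and the coordinates of
#' the planted diagnostic marker window.
#'
#' @slot sequences `DNAStringSet` of member sequences (gaps removed).
#' @slot alignment character matrix, members x alignment columns.
#' @slot groups named character, member id to group label.
#' @slot marker list with `start`, `end` (1-based inclusive alignment
#'   columns), `flankLen` and `diagnosticColumns`.
#' @slot seed integer seed the panel was generated from.
#' @export
setClass("ReferencePanel",
  representation(sequences = "DNAStringSet", alignment = "matrix",
                 groups = "character", marker = "list", seed = "integer"))

setMethod("show", "MeltCurveSet", function(object) {
  cat(sprintf("MeltCurveSet: %d samples, grid %.1f..%.1f by %.2f degC (%d points)\n",
              ncol(object@fluorescence), min(object@temperature),
              max(object@temperature), diff(object@temperature[1:2]),
              length(object@temperature)))
})

setMethod("show", "NormalizedCurveSet", function(object) {
  cat(sprintf("NormalizedCurveSet: %d samples over %.1f..%.1f degC; Tm %s\n",
              ncol(object@values), min(object@temperature),
              max(object@temperature),
              paste(sprintf("%.2f", unname(object@tmEst)), collapse = ", ")))
})

setMethod("show", "HRMConfig", function(object) {
  cat(sprintf(paste0("HRMConfig: pre %.1f-%.1f, post %.1f-%.1f degC; ",
                     "sensitivity %.0f%%, dTm threshold %.2f degC, ",
                     "confidence floor %.0f%%\n"),
              object@preMeltWindow[1], object@preMeltWindow[2],
              object@postMeltWindow[1], object@postMeltWindow[2],
              object@shapeSensitivity, object@tmDiffThreshold,
              object@confidenceFloor))
})

setMethod("show", "ClusterResult", function(object) {
  k <- max(object@labels)
  cat(sprintf("ClusterResult: %d samples in %d clusters (Tm %s)\n",
              length(object@labels), k,
              paste(sprintf("%.2f", object@clusterTm), collapse = ", ")))
})

setMethod("show", "DigestPattern", function(object) {
  cat(sprintf("DigestPattern [%s on %d bp]: %s\n", object@enzyme,
              object@inputLength, paste(object@fragments, collapse = " / ")))
})

setMethod("show", "SpeciesCall", function(object) {
  cat(sprintf("SpeciesCall %s [%s]: %s (%.1f%%)%s\n", object@sampleId,
              object@method, object@call, object@confidence,
              if (isTRUE(object@mislabelFlag)) " MISLABEL" else ""))
})

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d members, %d groups, marker cols %d..%d\n",
              length(object@sequences), length(unique(object@groups)),
              object@marker$start, object@marker$end))
})
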