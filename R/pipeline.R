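#' @include hrm.R synth.R insilico_pcr.R rflp.R
NULL

#' Build an HRM reference set from a panel
#'
#' Simulates one noiseless, baseline-free melt curve per panel member on the
#' configured grid, normalizes them, and records the member group labels:
#' the in silico equivalent of running sequenced control specimens on every
#' plate. The marker's conserved flanks double as the primer pair used to
#' amplify unknowns.
#'
#' @param panel a [ReferencePanel-class].
#' @param config an [HRMConfig-class].
#' @param NaMM salt convention for the melt model.
#' @return list: `curves` ([NormalizedCurveSet-class]), `labels` (named
#'   character), `clusters` ([ClusterResult-class]), `fwdPrimer`,
#'   `revPrimer`, `config`.
#' @export
buildReferenceSet <- function(panel, config = HRMConfig(), NaMM = 100) {
  raw <- simulateMeltCurveSet(panel, replicates = 1L, noiseSd = 0,
                              grid = config@grid, flatBaseline = TRUE,
                              NaMM = NaMM, seed = panel@seed)
  norm <- normalizeCurves(raw, config)
  labels <- setNames(as.character(raw@sampleData$group), sampleIds(raw))
  clusters <- clusterCurves(norm, config, labels)
  mk <- panel@marker
  cons <- panel@alignment[1L, ]  # flanks are conserved across the panel
  fwd <- paste(cons[mk$start:(mk$start + mk$flankLen - 1L)], collapse = "")
  rev <- reverseComplementIUPAC(
    paste(cons[(mk$end - mk$flankLen + 1L):mk$end], collapse = ""))
  list(curves = norm, labels = labels, clusters = clusters,
       fwdPrimer = fwd, revPrimer = rev, config = config, NaMM = NaMM)
}

#' Identify one sample against a reference set
#'
#' Sequence input is pushed through the whole in silico workflow: amplify
#' the marker with the reference primer pair, simulate the amplicon's melt
#' curve, normalize it, and assign it against the reference clusters. A
#' melt-curve input (one-sample [MeltCurveSet-class]) skips straight to
#' normalization. When the marker fails to amplify the call is an explicit
#' `"no product"` — a real failure mode of short-fragment assays on some
#' taxa — rather than an error. If `declaredLabel` is given and the call is
#' a definite group that differs from it, the mislabel flag is raised;
#' an unassigned or failed call leaves the flag `NA`.
#'
#' @param input DNA sequence (character/`DNAString`) or one-sample
#'   [MeltCurveSet-class].
#' @param reference result of [buildReferenceSet()].
#' @param declaredLabel optional declared species/group label.
#' @param sampleId id for the report.
#' @param maxMismatches,clampLen in silico PCR settings.
#' @return a [SpeciesCall-class].
#' @export
identifySample <- function(input, reference, declaredLabel = NULL,
                           sampleId = "unknown", maxMismatches = 2L,
                           clampLen = 3L) {
  config <- reference$config
  if (methods::is(input, "MeltCurveSet")) {
    norm <- normalizeCurves(input, config)
    sampleId <- sampleIds(input)[1L]
  } else {
    seq <- as.character(input)
    amp <- amplify(seq, reference$fwdPrimer, reference$revPrimer,
                   maxMismatches = maxMismatches, clampLen = clampLen)
    if (nrow(amp) == 0L) {
      return(new("SpeciesCall", sampleId = sampleId, method = "hrm",
                 call = "no product", confidence = 0,
                 evidence = list(fwd = reference$fwdPrimer,
                                 rev = reference$revPrimer),
                 mislabelFlag = NA))
    }
    raw <- simulateMeltCurve(amp$sequence[1L], grid = config@grid,
                             NaMM = reference$NaMM, sampleId = sampleId)
    norm <- normalizeCurves(raw, config)
  }
  callObj <- assignUnknown(norm, reference$curves, reference$labels, config)
  flag <- NA
  if (!is.null(declaredLabel) &&
      callObj@call %in% unique(reference$labels))
    flag <- callObj@call != declaredLabel
  methods::initialize(callObj, sampleId = sampleId, mislabelFlag = flag)
}

#' Summarize a sample panel table
#'
#' Totals of every count column after filtering rows by equality predicates
#' on the text columns. Grouping never invents or loses specimens: the
#' grand totals of any disjoint set of filters add up to the unfiltered
#' totals.
#'
#' @param panel `data.frame` from [loadPanelTable()].
#' @param ... named filters on text columns, e.g. `sample_id = "DdG"` or
#'   `species = c("P. pagrus", "P. major")`.
#' @return list: `n_rows` and the summed count columns.
#' @export
summarizePanel <- function(panel, ...) {
  filters <- list(...)
  keep <- rep(TRUE, nrow(panel))
  for (nm in names(filters)) {
    if (!nm %in% names(panel))
      stop("unknown panel column '", nm, "'", call. = FALSE)
    keep <- keep & panel[[nm]] %in% filters[[nm]]
  }
  sub <- panel[keep, , drop = FALSE]
  counts <- lapply(.PANEL_COUNT_COLS, function(cc)
    sum(sub[[cc]]))
  names(counts) <- .PANEL_COUNT_COLS
  c(list(n_rows = nrow(sub)), counts)
}
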