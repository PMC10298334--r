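#' @include iupac.R
NULL

# Gas constant, cal/(mol K)
.R_GAS <- 1.987

.thermoCache <- new.env(parent = emptyenv())

# Unified nearest-neighbor parameter set, read once from the versioned data
# file. Ten unique stacks plus the two initiation terms; the complementary
# stack of each listed dinucleotide shares its parameters.
.nnTable <- function() {
  if (!is.null(.thermoCache$nn)) return(.thermoCache$nn)
  path <- system.file("extdata", "nn_unified.tsv", package = "meltmark",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  dH <- setNames(tab$dH_kcal, tab$term)
  dS <- setNames(tab$dS_cal, tab$term)
  comp <- function(x) reverseComplementIUPAC(x)
  stacks <- setdiff(tab$term, c("init_GC", "init_AT"))
  for (s in stacks) {
    rc <- comp(s)
    if (!rc %in% names(dH)) { dH[rc] <- dH[s]; dS[rc] <- dS[s] }
  }
  .thermoCache$nn <- list(dH = dH, dS = dS)
  .thermoCache$nn
}

# dH (kcal/mol), dS (cal/mol/K) of one concrete duplex, salt-corrected:
# dS' = dS + 0.368 (N-1) ln([Na+]), [Na+] in mol/L.
.duplexDHDS <- function(seq, NaMM) {
  nn <- .nnTable()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  stacks <- paste0(chars[-n], chars[-1L])
  dH <- sum(nn$dH[stacks])
  dS <- sum(nn$dS[stacks])
  for (term in chars[c(1L, n)]) {
    key <- if (term %in% c("G", "C")) "init_GC" else "init_AT"
    dH <- dH + nn$dH[[key]]
    dS <- dS + nn$dS[[key]]
  }
  dS <- dS + 0.368 * (n - 1L) * log(NaMM / 1000)
  c(dH = unname(dH), dS = unname(dS))
}

#' Nearest-neighbor thermodynamics of a primer/template duplex
#'
#' Helix formation enthalpy and entropy from the unified nearest-neighbor
#' parameter set (stack terms plus initiation terms with the terminal A-T
#' penalty), entropy salt correction `0.368 (N-1) ln([Na+])`, and the
#' bimolecular oligo melting temperature
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15` for non-self-complementary
#' oligos. Degenerate primers average dH and dS over all concrete expansions
#' (an oligo pool melts at roughly the mean of its variants); more than 64
#' expansions is an error.
#'
#' The default salt and strand-concentration convention was fixed once by
#' calibrating against a published 22-primer table (see
#' [calibrateTmConvention()]) and is frozen here.
#'
#' @param seq duplex sequence 5' to 3' (character or `DNAString`), length
#'   >= 8.
#' @param NaMM monovalent cation concentration, mM.
#' @param strandConcM total strand concentration, mol/L.
#' @return list with `dH` (kcal/mol), `dS` (cal/mol/K, salt-corrected) and
#'   `tm` (degrees C).
#' @export
duplexParams <- function(seq, NaMM = 100, strandConcM = 10^-6.2) {
  seq <- .canonicalizeBases(as.character(seq), what = "duplex")
  if (nchar(seq) < 8L) stop("too short for NN model", call. = FALSE)
  variants <- .expandDegenerate(seq, cap = 64L)
  hs <- vapply(variants, .duplexDHDS, numeric(2), NaMM = NaMM)
  dH <- mean(hs["dH", ]); dS <- mean(hs["dS", ])
  tm <- 1000 * dH / (dS + .R_GAS * log(strandConcM / 4)) - 273.15
  list(dH = dH, dS = dS, tm = tm)
}

#' Primer melting temperature under the calibrated convention
#'
#' @inheritParams duplexParams
#' @return Tm in degrees C (vectorized over `seq`).
#' @export
primerTm <- function(seq, NaMM = 100, strandConcM = 10^-6.2) {
  vapply(as.character(seq),
         function(s) duplexParams(s, NaMM, strandConcM)$tm, numeric(1),
         USE.NAMES = !is.null(names(seq)))
}

#' Calibrate the global salt/strand-concentration convention
#'
#' The printed Tm column of a primer table rarely states its formula. This
#' fits the two free knobs of the nearest-neighbor convention — monovalent
#' salt and total strand concentration — by deterministic grid search
#' minimizing the mean absolute error between predicted and reported Tm over
#' all primers with a reported value, and reports the per-primer residuals.
#' Ties resolve to the lowest salt, then the lowest concentration.
#'
#' @param primers `data.frame` with `name`, `sequence`, `tm` columns (as from
#'   [loadPrimerTable()]).
#' @param NaGrid candidate Na+ concentrations, mM.
#' @param concGrid candidate strand concentrations, mol/L.
#' @return list: `NaMM`, `strandConcM`, `mae`, `maxAbsErr`, and `table`
#'   (per-primer predicted/reported Tm and error).
#' @export
calibrateTmConvention <- function(primers,
                                  NaGrid = seq(30, 300, by = 10),
                                  concGrid = 10^seq(-7.6, -5.4, by = 0.1)) {
  keep <- !is.na(primers$tm)
  if (!any(keep)) stop("no reported Tm values to calibrate on", call. = FALSE)
  primers <- primers[keep, , drop = FALSE]
  # salt and concentration act additively on dS and the log term, so dH/dS
  # per primer is precomputed once and the grid evaluated in closed form
  base <- lapply(primers$sequence, function(s) {
    variants <- .expandDegenerate(.canonicalizeBases(s, what = s), cap = 64L)
    hs <- vapply(variants, .duplexDHDS, numeric(2), NaMM = 1000)  # no-salt
    c(dH = mean(hs["dH", ]), dS0 = mean(hs["dS", ]),
      n = nchar(variants[1L]))
  })
  dH <- vapply(base, `[[`, numeric(1), "dH")
  dS0 <- vapply(base, `[[`, numeric(1), "dS0")
  nlen <- vapply(base, `[[`, numeric(1), "n")
  best <- NULL
  for (Na in NaGrid) for (conc in concGrid) {
    dS <- dS0 + 0.368 * (nlen - 1) * log(Na / 1000)
    tm <- 1000 * dH / (dS + .R_GAS * log(conc / 4)) - 273.15
    err <- abs(tm - primers$tm)
    mae <- mean(err)
    if (is.null(best) || mae < best$mae - 1e-12) {
      best <- list(NaMM = Na, strandConcM = conc, mae = mae,
                   maxAbsErr = max(err), predicted = tm)
    }
  }
  best$table <- data.frame(name = primers$name, reported = primers$tm,
                           predicted = best$predicted,
                           error = best$predicted - primers$tm,
                           stringsAsFactors = FALSE)
  best$predicted <- NULL
  best
}

# Long-duplex (amplicon) melting temperature, unimolecular approximation:
# Tm = 1000 dH / dS in kelvin with salt-corrected dS, no concentration term.
.ampliconTm <- function(seq, NaMM = 100) {
  hs <- .duplexDHDS(seq, NaMM)
  1000 * hs[["dH"]] / hs[["dS"]] - 273.15
}

#' Simulate the melt curve of an amplicon
#'
#' Two-state model: helicity
#' `theta(T) = 1 / (1 + exp[(dH_melt/R) (1/Tm - 1/T)])` with
#' `dH_melt = -dH`, temperatures in kelvin and `Tm = dH/dS` under the
#' unimolecular long-duplex approximation (salt-corrected entropy, no
#' concentration term: on HRM timescales long products re-anneal
#' intramolecularly, and the observable is curve shape and relative Tm).
#' The windowed model averages per-window two-state helicities over
#' overlapping subsequences, producing the compound transitions of
#' multi-domain amplicons; with `windowLen` equal to the amplicon length it
#' reduces exactly to the two-state model. Output is scaled to
#' `100 * theta`.
#'
#' @param seq concrete amplicon sequence, length >= 20.
#' @param grid `c(start, stop, step)` in degrees C (default the HRM
#'   acquisition grid 65--95 by 0.2).
#' @param model `"two_state"` or `"windowed"`.
#' @param windowLen,windowStep window geometry (bases) for the windowed
#'   model.
#' @param NaMM monovalent salt, mM.
#' @param sampleId column name of the returned curve.
#' @return a one-sample [MeltCurveSet-class].
#' @export
simulateMeltCurve <- function(seq, grid = c(65, 95, 0.2),
                              model = c("two_state", "windowed"),
                              windowLen = 50L, windowStep = 10L,
                              NaMM = 100, sampleId = "sim") {
  model <- match.arg(model)
  seq <- .canonicalizeBases(as.character(seq), what = "amplicon")
  L <- nchar(seq)
  if (L < 20L)
    stop("amplicon shorter than 20 bp is not a meaningful HRM product",
         call. = FALSE)
  if (length(grid) != 3L || grid[3] <= 0 || grid[2] <= grid[1])
    stop("grid must be c(start, stop, step)", call. = FALSE)
  temps <- seq(grid[1], grid[2], by = grid[3])
  tk <- temps + 273.15
  theta1 <- function(s) {
    hs <- .duplexDHDS(s, NaMM)
    tmK <- 1000 * hs[["dH"]] / hs[["dS"]]
    dHmelt <- -hs[["dH"]] * 1000      # cal/mol, positive
    1 / (1 + exp((dHmelt / .R_GAS) * (1 / tmK - 1 / tk)))
  }
  if (model == "two_state") {
    theta <- theta1(seq)
  } else {
    if (windowLen > L)
      stop("windowLen exceeds amplicon length", call. = FALSE)
    starts <- seq(1L, L - windowLen + 1L, by = windowStep)
    if (tail(starts, 1L) != L - windowLen + 1L)
      starts <- c(starts, L - windowLen + 1L)
    thetas <- vapply(starts, function(s)
      theta1(substr(seq, s, s + windowLen - 1L)), numeric(length(tk)))
    theta <- rowMeans(thetas)   # equal-length windows: plain mean
  }
  MeltCurveSet(temps, matrix(100 * theta, ncol = 1L,
                             dimnames = list(NULL, sampleId)))
}
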