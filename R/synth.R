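#' @include AllClasses.R thermo.R
NULL

# All randomness in this module flows through one RNG stream created from
# the seed; no global RNG state is touched.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.randomBases <- function(n, prob = NULL)
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)

# substitute each position with probability `rate`, drawing uniformly among
# the three other bases; positions in `protect` are never touched
.mutate <- function(chars, rate, protect = integer(0)) {
  hit <- which(runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Simulate a deterministic multi-group reference panel
#'
#' Generates an ancestor sequence, derives one consensus per group by random
#' substitutions at the inter-group rate, and members per group by
#' substitutions at the intra-group rate — the divergence structure of
#' closely related species sharing a recent ancestor, at rates matching the
#' percent-identity ranges seen between congeneric fish on short
#' mitochondrial fragments. A diagnostic marker window is planted: its
#' `flankLen` flanks are fully conserved (universal primer sites), its
#' interior carries a ladder of group-diagnostic substitutions
#' (group \eqn{g} converts \eqn{2(g-1)} planted A positions to G), so every
#' group pair differs inside the window and group amplicons form a melting
#' temperature ladder with steps of roughly one degree. Substitution
#' noise never lands inside the marker window, and intra-group noise never
#' breaks within-group identity there, mirroring a marker chosen for being
#' identical within groups. The same seed reproduces the panel bit for bit.
#'
#' @param nGroups number of groups (default 6: the five lookalike taxa plus
#'   the imported stock of a market panel).
#' @param membersPerGroup sequenced specimens per group.
#' @param seqLen ungapped sequence length of the simulated fragment.
#' @param interDivergence substitutions/site between group consensi
#'   (default 0.04, i.e. roughly 96% inter-group identity).
#' @param intraDivergence substitutions/site within groups (default 0.005).
#' @param markerStart 1-based alignment column where the marker window
#'   begins.
#' @param markerLen marker window length including both flanks (default 113,
#'   a short degraded-sample-safe amplicon).
#' @param flankLen conserved flank length (default 18).
#' @param indelGroup optional group index receiving a 1-base insertion
#'   inside the marker interior (the 16s-type case); all other rows gain a
#'   gap column.
#' @param seed integer seed.
#' @return a [ReferencePanel-class].
#' @export
simulateReferencePanel <- function(nGroups = 6L, membersPerGroup = 3L,
                                   seqLen = 600L, interDivergence = 0.04,
                                   intraDivergence = 0.005,
                                   markerStart = 201L, markerLen = 113L,
                                   flankLen = 18L, indelGroup = NULL,
                                   seed = 1L) {
  if (interDivergence > 0.5 || intraDivergence > 0.5)
    stop("divergence rates > 0.5 are not meaningful", call. = FALSE)
  if (interDivergence < intraDivergence)
    stop("inter-group divergence must be >= intra-group", call. = FALSE)
  markerEnd <- markerStart + markerLen - 1L
  if (markerEnd > seqLen) stop("marker window out of bounds", call. = FALSE)
  .withSeed(seed, {
    anc <- .randomBases(seqLen)
    # marker region drawn AT-rich (60% A/T), as in mitochondrial DNA: keeps
    # the amplicon Tm ladder well below the post-melt acquisition window
    anc[markerStart:markerEnd] <-
      .randomBases(markerLen, prob = c(0.3, 0.2, 0.2, 0.3))
    interior <- (markerStart + flankLen):(markerEnd - flankLen)
    nDiag <- 2L * (nGroups - 1L)   # two A/T -> G steps per group rung
    if (length(interior) < nDiag)
      stop("marker interior too short for the diagnostic ladder",
           call. = FALSE)
    diagCols <- interior[round(seq(1L, length(interior), length.out = nDiag))]
    anc[diagCols] <- "A"                       # ladder base state
    markerCols <- markerStart:markerEnd
    groupsIdx <- seq_len(nGroups)
    gnames <- sprintf("G%d", groupsIdx)
    consensi <- lapply(groupsIdx, function(g) {
      cons <- .mutate(anc, interDivergence, protect = markerCols)
      if (g > 1L) cons[diagCols[seq_len(2L * (g - 1L))]] <- "G"
      cons
    })
    rows <- list(); groups <- character(0)
    for (g in groupsIdx) for (m in seq_len(membersPerGroup)) {
      id <- sprintf("%s_m%d", gnames[g], m)
      rows[[id]] <- .mutate(consensi[[g]], intraDivergence,
                            protect = markerCols)
      groups[id] <- gnames[g]
    }
    aln <- do.call(rbind, rows)
    if (!is.null(indelGroup)) {
      # one-base insertion in the marked group: new alignment column after a
      # mid-interior position, gap in every other row
      at <- interior[length(interior) %/% 2L]
      ins <- sample(c("A", "C", "G", "T"), 1L)
      newCol <- ifelse(groups[rownames(aln)] == gnames[indelGroup], ins, "-")
      aln <- cbind(aln[, 1:at, drop = FALSE], newCol,
                   aln[, (at + 1L):ncol(aln), drop = FALSE])
      colnames(aln) <- NULL
      markerEnd <- markerEnd + 1L
      diagCols <- ifelse(diagCols > at, diagCols + 1L, diagCols)
    }
    seqs <- Biostrings::DNAStringSet(apply(aln, 1L, function(r)
      paste(r[r != "-"], collapse = "")))
    new("ReferencePanel", sequences = seqs, alignment = aln,
        groups = groups,
        marker = list(start = markerStart, end = markerEnd,
                      flankLen = flankLen, diagnosticColumns = diagCols),
        seed = as.integer(seed))
  })
}

# marker amplicon of one panel member (gaps removed)
.memberAmplicon <- function(panel, id) {
  mk <- panel@marker
  r <- panel@alignment[id, mk$start:mk$end]
  paste(r[r != "-"], collapse = "")
}

#' Simulate a plate of melt curves for a reference panel
#'
#' For every panel member, simulates the melt curve of its marker amplicon
#' and emulates the acquisition: `replicates` wells per member (samples run
#' as triplicates by default), i.i.d. Gaussian fluorescence noise, and a
#' random linear baseline (drifting dye background) that the normalization
#' step must remove. `noiseSd = 0` with `flatBaseline = TRUE` returns the
#' thermodynamic curves exactly.
#'
#' @param panel a [ReferencePanel-class].
#' @param replicates wells per member (default 3).
#' @param noiseSd fluorescence noise sd in percent-scale units (default
#'   0.3).
#' @param grid melt acquisition grid `c(start, stop, step)`.
#' @param flatBaseline disable the random baseline.
#' @param NaMM salt convention for the melt model.
#' @param seed integer seed.
#' @return a [MeltCurveSet-class] with samples named
#'   `<member>_r<replicate>` and a `group` column in `sampleData`.
#' @export
simulateMeltCurveSet <- function(panel, replicates = 3L, noiseSd = 0.3,
                                 grid = c(65, 95, 0.2), flatBaseline = FALSE,
                                 NaMM = 100, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  ids <- names(panel@sequences)
  .withSeed(seed + 1L, {
    temps <- seq(grid[1], grid[2], by = grid[3])
    cols <- list(); groupCol <- character(0)
    for (id in ids) {
      amp <- .memberAmplicon(panel, id)
      theta <- curveValues(simulateMeltCurve(amp, grid, NaMM = NaMM))[, 1L]
      for (r in seq_len(replicates)) {
        well <- sprintf("%s_r%d", id, r)
        if (flatBaseline) {
          base <- 0
        } else {
          slope <- runif(1, -0.15, -0.05)
          intercept <- runif(1, 8, 15)
          base <- intercept + slope * (temps - grid[1])
        }
        f <- theta + base + if (noiseSd > 0)
          rnorm(length(temps), 0, noiseSd) else 0
        cols[[well]] <- pmax(f, 0)
        groupCol[well] <- panel@groups[[id]]
      }
    }
    m <- do.call(cbind, cols)
    MeltCurveSet(temps, m,
                 S4Vectors::DataFrame(group = unname(groupCol),
                                      row.names = names(groupCol)))
  })
}

#' Simulate a labeled market survey with planted mislabeling
#'
#' Draws samples from the panel's groups, declares a label for each, and
#' mislabels a seeded fraction by declaring a different group — the ground
#' truth against which an identification pipeline's mislabel detection is
#' scored.
#'
#' @param panel a [ReferencePanel-class].
#' @param nSamples number of market samples.
#' @param mislabelRate probability a sample's declared label is wrong.
#' @param seed integer seed.
#' @return list: `samples` (`data.frame` with `sample_id`, `member_id`,
#'   `true_group`, `declared_group`, `mislabeled`) and `sequences`
#'   (`DNAStringSet` of the sampled specimens).
#' @export
simulateMarketSurvey <- function(panel, nSamples = 20L, mislabelRate = 0.1,
                                 seed = 1L) {
  if (mislabelRate < 0 || mislabelRate > 1)
    stop("mislabelRate must be in [0, 1]", call. = FALSE)
  gnames <- unique(panel@groups)
  ids <- names(panel@sequences)
  .withSeed(seed + 2L, {
    trueGroup <- sample(gnames, nSamples, replace = TRUE)
    memberId <- vapply(trueGroup, function(g)
      sample(ids[panel@groups == g], 1L), character(1))
    mis <- runif(nSamples) < mislabelRate
    declared <- trueGroup
    for (i in which(mis))
      declared[i] <- sample(setdiff(gnames, trueGroup[i]), 1L)
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(nSamples)),
      member_id = unname(memberId), true_group = trueGroup,
      declared_group = declared, mislabeled = mis,
      stringsAsFactors = FALSE)
    seqs <- panel@sequences[samples$member_id]
    names(seqs) <- samples$sample_id
    list(samples = samples, sequences = seqs)
  })
}
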