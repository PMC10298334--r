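#' @include thermo.R
NULL

# Per-column summaries used by the window scan. `aln` is a character matrix
# (rows = sequences), `groups` a named character of row id -> group.
.columnFlags <- function(aln, groups) {
  ids <- rownames(aln)
  glist <- split(ids, groups[ids])
  groupConsistent <- vapply(glist, function(members) {
    sub <- aln[members, , drop = FALSE]
    colSums(sub != sub[rep(1L, nrow(sub)), , drop = FALSE]) == 0L
  }, logical(ncol(aln)))
  allConsistent <- colSums(aln != aln[rep(1L, nrow(aln)), , drop = FALSE]) == 0L
  consensus <- vapply(glist, function(members) aln[members[1L], ],
                      character(ncol(aln)))
  list(groupConsistent = t(groupConsistent), allConsistent = allConsistent,
       consensus = t(consensus), groups = names(glist))
}

#' Scan an alignment for short diagnostic marker windows
#'
#' Finds every alignment window of length `minLen`..`maxLen` columns that
#' could support a short melt-analysis marker: (a) inside the window each
#' group is column-identical across its members, so the group has one
#' haplotype of the fragment; (b) at least one interior (non-flank) column
#' separates every pair of groups that must be discriminated; (c) both
#' `flankLen` flanks are near-universal primer landing sites, with at most
#' `maxFlankMismatch` columns variable across \emph{all} sequences.
#' Candidates are ranked by the number of diagnostic interior columns, ties
#' by shorter window, then by start. Windows containing gap columns are
#' allowed (a one-base indel between groups is itself informative) and
#' flagged.
#'
#' @param aln character matrix (rows = aligned sequences, rownames = ids).
#' @param groups named character, sequence id to group label.
#' @param minLen,maxLen window length bounds in alignment columns (defaults
#'   100 and 160, the short-fragment range of degraded-sample assays).
#' @param flankLen primer flank length in columns (default 18).
#' @param maxFlankMismatch maximum variable columns tolerated per flank.
#' @param mustDiscriminate optional 2-column matrix/data.frame of group
#'   pairs that must be separated; default all pairs.
#' @return `data.frame` of candidates: `start`, `end` (1-based inclusive
#'   columns), `length`, `n_diagnostic`, `diagnostic_columns` (comma-joined),
#'   `has_indel`, plus per-group amplicon lengths after gap removal in
#'   attribute `"amplicon_len"`. When empty, attribute `"failure_tally"`
#'   counts windows rejected per constraint.
#' @export
scanDiagnosticWindows <- function(aln, groups, minLen = 100L, maxLen = 160L,
                                  flankLen = 18L, maxFlankMismatch = 2L,
                                  mustDiscriminate = NULL) {
  if (minLen < 2L * flankLen + 1L)
    stop("minLen must be at least 2*flankLen + 1", call. = FALSE)
  if (!all(rownames(aln) %in% names(groups)))
    stop("every alignment row needs a group", call. = FALSE)
  fl <- .columnFlags(aln, groups)
  gnames <- fl$groups
  pairs <- utils::combn(gnames, 2L)
  if (!is.null(mustDiscriminate)) {
    md <- as.matrix(mustDiscriminate)
    keep <- apply(pairs, 2L, function(p)
      any((md[, 1] == p[1] & md[, 2] == p[2]) |
          (md[, 1] == p[2] & md[, 2] == p[1])))
    pairs <- pairs[, keep, drop = FALSE]
  }
  nc <- ncol(aln)
  # column-level indicators
  grpBad <- colSums(!fl$groupConsistent) > 0L        # any group inconsistent
  varAll <- !fl$allConsistent
  pairDiff <- matrix(FALSE, ncol(pairs), nc)
  for (q in seq_len(ncol(pairs))) {
    g1 <- pairs[1, q]; g2 <- pairs[2, q]
    both <- fl$groupConsistent[g1, ] & fl$groupConsistent[g2, ]
    pairDiff[q, ] <- both & fl$consensus[g1, ] != fl$consensus[g2, ]
  }
  anyDiff <- if (nrow(pairDiff)) colSums(pairDiff) > 0L else rep(FALSE, nc)
  gapCol <- colSums(aln == "-") > 0L

  cumBad <- c(0L, cumsum(grpBad))
  cumVar <- c(0L, cumsum(varAll))
  cp <- matrix(apply(pairDiff, 1L, function(x) cumsum(as.integer(x))),
               nrow = nc)
  cumPair <- rbind(0L, cp)
  cumAny <- c(0L, cumsum(anyDiff))
  cumGap <- c(0L, cumsum(gapCol))

  cand <- list()
  tally <- c(group_inconsistent = 0L, no_pair_separation = 0L,
             flank_variable = 0L)
  for (L in seq(minLen, maxLen)) {
    starts <- seq_len(nc - L + 1L)
    ends <- starts + L - 1L
    okA <- (cumBad[ends + 1L] - cumBad[starts]) == 0L
    leftVar <- cumVar[starts + flankLen] - cumVar[starts]
    rightVar <- cumVar[ends + 1L] - cumVar[ends + 1L - flankLen]
    okC <- leftVar <= maxFlankMismatch & rightVar <= maxFlankMismatch
    iS <- starts + flankLen; iE <- ends - flankLen   # interior bounds
    okB <- rep(TRUE, length(starts))
    for (q in seq_len(ncol(pairs))) {
      cnt <- cumPair[iE + 1L, q] - cumPair[iS, q]
      okB <- okB & cnt > 0L
    }
    tally["group_inconsistent"] <- tally["group_inconsistent"] + sum(!okA)
    tally["no_pair_separation"] <- tally["no_pair_separation"] +
      sum(okA & !okB)
    tally["flank_variable"] <- tally["flank_variable"] + sum(okA & okB & !okC)
    ok <- which(okA & okB & okC)
    if (length(ok))
      cand[[length(cand) + 1L]] <- data.frame(
        start = starts[ok], end = ends[ok], length = L,
        n_diagnostic = cumAny[iE[ok] + 1L] - cumAny[iS[ok]],
        has_indel = (cumGap[ends[ok] + 1L] - cumGap[starts[ok]]) > 0L)
  }
  if (length(cand) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_diagnostic = integer(0),
                      diagnostic_columns = character(0),
                      has_indel = logical(0))
    attr(out, "failure_tally") <- tally
    return(out)
  }
  out <- do.call(rbind, cand)
  out <- out[order(-out$n_diagnostic, out$length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  diagCols <- which(anyDiff)
  out$diagnostic_columns <- vapply(seq_len(nrow(out)), function(i) {
    cols <- diagCols[diagCols > out$start[i] + flankLen - 1L &
                     diagCols <= out$end[i] - flankLen]
    paste(cols, collapse = ",")
  }, character(1))
  out <- out[, c("start", "end", "length", "n_diagnostic",
                 "diagnostic_columns", "has_indel")]
  ampLen <- t(vapply(seq_len(nrow(out)), function(i) {
    vapply(gnames, function(g) {
      cons <- fl$consensus[g, out$start[i]:out$end[i]]
      sum(cons != "-")
    }, integer(1))
  }, integer(length(gnames))))
  colnames(ampLen) <- gnames
  attr(out, "amplicon_len") <- ampLen
  attr(out, "groups") <- gnames
  out
}

#' Propose a primer pair for a marker candidate
#'
#' Reads the two primers off the flank consensus across all aligned
#' sequences, writing an IUPAC ambiguity code at each variable flank column
#' (a degenerate pool anneals to every panel member); a flank needing more
#' than `maxDegenerate` ambiguous positions is rejected. Pairs outside the
#' length, Tm or Tm-balance constraints are dropped.
#'
#' @param candidate one row of the [scanDiagnosticWindows()] result (or a
#'   list with `start` and `end`).
#' @param aln the alignment the candidate came from.
#' @param flankLen flank length used in the scan.
#' @param tmRange allowed primer Tm range, degrees C.
#' @param maxTmDiff maximum |Tm(fwd) - Tm(rev)|.
#' @param maxDegenerate maximum IUPAC-degenerate positions per primer.
#' @param NaMM,strandConcM Tm convention (see [primerTm()]).
#' @return `data.frame` with `fwd`, `rev`, `tm_fwd`, `tm_rev`,
#'   `degenerate_positions`; zero rows (with attribute `"reason"`) when the
#'   candidate yields no acceptable pair.
#' @export
proposePrimerPairs <- function(candidate, aln, flankLen = 18L,
                               tmRange = c(50, 65), maxTmDiff = 3,
                               maxDegenerate = 3L, NaMM = 100,
                               strandConcM = 10^-6.2) {
  s <- candidate$start[1L]; e <- candidate$end[1L]
  consensusOf <- function(cols) {
    sub <- aln[, cols, drop = FALSE]
    if (any(sub == "-")) return(NULL)
    masks <- apply(sub, 2L, function(col)
      Reduce(bitwOr, unname(.IUPAC_BITS[col])))
    list(seq = .decodeDNA(masks),
         nDeg = sum(vapply(seq_len(ncol(sub)), function(j)
           length(unique(sub[, j])) > 1L, logical(1))))
  }
  empty <- function(reason) {
    out <- data.frame(fwd = character(0), rev = character(0),
                      tm_fwd = numeric(0), tm_rev = numeric(0),
                      degenerate_positions = integer(0))
    attr(out, "reason") <- reason
    out
  }
  fwd <- consensusOf(s:(s + flankLen - 1L))
  rv <- consensusOf((e - flankLen + 1L):e)
  if (is.null(fwd) || is.null(rv)) return(empty("gap in primer flank"))
  if (fwd$nDeg > maxDegenerate || rv$nDeg > maxDegenerate)
    return(empty(sprintf("flank needs > %d degenerate positions",
                         maxDegenerate)))
  revSeq <- reverseComplementIUPAC(rv$seq)
  if (flankLen < 18L || flankLen > 26L)
    return(empty("primer length outside 18-26"))
  tmF <- primerTm(fwd$seq, NaMM, strandConcM)
  tmR <- primerTm(revSeq, NaMM, strandConcM)
  if (tmF < tmRange[1] || tmF > tmRange[2] ||
      tmR < tmRange[1] || tmR > tmRange[2])
    return(empty("primer Tm outside range"))
  if (abs(tmF - tmR) > maxTmDiff) return(empty("Tm imbalance"))
  data.frame(fwd = fwd$seq, rev = revSeq, tm_fwd = unname(tmF),
             tm_rev = unname(tmR),
             degenerate_positions = fwd$nDeg + rv$nDeg)
}

#' Predicted separability of groups over a marker candidate
#'
#' For every group pair: percent identity over the window (columns where
#' either group consensus has a gap count as differences) and the absolute
#' difference of simulated melting temperatures of the group consensus
#' amplicons (gaps removed). A pair is flagged HRM-separable when its
#' simulated |dTm| reaches the configured Tm difference threshold or the
#' RMS distance between its simulated curves reaches the shape cut
#' `d_cut = (1 - shapeSensitivity/100) d_scale`, with `d_scale` the largest
#' pairwise curve distance among the candidate's group curves.
#'
#' @param candidate one row of the [scanDiagnosticWindows()] result.
#' @param aln alignment; `groups` named character id -> group.
#' @param groups named character, sequence id to group label.
#' @param config an [HRMConfig-class] (threshold, sensitivity, grid).
#' @param NaMM salt convention for the melt simulation.
#' @return `data.frame` per group pair: `group1`, `group2`,
#'   `identity_percent`, `delta_tm`, `rms_distance`, `separable`,
#'   `has_indel`.
#' @export
predictAssaySeparation <- function(candidate, aln, groups,
                                   config = HRMConfig(), NaMM = 100) {
  s <- candidate$start[1L]; e <- candidate$end[1L]
  fl <- .columnFlags(aln, groups)
  gnames <- fl$groups
  cons <- fl$consensus[, s:e, drop = FALSE]
  badCols <- colSums(!fl$groupConsistent[, s:e, drop = FALSE]) > 0L
  if (mean(badCols) > 0.10)
    stop("group consensus ambiguous at > 10% of candidate columns",
         call. = FALSE)
  amp <- setNames(lapply(gnames, function(g) {
    x <- cons[g, ]
    paste(x[x != "-"], collapse = "")
  }), gnames)
  curves <- lapply(amp, function(a)
    curveValues(simulateMeltCurve(a, grid = config@grid, NaMM = NaMM))[, 1L])
  tms <- vapply(amp, .ampliconTm, numeric(1), NaMM = NaMM)
  M <- do.call(cbind, curves)
  D <- as.matrix(.rmsDist(M))
  dScale <- max(D)
  dCut <- (1 - config@shapeSensitivity / 100) * dScale
  prs <- utils::combn(gnames, 2L)
  res <- lapply(seq_len(ncol(prs)), function(q) {
    g1 <- prs[1, q]; g2 <- prs[2, q]
    c1 <- cons[g1, ]; c2 <- cons[g2, ]
    match_ <- c1 == c2 & c1 != "-"
    idPct <- 100 * sum(match_) / length(c1)
    dtm <- abs(tms[[g1]] - tms[[g2]])
    rms <- D[g1, g2]
    data.frame(group1 = g1, group2 = g2, identity_percent = idPct,
               delta_tm = dtm, rms_distance = rms,
               separable = dtm >= config@tmDiffThreshold |
                 (dScale > 0 & rms >= dCut & dCut > 0),
               has_indel = nchar(amp[[g1]]) != nchar(amp[[g2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
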