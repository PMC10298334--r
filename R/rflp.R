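#' @include AllClasses.R
NULL

.BUILTIN_ENZYMES <- list(
  HindIII = list(recognition = "AAGCTT", cutOffset = 1L),  # A^AGCTT
  Sau3AI  = list(recognition = "GATC",   cutOffset = 0L),  # ^GATC
  XbaI    = list(recognition = "TCTAGA", cutOffset = 1L)   # T^CTAGA
)

#' Restriction enzyme constructor
#'
#' Builds a [RestrictionEnzyme-class], either one of the built-ins
#' (`HindIII`, `Sau3AI`, `XbaI`) by name, or a custom palindromic enzyme
#' from an explicit recognition site and cut offset. Non-palindromic sites
#' are rejected: the digest scans the top strand only, which is complete
#' exactly for palindromic sites.
#'
#' @param name enzyme name.
#' @param recognition concrete recognition site 5' to 3' (omit for a
#'   built-in).
#' @param cutOffset bases from the site's 5' start to the top-strand cut.
#' @return a [RestrictionEnzyme-class].
#' @examples
#' restrictionEnzyme("Sau3AI")
#' restrictionEnzyme("EcoRI", "GAATTC", 1L)
#' @export
restrictionEnzyme <- function(name, recognition = NULL, cutOffset = NULL) {
  if (is.null(recognition)) {
    spec <- .BUILTIN_ENZYMES[[name]]
    if (is.null(spec))
      stop("unknown enzyme '", name, "'; built-ins: ",
           paste(names(.BUILTIN_ENZYMES), collapse = ", "), call. = FALSE)
    recognition <- spec$recognition
    cutOffset <- spec$cutOffset
  }
  new("RestrictionEnzyme", name = name, recognition = toupper(recognition),
      cutOffset = as.integer(cutOffset))
}

#' Digest a linear sequence with a restriction enzyme
#'
#' Cuts the top strand at `site start + cutOffset` for every occurrence of
#' the recognition sequence. Fragment lengths always sum to the input
#' length; a sequence without sites yields one full-length fragment.
#' Fragments under `gelFloor` bases are retained but flagged as possibly
#' unresolvable on an agarose gel.
#'
#' @param seq concrete linear DNA (character or `DNAString`); ambiguity codes
#'   are an error, as digestion operates on realized amplicons.
#' @param enzyme a [RestrictionEnzyme-class] or built-in enzyme name.
#' @param gelFloor resolution floor in bases (default 40).
#' @return a [DigestPattern-class].
#' @examples
#' fragments(digestSequence("AAAGATCCCGATCTT", "Sau3AI"))  # 6 6 3
#' @export
digestSequence <- function(seq, enzyme, gelFloor = 40L) {
  if (is.character(enzyme)) enzyme <- restrictionEnzyme(enzyme)
  seq <- .canonicalizeBases(as.character(seq), what = "digest input")
  if (!grepl("^[ACGT]+$", seq))
    stop("digest operates on concrete sequences (no ambiguity codes)",
         call. = FALSE)
  L <- nchar(seq)
  starts <- unlist(gregexpr(enzyme@recognition, seq, fixed = TRUE))
  starts <- starts[starts > 0L]
  cuts <- sort(unique(starts + enzyme@cutOffset - 1L))  # cut after this base
  cuts <- cuts[cuts >= 1L & cuts < L]
  bounds <- c(0L, cuts, L)
  frag <- as.integer(diff(bounds))
  ord <- order(frag, decreasing = TRUE)
  new("DigestPattern", enzyme = enzyme@name, inputLength = L,
      fragments = frag[ord], cutPositions = as.integer(cuts),
      subResolution = frag[ord] < gelFloor)
}

#' Greedy band matching between an observed and a predicted pattern
#'
#' Pairs observed gel bands one-to-one with predicted fragments when the
#' observed size lies within `relTol` of the predicted size (gel read-off is
#' approximate; the default 12% reflects ladder-based size estimation).
#' Score is matched pairs over the larger pattern size, so 1.0 means the
#' patterns are identical at tolerance.
#'
#' @param observed numeric vector of observed band sizes.
#' @param predicted a [DigestPattern-class] or numeric fragment vector.
#' @param relTol relative tolerance, in (0, 1).
#' @return match score in `[0, 1]`.
#' @export
matchBands <- function(observed, predicted, relTol = 0.12) {
  if (methods::is(predicted, "DigestPattern")) predicted <- predicted@fragments
  if (length(observed) == 0L) stop("observed bands must be non-empty",
                                   call. = FALSE)
  if (relTol <= 0 || relTol >= 1) stop("relTol must be in (0, 1)",
                                       call. = FALSE)
  pred <- sort(predicted, decreasing = TRUE)
  obs <- observed
  used <- logical(length(obs))
  matched <- 0L
  for (p in pred) {
    cand <- which(!used & abs(obs - p) <= relTol * p)
    if (length(cand)) {
      pick <- cand[which.min(abs(obs[cand] - p))]
      used[pick] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / max(length(obs), length(pred))
}

#' Digest patterns per group, with a discriminability verdict
#'
#' Digests one representative amplicon per group and lists every pair of
#' groups whose band patterns cannot be told apart at the gel tolerance —
#' the in silico counterpart of discovering that two taxa share a digest
#' pattern and the assay cannot separate them.
#'
#' @param amplicons named character vector or `DNAStringSet` of group
#'   amplicons; names are group labels (the first sequence per label
#'   represents the group).
#' @param enzyme [RestrictionEnzyme-class] or built-in name.
#' @param relTol band-matching tolerance (see [matchBands()]).
#' @return list: `patterns` (named list of [DigestPattern-class]) and
#'   `indistinguishable` (`data.frame` of group pairs with match score 1 at
#'   tolerance).
#' @export
rflpKey <- function(amplicons, enzyme, relTol = 0.12) {
  seqs <- as.character(amplicons)
  names(seqs) <- names(amplicons)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("amplicons must carry group labels as names", call. = FALSE)
  groups <- unique(names(seqs))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  patterns <- lapply(groups, function(g)
    digestSequence(seqs[[which(names(seqs) == g)[1L]]], enzyme))
  names(patterns) <- groups
  pairs <- utils::combn(groups, 2L)
  same <- apply(pairs, 2L, function(p) {
    a <- patterns[[p[1]]]@fragments
    b <- patterns[[p[2]]]@fragments
    matchBands(a, b, relTol) >= 1 && matchBands(b, a, relTol) >= 1
  })
  list(patterns = patterns,
       indistinguishable = data.frame(group1 = pairs[1L, same],
                                      group2 = pairs[2L, same],
                                      stringsAsFactors = FALSE))
}
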