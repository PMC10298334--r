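# IUPAC nucleotide semantics shared by the whole package.
#
# Bases are encoded as 4-bit masks (A=1, C=2, G=4, T=8); an ambiguity code is
# the union of its degeneracy set. A primer base is compatible with a template
# base iff the template's set is contained in the primer's set, which reduces
# to a bitwAnd test and also gives the rule for ambiguous template positions.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_ALPHABET <- names(.IUPAC_BITS)

# inverse lookup: bitmask -> IUPAC letter
.BITS_IUPAC <- character(15L)
.BITS_IUPAC[.IUPAC_BITS] <- names(.IUPAC_BITS)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# Canonicalize a nucleotide string: uppercase, U -> T, validate alphabet.
# `allowGaps` admits '-' (alignment rows); '.' is always rejected.
.canonicalizeBases <- function(x, allowGaps = FALSE, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "T", chartr("U", "T", toupper(x)))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  ok <- chars %in% .IUPAC_ALPHABET
  if (allowGaps) ok <- ok | chars == "-"
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("illegal character '%s' at position %d in %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  x
}

.encodeDNA <- function(x) {
  unname(.IUPAC_BITS[strsplit(x, "", fixed = TRUE)[[1]]])
}

.decodeDNA <- function(bits) {
  paste(.BITS_IUPAC[bits], collapse = "")
}

#' Test whether a primer base can pair a concrete template base
#'
#' A degenerate (IUPAC) primer base matches a template base when the template
#' base belongs to the primer base's degeneracy set; for example \code{"R"}
#' (A/G) matches \code{"A"} but not \code{"C"}. Template bases must be
#' concrete (A, C, G or T): primer degeneracy expresses an oligo pool, while
#' a template molecule has a definite base at every position.
#'
#' @param primerBase single IUPAC character (A, C, G, T, R, Y, S, W, K, M,
#'   B, D, H, V or N).
#' @param templateBase single concrete base: A, C, G or T.
#' @return `TRUE` iff `templateBase` is in the degeneracy set of `primerBase`.
#' @examples
#' iupacMatch("R", "A")  # TRUE
#' iupacMatch("R", "C")  # FALSE
#' iupacMatch("N", "T")  # TRUE
#' @export
iupacMatch <- function(primerBase, templateBase) {
  primerBase <- .canonicalizeBases(primerBase, what = "primer base")
  templateBase <- .canonicalizeBases(templateBase, what = "template base")
  if (nchar(primerBase) != 1L || nchar(templateBase) != 1L)
    stop("iupacMatch() compares single bases", call. = FALSE)
  tb <- .IUPAC_BITS[[templateBase]]
  if (!templateBase %in% c("A", "C", "G", "T"))
    stop("template base must be concrete (A, C, G or T), got '",
         templateBase, "'", call. = FALSE)
  pb <- .IUPAC_BITS[[primerBase]]
  bitwAnd(pb, tb) == tb
}

#' Reverse complement of an IUPAC DNA string
#'
#' IUPAC-aware: ambiguity codes map to the code of the complementary set
#' (R to Y, K to M, S and W to themselves, B to V, D to H, N to N). The
#' operation is an involution: applying it twice returns the input.
#'
#' @param x a single DNA string (IUPAC alphabet; 'U' accepted and read as 'T').
#' @return the reverse-complemented string, uppercase.
#' @examples
#' reverseComplementIUPAC("ACGT")  # "ACGT"
#' reverseComplementIUPAC("AAR")   # "YTT"
#' @export
reverseComplementIUPAC <- function(x) {
  x <- .canonicalizeBases(x, what = "sequence")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

# All concrete expansions of a degenerate sequence (capped).
.expandDegenerate <- function(x, cap = 64L) {
  sets <- strsplit(c(A = "A", C = "C", G = "G", T = "T",
                     R = "AG", Y = "CT", S = "CG", W = "AT",
                     K = "GT", M = "AC", B = "CGT", D = "AGT",
                     H = "ACT", V = "ACG", N = "ACGT")[
                       strsplit(x, "", fixed = TRUE)[[1]]], "", fixed = TRUE)
  n <- prod(lengths(sets))
  if (n > cap)
    stop(sprintf("degenerate sequence expands to %d > %d variants", n, cap),
         call. = FALSE)
  if (n == 1L) return(x)
  grid <- expand.grid(sets, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  apply(grid[, seq_along(sets), drop = FALSE], 1L, paste, collapse = "")
}
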