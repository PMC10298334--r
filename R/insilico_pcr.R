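#' @include iupac.R
NULL

# Count primer/template incompatibilities at every ungapped offset.
# `tmpl`, `prm` are bitmask vectors. A position matches when the template
# base's degeneracy set is contained in the primer base's set; an ambiguous
# template base therefore counts as a mismatch unless the primer base covers
# every base it could be.
.mismatchProfile <- function(tmpl, prm) {
  n <- length(tmpl); m <- length(prm)
  if (m > n) return(list(total = integer(0), perPos = NULL))
  nw <- n - m + 1L
  mm <- matrix(FALSE, nrow = nw, ncol = m)
  for (j in seq_len(m)) {
    tj <- tmpl[j:(j + nw - 1L)]
    mm[, j] <- bitwAnd(tj, prm[j]) != tj
  }
  list(total = as.integer(rowSums(mm)), perPos = mm)
}

#' Locate degenerate-primer binding sites on a template
#'
#' Scans both strands for ungapped alignments of the primer with at most
#' `maxMismatches` incompatible positions and none inside the 3'-terminal
#' `clampLen` bases (the polymerase extension end). Matching is
#' IUPAC-degeneracy aware (see [iupacMatch()]); ambiguity codes in the
#' template count as mismatches unless the primer base's set covers them.
#' Circular templates are scanned across the origin; such sites report a
#' start beyond the origin-unwrapped end.
#'
#' @param template template sequence (character or `DNAString`).
#' @param primer primer sequence, 5' to 3' (character or `DNAString`).
#' @param maxMismatches maximum mismatches outside the clamp (default 2).
#' @param clampLen 3'-terminal bases that must match exactly (default 3).
#' @param circular treat the template as circular.
#' @param templateId id used in the report.
#' @return `data.frame` with columns `template_id`, `start` (1-based
#'   position of the 5'-most template base covered), `end`, `strand`,
#'   `mismatches`, `three_prime_mismatch`.
#' @export
findBindingSites <- function(template, primer, maxMismatches = 2L,
                             clampLen = 3L, circular = FALSE,
                             templateId = "template") {
  if (maxMismatches < 0 || clampLen < 0)
    stop("maxMismatches and clampLen must be non-negative", call. = FALSE)
  template <- .canonicalizeBases(as.character(template), what = "template")
  primer <- .canonicalizeBases(as.character(primer), what = "primer")
  L <- nchar(template); m <- nchar(primer)
  clampLen <- min(as.integer(clampLen), m)
  scan <- if (circular && L >= m) {
    paste0(template, substr(template, 1L, m - 1L))
  } else template
  tmpl <- .encodeDNA(scan)
  pF <- .encodeDNA(primer)
  pR <- .encodeDNA(reverseComplementIUPAC(primer))

  res <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pF else pR
    prof <- .mismatchProfile(tmpl, p)
    if (length(prof$total) == 0L) next
    # clamp columns: 3' end of the primer sits at the window end on '+',
    # at the window start on '-'
    clampCols <- if (clampLen == 0L) integer(0)
      else if (strand == "+") (m - clampLen + 1L):m else 1:clampLen
    clampMM <- if (length(clampCols))
      as.integer(rowSums(prof$perPos[, clampCols, drop = FALSE]))
      else integer(length(prof$total))
    hit <- which(prof$total <= maxMismatches & clampMM == 0L)
    if (circular) hit <- hit[hit <= L]
    if (length(hit))
      res[[strand]] <- data.frame(
        template_id = templateId, start = hit, end = hit + m - 1L,
        strand = strand, mismatches = prof$total[hit],
        three_prime_mismatch = clampMM[hit] > 0L,
        stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0),
                      three_prime_mismatch = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR products of a primer pair on a template
#'
#' Pairs every forward-primer site on the plus strand with every
#' reverse-primer site on the minus strand downstream of it. Product length
#' follows the gel convention and counts both primer footprints: 5' end of
#' the forward site through the 5' end of the reverse site, inclusive, so a
#' full amplicon of a 706 bp assay reports 706. Circular templates amplify
#' across the origin.
#'
#' @param template template sequence; character, `DNAString`, or a one-record
#'   `DNAStringSet` whose `topology` metadata marks circularity.
#' @param fwd,rev primer sequences 5' to 3' (character or `DNAString`);
#'   optionally named via `fwdName`/`revName`.
#' @param maxMismatches,clampLen see [findBindingSites()].
#' @param maxProduct largest product length searched (default 3000).
#' @param circular treat template as circular (overridden by `DNAStringSet`
#'   metadata when present).
#' @param templateId,fwdName,revName report labels.
#' @return `data.frame` sorted by decreasing length with columns
#'   `template_id`, `fwd_primer`, `rev_primer`, `start`, `end` (1-based
#'   inclusive; `end` may exceed the template length for origin-spanning
#'   products), `length`, `fwd_mismatches`, `rev_mismatches`, `sequence`.
#' @export
amplify <- function(template, fwd, rev, maxMismatches = 2L, clampLen = 3L,
                    maxProduct = 3000L, circular = FALSE,
                    templateId = "template", fwdName = "fwd",
                    revName = "rev") {
  if (methods::is(template, "DNAStringSet")) {
    if (length(template) != 1L)
      stop("amplify() expects a single template", call. = FALSE)
    mc <- S4Vectors::mcols(template)
    if (!is.null(mc$topology)) circular <- mc$topology[1L] == "circular"
    if (!is.null(names(template))) templateId <- names(template)[1L]
    template <- as.character(template[[1L]])
  }
  template <- .canonicalizeBases(as.character(template), what = "template")
  L <- nchar(template)
  fseq <- as.character(fwd); rseq <- as.character(rev)
  fsites <- findBindingSites(template, fseq, maxMismatches, clampLen,
                             circular, templateId)
  rsites <- findBindingSites(template, rseq, maxMismatches, clampLen,
                             circular, templateId)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]
  out <- list()
  unwrapped <- if (circular) paste0(template, template) else template
  for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
    s <- fsites$start[i]          # forward 5' end
    e <- rsites$end[j]            # reverse 5' end (rightmost covered base)
    if (circular && e < s) e <- e + L   # product wraps the origin
    len <- e - s + 1L
    if (e <= s) next
    if (len < max(nchar(fseq), nchar(rseq))) next
    if (len > maxProduct) next
    if (circular && len > L) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = templateId, fwd_primer = fwdName, rev_primer = revName,
      start = s, end = e, length = len,
      fwd_mismatches = fsites$mismatches[i],
      rev_mismatches = rsites$mismatches[j],
      sequence = substr(unwrapped, s, e), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(template_id = character(0), fwd_primer = character(0),
                      rev_primer = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(-res$length, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict the product pattern of a multiplex PCR
#'
#' Runs [amplify()] for each primer pair and merges the products,
#' deduplicated by (pair, length). The `pattern_key` — the product lengths
#' sorted decreasing — is the in silico analogue of the species-diagnostic
#' band pattern on a gel lane.
#'
#' @param template as in [amplify()].
#' @param pairs named list; each element `c(fwd_name, rev_name)` referring to
#'   rows of `primers`.
#' @param primers primer table (`data.frame` with `name`, `sequence`) as from
#'   [loadPrimerTable()].
#' @param ... passed to [amplify()].
#' @return list with `template_id`, `products` (`data.frame`: pair, length,
#'   start, end) and `pattern_key` (numeric, sorted decreasing).
#' @export
multiplexPredict <- function(template, pairs, primers, ...) {
  if (length(pairs) == 0L) stop("at least one primer pair required",
                                call. = FALSE)
  getSeq <- function(nm) {
    i <- match(nm, primers$name)
    if (is.na(i)) stop("primer '", nm, "' not in primer table", call. = FALSE)
    primers$sequence[i]
  }
  prods <- list()
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    pname <- if (!is.null(names(pairs)) && nzchar(names(pairs)[k]))
      names(pairs)[k] else paste(p[1], p[2], sep = ":")
    amp <- amplify(template, getSeq(p[1]), getSeq(p[2]),
                   fwdName = p[1], revName = p[2], ...)
    if (nrow(amp))
      prods[[length(prods) + 1L]] <- data.frame(
        pair = pname, length = amp$length, start = amp$start, end = amp$end,
        stringsAsFactors = FALSE)
  }
  products <- if (length(prods)) unique(do.call(rbind, prods))
    else data.frame(pair = character(0), length = integer(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  products <- products[!duplicated(products[c("pair", "length")]), ,
                       drop = FALSE]
  rownames(products) <- NULL
  tid <- if (methods::is(template, "DNAStringSet") &&
             !is.null(names(template))) names(template)[1L] else "template"
  list(template_id = tid, products = products,
       pattern_key = sort(products$length, decreasing = TRUE))
}
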