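#' @include iupac.R
NULL

# -- sequence I/O -------------------------------------------------------------

#' Read reference sequences from FASTA or GenBank flat files
#'
#' Returns a `DNAStringSet` with uppercase bases ('U' read as 'T') and
#' per-record metadata columns `topology` ("linear" or "circular"),
#' `species_label` and `group_label`. FASTA ids are taken verbatim up to the
#' first whitespace. GenBank flat files contribute the accession as id and
#' the LOCUS-line topology, so a complete circular mitogenome loads with
#' `topology == "circular"`; features are ignored. With `aligned = TRUE` a
#' gapped FASTA is read as an alignment (see [loadAlignment()]).
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`.
#' @param aligned read a gapped FASTA as an alignment matrix instead.
#' @return `DNAStringSet` with metadata columns, or a character matrix when
#'   `aligned = TRUE`.
#' @export
loadSequences <- function(path, format = c("fasta", "genbank"),
                          aligned = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (aligned) {
    if (format != "fasta") stop("alignments are FASTA-only", call. = FALSE)
    return(loadAlignment(path))
  }
  if (format == "fasta") .loadFasta(path) else .loadGenbank(path)
}

.loadFasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    paste(body[!grepl("^>", body)], collapse = "")
  }, character(1))
  seqs <- vapply(seq_along(seqs), function(i)
    .canonicalizeBases(seqs[i], what = sprintf("record '%s'", ids[i])),
    character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    topology = rep("linear", length(out)),
    species_label = NA_character_, group_label = NA_character_)
  out
}

# Minimal GenBank flat-file reader: LOCUS name + topology, ACCESSION if
# present, and the ORIGIN sequence block. Feature tables are skipped.
.loadGenbank <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  if (length(recs) == 0L)
    stop("no LOCUS record in '", path, "'", call. = FALSE)
  ids <- character(0); seqs <- character(0); topo <- character(0)
  for (rec in recs) {
    locus <- strsplit(trimws(rec[1L]), "\\s+")[[1]]
    id <- locus[2L]
    acc <- grep("^ACCESSION", rec, value = TRUE)
    if (length(acc)) {
      accId <- strsplit(trimws(acc[1L]), "\\s+")[[1]][2L]
      if (!is.na(accId) && nzchar(accId)) id <- accId
    }
    t <- if (any(grepl("circular", rec[1L], ignore.case = TRUE)))
      "circular" else "linear"
    ori <- grep("^ORIGIN", rec)
    if (length(ori) == 0L)
      stop("record '", id, "' has no ORIGIN block", call. = FALSE)
    stop_at <- grep("^//", rec)
    stop_at <- stop_at[stop_at > ori[1L]][1L]
    if (is.na(stop_at)) stop_at <- length(rec) + 1L
    body <- rec[seq(ori[1L] + 1L, stop_at - 1L)]
    s <- gsub("[0-9[:space:]/]", "", paste(body, collapse = ""))
    ids <- c(ids, id)
    seqs <- c(seqs, .canonicalizeBases(s, what = sprintf("record '%s'", id)))
    topo <- c(topo, t)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    topology = topo, species_label = NA_character_,
    group_label = NA_character_)
  out
}

#' Write sequences to FASTA
#'
#' Round-trip companion of [loadSequences()]: `loadSequences(writeSequences(x))`
#' preserves ids and bases.
#'
#' @param x `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a gapped FASTA alignment
#'
#' The only gap character accepted is '-'; '.' is rejected so that a single
#' alignment dialect is in force. All rows must have equal length.
#'
#' @param path FASTA path.
#' @return character matrix, one row per sequence (rownames are ids), one
#'   column per alignment column.
#' @export
loadAlignment <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1L] - 1L, length(lines))
  rows <- lapply(seq_along(hdr), function(i) {
    s <- paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
    if (grepl(".", s, fixed = TRUE))
      stop("'.' gaps are not accepted; use '-' (record '", ids[i], "')",
           call. = FALSE)
    s <- .canonicalizeBases(s, allowGaps = TRUE,
                            what = sprintf("record '%s'", ids[i]))
    strsplit(s, "", fixed = TRUE)[[1]]
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Drop gaps from alignment rows
#'
#' @param aln character matrix as returned by [loadAlignment()].
#' @return `DNAStringSet` of the ungapped row sequences.
#' @export
alignmentToSequences <- function(aln) {
  seqs <- apply(aln, 1L, function(r) paste(r[r != "-"], collapse = ""))
  Biostrings::DNAStringSet(seqs)
}

# -- tabular I/O --------------------------------------------------------------

.PANEL_COUNT_COLS <- c("n_total", "n_fc", "n_fm_sm", "n_re", "n_frozen",
                       "n_cooked")
.PANEL_COLS <- c("species", "sample_id", "region", "fao_region",
                 .PANEL_COUNT_COLS)

#' Read primer, sample-panel or melt-curve tables
#'
#' One loader per delimited-text schema used across the workflow:
#' \describe{
#'   \item{primers}{columns `name`, `sequence`, `tm` (blank Tm allowed);
#'     sequences are IUPAC, length >= 10, reported Tm inside (30, 80).}
#'   \item{panel}{the market-survey bookkeeping schema: `species`,
#'     `sample_id`, `region`, `fao_region` and the count columns `n_total`,
#'     `n_fc`, `n_fm_sm`, `n_re`, `n_frozen`, `n_cooked`. Blank counts read
#'     as 0, blank regions as empty text, mirroring how such tables print.}
#'   \item{curves}{column `temperature_C` plus one column per sample id;
#'     returns a [MeltCurveSet-class].}
#' }
#'
#' @param path delimited text file (tab separated).
#' @param kind one of `"primers"`, `"panel"`, `"curves"`.
#' @return a `data.frame` (primers, panel) or [MeltCurveSet-class] (curves).
#' @export
loadTables <- function(path, kind = c("primers", "panel", "curves")) {
  kind <- match.arg(kind)
  switch(kind,
         primers = loadPrimerTable(path),
         panel = loadPanelTable(path),
         curves = loadCurveTable(path))
}

#' @rdname loadTables
#' @export
loadPrimerTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  need <- c("name", "sequence", "tm")
  if (!all(need %in% names(df)))
    stop("primer table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(name = character(0), sequence = character(0),
                      tm = numeric(0), stringsAsFactors = FALSE))
  seqs <- vapply(seq_len(nrow(df)), function(i)
    .canonicalizeBases(df$sequence[i],
                       what = sprintf("primer '%s'", df$name[i])),
    character(1))
  short <- nchar(seqs) < 10L
  if (any(short))
    stop("primer '", df$name[which(short)[1]], "' is shorter than 10 nt",
         call. = FALSE)
  tm <- suppressWarnings(as.numeric(df$tm))
  bad <- !is.na(df$tm) & nzchar(trimws(df$tm)) & is.na(tm)
  if (any(bad))
    stop("non-numeric tm in primer table row ", which(bad)[1], call. = FALSE)
  out_of_range <- !is.na(tm) & (tm <= 30 | tm >= 80)
  if (any(out_of_range))
    stop("reported tm out of (30, 80) degC in row ", which(out_of_range)[1],
         call. = FALSE)
  data.frame(name = df$name, sequence = seqs, tm = tm,
             stringsAsFactors = FALSE)
}

#' @rdname loadTables
#' @export
loadPanelTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  if (!all(.PANEL_COLS %in% names(df)))
    stop("panel table must have columns: ",
         paste(.PANEL_COLS, collapse = ", "), call. = FALSE)
  df <- df[, .PANEL_COLS]
  for (cc in .PANEL_COUNT_COLS) {
    raw <- trimws(df[[cc]])
    raw[!nzchar(raw)] <- "0"
    val <- suppressWarnings(as.integer(raw))
    if (anyNA(val))
      stop("non-numeric count in column '", cc, "', row ",
           which(is.na(val))[1], call. = FALSE)
    if (any(val < 0))
      stop("negative count in column '", cc, "'", call. = FALSE)
    df[[cc]] <- val
  }
  over <- df[setdiff(.PANEL_COUNT_COLS, "n_total")] > df$n_total
  if (any(over))
    stop("sub-count exceeds n_total in row ", which(rowSums(over) > 0)[1],
         call. = FALSE)
  df
}

#' @rdname loadTables
#' @export
loadCurveTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"temperature_C" %in% names(df))
    stop("curve table must have a 'temperature_C' column", call. = FALSE)
  samples <- setdiff(names(df), "temperature_C")
  if (length(samples) == 0L)
    stop("curve table has no sample columns", call. = FALSE)
  m <- as.matrix(df[, samples, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric fluorescence values", call. = FALSE)
  MeltCurveSet(df$temperature_C, m)
}

#' Write a MeltCurveSet as a delimited curve table
#'
#' @param x [MeltCurveSet-class] or [NormalizedCurveSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCurveTable <- function(x, path) {
  df <- data.frame(temperature_C = temperatures(x), check.names = FALSE)
  df <- cbind(df, as.data.frame(curveValues(x), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
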