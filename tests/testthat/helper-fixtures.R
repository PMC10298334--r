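# Shared fixtures and independent oracles, built in code at test time.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# first concrete expansion of a degenerate oligo (used to embed a primer
# footprint into a synthetic template)
concretize <- function(x) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C", S = "C",
           W = "A", K = "G", M = "A", B = "C", D = "A", H = "A", V = "A",
           N = "A")
  paste(map[strsplit(x, "", fixed = TRUE)[[1]]], collapse = "")
}

# synthetic template carrying one planted amplicon of exactly `len` bases
# (both primer footprints included), flanked by random padding
plant_amplicon <- function(fwd, rev, len, padLeft = 30, padRight = 30) {
  core <- len - nchar(fwd) - nchar(rev)
  stopifnot(core >= 0)
  paste0(rand_dna(padLeft), concretize(fwd), rand_dna(core),
         reverseComplementIUPAC(concretize(rev)), rand_dna(padRight))
}

# brute-force binding-site oracle: scan every offset on both strands with
# per-base iupacMatch, no clamp shortcuts shared with the implementation
brute_sites <- function(template, primer, maxMismatches, clampLen,
                        circular = FALSE) {
  L <- nchar(template)
  scan <- if (circular) paste0(template, substr(template, 1, nchar(primer) - 1))
          else template
  out <- NULL
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else reverseComplementIUPAC(primer)
    pc <- strsplit(p, "", fixed = TRUE)[[1]]
    m <- length(pc)
    if (m > nchar(scan)) next
    for (s in seq_len(nchar(scan) - m + 1)) {
      win <- strsplit(substr(scan, s, s + m - 1), "", fixed = TRUE)[[1]]
      ok <- logical(m)
      for (j in seq_len(m)) {
        ok[j] <- win[j] %in% c("A", "C", "G", "T") && iupacMatch(pc[j], win[j])
      }
      mm <- sum(!ok)
      clampIdx <- if (clampLen == 0) integer(0)
                  else if (strand == "+") (m - clampLen + 1):m
                  else 1:clampLen
      if (mm <= maxMismatches && all(ok[clampIdx]) && (!circular || s <= L))
        out <- rbind(out, data.frame(start = s, strand = strand,
                                     mismatches = mm))
    }
  }
  if (is.null(out)) data.frame(start = integer(0), strand = character(0),
                               mismatches = integer(0))
  else out[order(out$start, out$strand), , drop = FALSE]
}

# brute-force diagnostic-window validator: enumerate every window and check
# the three constraints by direct column comparison
brute_windows <- function(aln, groups, minLen, maxLen, flankLen,
                          maxFlankMismatch) {
  nc <- ncol(aln)
  gl <- split(rownames(aln), groups[rownames(aln)])
  gnames <- names(gl)
  prs <- combn(gnames, 2)
  res <- NULL
  for (L in minLen:maxLen) for (s in seq_len(nc - L + 1)) {
    e <- s + L - 1
    win <- aln[, s:e, drop = FALSE]
    okA <- all(vapply(gl, function(mem) {
      sub <- win[mem, , drop = FALSE]
      all(apply(sub, 2, function(col) length(unique(col)) == 1))
    }, logical(1)))
    if (!okA) next
    flankL <- win[, 1:flankLen, drop = FALSE]
    flankR <- win[, (L - flankLen + 1):L, drop = FALSE]
    nvar <- function(m) sum(apply(m, 2, function(col)
      length(unique(col)) > 1))
    if (nvar(flankL) > maxFlankMismatch || nvar(flankR) > maxFlankMismatch)
      next
    interior <- win[, (flankLen + 1):(L - flankLen), drop = FALSE]
    okB <- all(apply(prs, 2, function(p) {
      c1 <- interior[gl[[p[1]]][1], ]
      c2 <- interior[gl[[p[2]]][1], ]
      any(c1 != c2)
    }))
    if (!okB) next
    res <- rbind(res, data.frame(start = s, end = e, length = L))
  }
  if (is.null(res)) data.frame(start = integer(0), end = integer(0),
                               length = integer(0)) else res
}

# direct two-state curve with a chosen Tm (independent of the thermo module)
synth_curve <- function(tmC, temps = seq(65, 95, by = 0.2), dH = 9e5,
                        noise = 0, baseline = c(0, 0)) {
  tk <- temps + 273.15
  theta <- 1 / (1 + exp((dH / 1.987) * (1 / (tmC + 273.15) - 1 / tk)))
  pmax(100 * theta + baseline[1] + baseline[2] * (temps - temps[1]) +
         rnorm(length(temps), 0, noise), 0)
}

fixture_path <- function(f) system.file("extdata", f, package = "meltmark")
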