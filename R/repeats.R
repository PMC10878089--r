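#' @include AllClasses.R
NULL

# Hamming mismatch count between two equal-length strings
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Detect a telomeric tandem repeat at one end of a linear genome
#'
#' Linear ciliate mitogenomes are capped by tandem repeats whose unit length
#' varies widely between species (tens to >100 bp, with copy numbers from
#' under twenty to several hundred). The detector reports the smallest period
#' `p <= maxUnit` such that the terminal sequence consists of at least
#' `minCopies` tandem copies of the terminal `p`-mer, allowing a per-copy
#' Hamming mismatch fraction up to `tolerance`. The smallest-period rule makes
#' the reported unit the primitive repeat unit.
#'
#' @param genome a [Mitogenome-class] (or plain nucleotide string).
#' @param end `"5prime"` or `"3prime"`.
#' @param maxUnit largest unit length considered, bp (default 150, covering
#'   observed ciliate units).
#' @param minCopies minimum tandem copy count to call a telomere (default 5).
#' @param tolerance per-copy mismatch fraction allowed (default 0.05).
#' @return `NULL` if no repeat qualifies; otherwise a list with `end`, `unit`,
#'   `unitLength`, `copyNumber` (fractional when a partial copy of at least
#'   half a unit continues inward), `totalLength`, `start`, `stop` (1-based
#'   genome interval) and `gc`.
#' @details Copy extension runs inward from the genome end until the next
#'   full unit exceeds the mismatch tolerance; a trailing partial copy is
#'   counted fractionally only when at least half a unit matches, so clean
#'   planted repeats are recovered with integer copy numbers. Circular
#'   genomes are rejected (unsupported topology).
#' @export
detectTelomere <- function(genome, end = c("3prime", "5prime"),
                           maxUnit = 150L, minCopies = 5L,
                           tolerance = 0.05) {
  end <- match.arg(end)
  if (is(genome, "Mitogenome")) {
    if (genomeTopology(genome) != "linear")
      .stopf("telomere detection requires a linear genome (topology '%s')",
             genomeTopology(genome))
    s <- .asChar(genomeSequence(genome))
  } else s <- toupper(as.character(genome))
  L <- nchar(s)
  if (maxUnit < 1L) .stopf("maxUnit must be >= 1")
  # scan from the 3' end; for the 5' end operate on the reversed string
  if (end == "5prime") {
    s <- paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }
  for (p in seq_len(min(maxUnit, L %/% max(2L, minCopies)))) {
    unit <- substring(s, L - p + 1L, L)
    maxMis <- floor(tolerance * p)
    copies <- 1L
    pos <- L - p  # last base of next candidate copy
    while (pos - p + 1L >= 1L) {
      cand <- substring(s, pos - p + 1L, pos)
      if (.hamming(cand, unit) > maxMis) break
      copies <- copies + 1L
      pos <- pos - p
    }
    frac <- 0
    if (pos >= 1L) {           # partial copy continuing inward?
      q <- min(pos, p)
      part <- substring(s, pos - q + 1L, pos)
      tail <- substring(unit, p - q + 1L, p)
      if (q >= max(4L, ceiling(p / 2)) && .hamming(part, tail) <= floor(tolerance * q))
        frac <- q / p
    }
    if (copies >= minCopies) {
      total <- copies * p + round(frac * p)
      startRev <- L - total + 1L
      iv <- if (end == "3prime") c(L - total + 1L, L) else c(1L, total)
      region <- substring(s, startRev, L)
      if (end == "5prime")
        unitOut <- paste(rev(strsplit(unit, "", fixed = TRUE)[[1L]]),
                         collapse = "")
      else unitOut <- unit
      return(list(end = end, unit = unitOut, unitLength = p,
                  copyNumber = copies + frac, totalLength = total,
                  start = iv[1L], stop = iv[2L], gc = .gc(region)))
    }
  }
  NULL
}

#' Detect AT-rich central-repeat (CR) regions
#'
#' CR regions of ciliate mitogenomes are internal repeat stretches of very
#' high AT content (observed 94.65%-100%), implicated in replication
#' initiation and coinciding with transcription strand switches. Windows of
#' AT content at or above `atMin` are merged, trimmed to their maximal A/T
#' extent, filtered by `minLen`, and any call overlapping a telomere interval
#' is removed.
#'
#' @param genome a [Mitogenome-class] or nucleotide string.
#' @param window window size, bp (default 100).
#' @param atMin minimum AT proportion (default 0.9465, the observed lower
#'   bound in ciliate CRs).
#' @param step window step, bp (default `window`, i.e. tiling).
#' @param minLen minimum call length, bp (default 100).
#' @param telomeres optional list of telomere calls (from [detectTelomere()])
#'   or a two-column matrix of intervals to exclude.
#' @return data.frame with columns `start`, `end`, `length`, `at` (one row
#'   per call; zero rows when nothing qualifies).
#' @export
detectCentralRepeats <- function(genome, window = 100L, atMin = 0.9465,
                                 step = window, minLen = 100L,
                                 telomeres = NULL) {
  if (atMin <= 0 || atMin > 1) .stopf("atMin must be in (0, 1]")
  s <- if (is(genome, "Mitogenome")) .asChar(genomeSequence(genome))
       else toupper(as.character(genome))
  L <- nchar(s)
  v <- strsplit(s, "", fixed = TRUE)[[1L]] %in% c("A", "T")
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), at = numeric(0))
  if (L < window) return(empty)
  starts <- seq(1L, L - window + 1L, by = step)
  at <- vapply(starts, function(i) mean(v[i:(i + window - 1L)]), numeric(1))
  ok <- at >= atMin
  if (!any(ok)) return(empty)
  # merge overlapping/adjacent qualifying windows
  ivs <- cbind(starts[ok], starts[ok] + window - 1L)
  merged <- list(ivs[1L, ])
  if (nrow(ivs) > 1L) for (i in 2L:nrow(ivs)) {
    last <- merged[[length(merged)]]
    if (ivs[i, 1L] <= last[2L] + 1L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], ivs[i, 2L]))
    } else merged[[length(merged) + 1L]] <- ivs[i, ]
  }
  calls <- lapply(merged, function(iv) {
    a <- iv[1L]; b <- iv[2L]
    while (a > 1L && v[a - 1L]) a <- a - 1L     # extend to the full A/T run
    while (b < L && v[b + 1L]) b <- b + 1L
    c(a, b)
  })
  df <- do.call(rbind, lapply(calls, function(iv)
    data.frame(start = iv[1L], end = iv[2L], length = iv[2L] - iv[1L] + 1L,
               at = mean(v[iv[1L]:iv[2L]]))))
  df <- df[df$length >= minLen & df$at >= atMin, , drop = FALSE]
  if (!is.null(telomeres)) {
    if (is.list(telomeres) && !is.null(telomeres$start))
      telomeres <- list(telomeres)
    if (is.list(telomeres))
      telIv <- do.call(rbind, lapply(telomeres, function(t)
        c(t$start, t$stop)))
    else telIv <- telomeres
    keep <- apply(df, 1L, function(r)
      !any(r[["start"]] <= telIv[, 2L] & r[["end"]] >= telIv[, 1L]))
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Transcription strand-switch points of a gene order
#'
#' Positions between consecutive genes where the coding strand flips; in
#' ciliate mitogenomes such switches cluster near the central repeat.
#'
#' @param order a [GeneOrder-class] with at least two genes.
#' @return data.frame with columns `after`, `before` (the flanking gene
#'   labels) and `position` (index of the gap, 1 = between genes 1 and 2).
#' @export
strandSwitchPoints <- function(order) {
  g <- orderGenes(order); s <- orderStrands(order)
  if (length(g) < 2L) .stopf("need at least two genes")
  flip <- which(s[-length(s)] != s[-1L])
  data.frame(after = g[flip], before = g[flip + 1L], position = flip)
}

#' Find open reading frames on both strands
#'
#' Scans all six frames for maximal ORFs under the chosen genetic code: each
#' ORF runs from the first start codon after the previous in-frame stop to
#' the next stop (inclusive), or to the contig end for open 3' ends. Used to
#' screen unannotated mitogenome regions, where runs of ORFs above ~75 nt
#' flag possible unrecognised genes.
#'
#' @param seq nucleotide string or [Mitogenome-class].
#' @param minLenNt minimum ORF length in nucleotides, stop included
#'   (default 75).
#' @param codeTable NCBI genetic-code id (default `"4"`).
#' @param startCodon start codon (default `"ATG"`).
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return data.frame with columns `start`, `end` (1-based on the input
#'   sequence), `strand`, `lengthNt`, `proteinAa`, `open` (TRUE when the ORF
#'   runs off the contig end without a stop).
#' @export
findOrfs <- function(seq, minLenNt = 75L, codeTable = "4",
                     startCodon = "ATG", strands = "both") {
  if (minLenNt < 3L) .stopf("minLenNt must be >= 3")
  s <- if (is(seq, "Mitogenome")) .asChar(genomeSequence(seq))
       else toupper(as.character(seq))
  L <- nchar(s)
  code <- .geneticCode(codeTable)
  stops <- names(code)[code == "*"]
  scanStrand <- function(sc, strandLab) {
    out <- list()
    for (frame in 0:2) {
      n <- (L - frame) %/% 3L
      if (n == 0L) next
      st <- frame + 3L * seq_len(n) - 2L
      cods <- substring(sc, st, st + 2L)
      isStop <- cods %in% stops
      isStart <- cods == startCodon
      segStart <- 1L
      bounds <- c(which(isStop), n + 1L)  # n+1 marks the open tail
      for (b in bounds) {
        if (b > segStart) {
          cand <- which(isStart[segStart:(b - 1L)])
          if (length(cand)) {
            i0 <- segStart + cand[1L] - 1L
            lastCodon <- min(b, n)          # include the stop when present
            open <- b > n
            ntLen <- (lastCodon - i0 + 1L) * 3L
            if (ntLen >= minLenNt) {
              a <- st[i0]
              z <- st[lastCodon] + 2L
              if (strandLab == "+") pos <- c(a, z)
              else pos <- c(L - z + 1L, L - a + 1L)
              aaLen <- if (open) ntLen %/% 3L else ntLen %/% 3L - 1L
              out[[length(out) + 1L]] <- data.frame(
                start = pos[1L], end = pos[2L], strand = strandLab,
                lengthNt = ntLen, proteinAa = aaLen, open = open)
            }
          }
        }
        segStart <- b + 1L
      }
    }
    out
  }
  res <- list()
  if (strands %in% c("both", "+")) res <- c(res, scanStrand(s, "+"))
  if (strands %in% c("both", "-")) res <- c(res, scanStrand(.revcomp(s), "-"))
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), lengthNt = integer(0),
                      proteinAa = integer(0), open = logical(0)))
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Sliding-window GC profile
#'
#' @param genome a [Mitogenome-class] or nucleotide string.
#' @param window window size, bp.
#' @param step step size, bp (must satisfy `window >= step >= 1`).
#' @return data.frame with `start` (1-based), `width`, `gc` (NA for windows
#'   with no unambiguous base, e.g. all-N). Windows tile from position 1; the
#'   final partial window is included with its own length as denominator, so
#'   with `step == window` the length-weighted mean of window GC equals the
#'   global GC.
#' @export
gcProfile <- function(genome, window = 100L, step = 50L) {
  if (!(window >= step && step >= 1L)) .stopf("need window >= step >= 1")
  s <- if (is(genome, "Mitogenome")) .asChar(genomeSequence(genome))
       else toupper(as.character(genome))
  L <- nchar(s)
  starts <- seq(1L, max(1L, L), by = step)
  starts <- starts[starts <= L]
  # keep windows that start within the sequence; trim the last to L
  ends <- pmin(starts + window - 1L, L)
  keep <- c(TRUE, utils::head(ends, -1L) < L)[seq_along(starts)]
  starts <- starts[keep]; ends <- ends[keep]
  gc <- vapply(seq_along(starts), function(i)
    .gc(substring(s, starts[i], ends[i])), numeric(1))
  data.frame(start = starts, width = ends - starts + 1L, gc = gc)
}
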