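#' @include AllClasses.R
NULL

# mask intervals (two-column matrix / data.frame start,end) with N
.maskSeq <- function(s, intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in seq_len(NROW(intervals))) {
    a <- max(1L, as.integer(intervals[i, 1L]))
    b <- min(length(v), as.integer(intervals[i, 2L]))
    if (a <= b) v[a:b] <- "N"
  }
  paste(v, collapse = "")
}

# merge k-mer hit positions sharing a diagonal into maximal exact segments
.mergeDiagonal <- function(i, j, k) {
  o <- order(i)
  i <- i[o]; j <- j[o]
  segStart <- c(TRUE, diff(i) != 1L)
  grp <- cumsum(segStart)
  firsts <- tapply(seq_along(i), grp, function(ix) ix[1L])
  lasts <- tapply(seq_along(i), grp, function(ix) ix[length(ix)])
  data.frame(start1 = i[firsts], end1 = i[lasts] + k - 1L,
             start2 = j[firsts], end2 = j[lasts] + k - 1L)
}

#' Find exact k-mer anchors between two genomes
#'
#' Reports maximal exact matches of length >= `k` between two genomes on
#' both orientations, the primitive for synteny analysis of small organelle
#' genomes. Overlapping k-mer hits on the same (anti)diagonal are merged
#' into maximal segments. Telomere and central-repeat intervals can be
#' masked first, since repeat caps produce spurious self-similarity.
#'
#' @param g1,g2 [Mitogenome-class] objects or nucleotide strings.
#' @param k minimum exact-match length (default 15; under a random-sequence
#'   null the expected number of shared k-mers is about `len1*len2/4^k`).
#' @param mask1,mask2 optional interval matrices (columns start, end;
#'   1-based) masked before anchoring, e.g. telomere/CR calls.
#' @param mode `"kmer"` (default) or `"orthologs"`; the latter pairs
#'   single-copy shared genes from `orthologs`, a data.frame as returned by
#'   [inferOrthogroups()] restricted to the two genomes.
#' @param orthologs orthogroup table for `mode = "orthologs"`.
#' @return data.frame of anchors: `start1`, `end1`, `start2`, `end2`
#'   (1-based inclusive on each genome, `start2 <= end2` always),
#'   `orientation` (`"same"`/`"inverted"`), `length`, `identity`, `kind`.
#' @export
findAnchors <- function(g1, g2, k = 15L, mask1 = NULL, mask2 = NULL,
                        mode = c("kmer", "orthologs"), orthologs = NULL) {
  mode <- match.arg(mode)
  if (mode == "orthologs") return(.orthologAnchors(g1, g2, orthologs))
  s1 <- if (is(g1, "Mitogenome")) .asChar(genomeSequence(g1)) else toupper(g1)
  s2 <- if (is(g2, "Mitogenome")) .asChar(genomeSequence(g2)) else toupper(g2)
  s1 <- .maskSeq(s1, mask1); s2 <- .maskSeq(s2, mask2)
  n1 <- nchar(s1); n2 <- nchar(s2)
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      orientation = character(0), length = integer(0),
                      identity = numeric(0), kind = character(0))
  if (n1 < k || n2 < k) return(empty)
  kmers <- function(s, n) substring(s, seq_len(n - k + 1L),
                                    seq_len(n - k + 1L) + k - 1L)
  k1 <- kmers(s1, n1)
  ok1 <- !grepl("N", k1, fixed = TRUE)
  hitsFor <- function(s2o) {
    k2 <- kmers(s2o, n2)
    ok2 <- !grepl("N", k2, fixed = TRUE)
    pos2 <- split(which(ok2), k2[ok2])
    m <- pos2[k1]
    m[!ok1] <- list(NULL)
    cnt <- lengths(m)
    list(i = rep(seq_along(k1), cnt), j = unlist(m, use.names = FALSE))
  }
  out <- list()
  fw <- hitsFor(s2)
  if (length(fw$i)) {
    d <- fw$j - fw$i
    segs <- do.call(rbind, lapply(split(seq_along(d), d), function(ix)
      .mergeDiagonal(fw$i[ix], fw$j[ix], k)))
    segs$orientation <- "same"
    out[["fw"]] <- segs
  }
  rc <- hitsFor(.revcomp(s2))
  if (length(rc$i)) {
    d <- rc$j - rc$i  # diagonal in reverse-complement coordinates
    segs <- do.call(rbind, lapply(split(seq_along(d), d), function(ix)
      .mergeDiagonal(rc$i[ix], rc$j[ix], k)))
    # map reverse-complement coordinates back to g2's forward strand
    s2n <- n2 + 1L - segs$end2
    e2n <- n2 + 1L - segs$start2
    segs$start2 <- s2n; segs$end2 <- e2n
    segs$orientation <- "inverted"
    out[["rc"]] <- segs
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  df$length <- df$end1 - df$start1 + 1L
  df$identity <- 1
  df$kind <- "kmer"
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.orthologAnchors <- function(g1, g2, orthologs) {
  if (is.null(orthologs)) .stopf("'orthologs' table required for mode = 'orthologs'")
  id1 <- genomeId(g1); id2 <- genomeId(g2)
  sub <- orthologs[orthologs$genome %in% c(id1, id2), , drop = FALSE]
  byOg <- split(sub, sub$orthogroup)
  keep <- Filter(function(x)
    nrow(x) == 2L && !anyDuplicated(x$genome), byOg)
  pos <- function(g, gene) {
    fx <- geneFeatures(g)
    i <- match(gene, as.character(mcols(fx)$gene))
    c(start(fx)[i], end(fx)[i], as.character(strand(fx))[i])
  }
  rows <- lapply(keep, function(x) {
    gene1 <- x$gene[x$genome == id1]; gene2 <- x$gene[x$genome == id2]
    p1 <- pos(g1, gene1); p2 <- pos(g2, gene2)
    data.frame(start1 = as.integer(p1[1L]), end1 = as.integer(p1[2L]),
               start2 = as.integer(p2[1L]), end2 = as.integer(p2[2L]),
               orientation = if (p1[3L] == p2[3L]) "same" else "inverted",
               length = as.integer(p1[2L]) - as.integer(p1[1L]) + 1L,
               identity = NA_real_, kind = "gene")
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame())
  df <- df[order(df$start1), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Chain anchors into synteny blocks
#'
#' Chains co-oriented anchors whose inter-anchor gaps are at most `maxGap`
#' on both genomes (with positions consistent with the orientation) into
#' maximal blocks; overlapping candidate blocks are resolved greedily by
#' total anchored length, ties by leftmost start.
#'
#' @param anchors anchor table from [findAnchors()] (one genome pair).
#' @param maxGap maximum inter-anchor gap, bp (default 1000).
#' @return data.frame of blocks: `start1`, `end1`, `start2`, `end2`,
#'   `span1`, `span2`, `orientation`, `nAnchors`, `anchorBp`.
#' @export
chainBlocks <- function(anchors, maxGap = 1000L) {
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      span1 = integer(0), span2 = integer(0),
                      orientation = character(0), nAnchors = integer(0),
                      anchorBp = integer(0))
  if (!NROW(anchors)) return(empty)
  blocks <- list()
  for (ori in c("same", "inverted")) {
    a <- anchors[anchors$orientation == ori, , drop = FALSE]
    if (!nrow(a)) next
    a <- a[order(a$start1, a$start2), , drop = FALSE]
    cur <- NULL
    flush <- function(cur) {
      data.frame(start1 = cur$s1, end1 = cur$e1, start2 = cur$s2,
                 end2 = cur$e2, span1 = cur$e1 - cur$s1 + 1L,
                 span2 = cur$e2 - cur$s2 + 1L, orientation = ori,
                 nAnchors = cur$n, anchorBp = cur$bp)
    }
    for (r in seq_len(nrow(a))) {
      an <- a[r, ]
      if (is.null(cur)) {
        cur <- list(s1 = an$start1, e1 = an$end1, s2 = an$start2,
                    e2 = an$end2, n = 1L, bp = an$length,
                    last2 = c(an$start2, an$end2))
        next
      }
      gap1 <- an$start1 - cur$e1 - 1L
      ok2 <- if (ori == "same") {
        gap2 <- an$start2 - cur$last2[2L] - 1L
        an$start2 > cur$last2[1L] && gap2 <= maxGap && gap2 >= -an$length
      } else {
        gap2 <- cur$last2[1L] - an$end2 - 1L
        an$end2 < cur$last2[2L] && gap2 <= maxGap && gap2 >= -an$length
      }
      if (gap1 <= maxGap && ok2) {
        cur$e1 <- max(cur$e1, an$end1)
        cur$s2 <- min(cur$s2, an$start2)
        cur$e2 <- max(cur$e2, an$end2)
        cur$n <- cur$n + 1L
        cur$bp <- cur$bp + an$length
        cur$last2 <- c(an$start2, an$end2)
      } else {
        blocks[[length(blocks) + 1L]] <- flush(cur)
        cur <- list(s1 = an$start1, e1 = an$end1, s2 = an$start2,
                    e2 = an$end2, n = 1L, bp = an$length,
                    last2 = c(an$start2, an$end2))
      }
    }
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur)
  }
  if (!length(blocks)) return(empty)
  df <- do.call(rbind, blocks)
  # greedy overlap resolution: keep blocks by decreasing anchored length,
  # ties leftmost; drop blocks overlapping a kept one on either genome
  df <- df[order(-df$anchorBp, df$start1), , drop = FALSE]
  kept <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    over <- FALSE
    if (any(kept)) {
      kk <- df[kept, , drop = FALSE]
      over <- any(df$start1[r] <= kk$end1 & df$end1[r] >= kk$start1) ||
              any(df$start2[r] <= kk$end2 & df$end2[r] >= kk$start2)
    }
    kept[r] <- !over
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$start1), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarise synteny blocks per pair and group
#'
#' @param blocksPerPair named list of block tables from [chainBlocks()];
#'   names are `"g1|g2"` pair ids.
#' @param groups optional named character vector mapping genome id -> group
#'   label; when given, pair totals are averaged within and between groups.
#' @param longThreshold block-length threshold for the long-block census,
#'   bp (default 2500).
#' @return list with `perPair` (pair, total span on genome 1, number of
#'   blocks, long blocks), `perGroup` (group pair, mean total), and
#'   `longBlocks` (total count above threshold).
#' @export
blockSummary <- function(blocksPerPair, groups = NULL,
                         longThreshold = 2500L) {
  perPair <- do.call(rbind, lapply(names(blocksPerPair), function(pid) {
    b <- blocksPerPair[[pid]]
    data.frame(pair = pid,
               totalBp = if (nrow(b)) sum(b$span1) else 0L,
               nBlocks = nrow(b),
               nLong = if (nrow(b)) sum(b$span1 > longThreshold) else 0L)
  }))
  rownames(perPair) <- NULL
  perGroup <- NULL
  if (!is.null(groups)) {
    ids <- strsplit(perPair$pair, "|", fixed = TRUE)
    gp <- vapply(ids, function(x) {
      gl <- sort(unname(groups[x]))
      paste(gl, collapse = "|")
    }, character(1))
    perGroup <- data.frame(
      groupPair = unique(gp),
      meanTotalBp = vapply(unique(gp), function(k)
        mean(perPair$totalBp[gp == k]), numeric(1)),
      nPairs = vapply(unique(gp), function(k) sum(gp == k), integer(1)),
      row.names = NULL)
  }
  list(perPair = perPair, perGroup = perGroup,
       longBlocks = sum(perPair$nLong))
}
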