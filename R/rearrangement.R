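#' @include AllClasses.R
NULL

# Vectorised event classifier on plain label/strand vectors. The sentinel
# "\x01START" cannot collide with a gene label.
.classifyCore <- function(refGenes, refStrands, tgtGenes, tgtStrands,
                          translocation = "predecessor") {
  shared <- refGenes[refGenes %in% tgtGenes]
  if (!length(shared))
    .stopf("no shared genes between reference and target orders")
  lost <- !(refGenes %in% tgtGenes)
  tIdx <- match(refGenes, tgtGenes)
  inverted <- !lost & refStrands != tgtStrands[tIdx]
  inverted[is.na(inverted)] <- FALSE

  rShared <- refGenes[!lost]
  tShared <- tgtGenes[tgtGenes %in% refGenes]
  if (translocation == "predecessor") {
    predRef <- c("\x01START", utils::head(rShared, -1L))
    predTgt <- c("\x01START", utils::head(tShared, -1L))
    moved <- predRef[match(refGenes, rShared)] !=
             predTgt[match(refGenes, tShared)]
  } else {  # position-index alternative for sensitivity analysis
    moved <- match(refGenes, rShared) != match(refGenes, tShared)
  }
  translocated <- !lost & moved
  translocated[is.na(translocated)] <- FALSE

  # constructed without data.frame() to keep exhaustive sweeps cheap
  out <- list(gene = refGenes,
              lost = lost,
              inverted = inverted,
              translocated = translocated,
              score = as.integer(lost) + as.integer(inverted) +
                      as.integer(translocated))
  class(out) <- "data.frame"
  attr(out, "row.names") <- .set_row_names(length(refGenes))
  out
}

#' Classify gene-order rearrangement events against a reference
#'
#' Decomposes the difference between a target gene order and a reference
#' order into per-gene events with equal weights, in the style of qMGR: a
#' reference gene is scored as \emph{lost} (absent from the target),
#' \emph{inverted} (present with the opposite strand) and/or
#' \emph{translocated} (its immediate predecessor differs between the two
#' orders after restricting both to their shared genes, with a linear start
#' sentinel). A lost gene scores 1; a retained gene scores 0, 1 or 2
#' (inversion and translocation can co-occur). Genes private to the target
#' produce no events.
#'
#' @param ref,target [GeneOrder-class] objects (or data.frames/lists with
#'   `genes` and `strands`). Orders are treated as linear: no wraparound
#'   adjacency.
#' @param translocation `"predecessor"` (default; changed immediate
#'   predecessor on the shared-gene-restricted orders) or `"position"`
#'   (changed index in the restricted orders), the latter provided for
#'   sensitivity analysis since published RF values do not pin down the
#'   adjacency convention.
#' @return data.frame with columns `gene`, `lost`, `inverted`,
#'   `translocated`, `score`, one row per reference gene, plus attributes
#'   `genomeId` and `reference`.
#' @examples
#' ref <- GeneOrder("ref", c("a", "b", "c", "d", "e"))
#' tgt <- GeneOrder("t", c("a", "c", "b", "d"), c("+", "+", "-", "+"))
#' ev <- classifyEvents(ref, tgt)
#' sum(ev$score)  # 5: e lost; b inverted+translocated; c, d translocated
#' @seealso [rearrangementScore()], [rearrangementFrequency()]
#' @export
classifyEvents <- function(ref, target,
                           translocation = c("predecessor", "position")) {
  translocation <- match.arg(translocation)
  getGS <- function(x) {
    if (is(x, "GeneOrder")) list(g = orderGenes(x), s = orderStrands(x),
                                 id = genomeId(x))
    else list(g = as.character(x$genes), s = as.character(x$strands),
              id = if (!is.null(x$genomeId)) x$genomeId else NA_character_)
  }
  r <- getGS(ref); t <- getGS(target)
  ev <- .classifyCore(r$g, r$s, t$g, t$s, translocation)
  attr(ev, "genomeId") <- t$id
  attr(ev, "reference") <- r$id
  ev
}

#' Rearrangement score (RS) of one genome
#'
#' The per-genome RS is the sum of per-gene event scores against the
#' reference order; identical orders score 0, and every event (loss,
#' inversion, translocation) adds 1.
#'
#' @param events event table from [classifyEvents()].
#' @return integer RS.
#' @export
rearrangementScore <- function(events) {
  as.integer(sum(events$score))
}

#' Rearrangement frequency (RF) per gene
#'
#' RF summarises, on a 0-100 scale, how often each reference gene was
#' involved in rearrangement events across the compared genomes:
#' \deqn{RF = 100 \times \sum_{genomes} score / (2 N)}
#' where N is the number of compared genomes and 2 is the maximum non-loss
#' score per genome. A gene lost in every genome therefore has RF 50.
#'
#' @param eventsList list of event tables from [classifyEvents()], one per
#'   compared genome (all against the same reference).
#' @return data.frame with columns `gene` and `rf`, in reference gene order.
#' @export
rearrangementFrequency <- function(eventsList) {
  if (!length(eventsList)) .stopf("need at least one compared genome")
  genes <- eventsList[[1L]]$gene
  tot <- numeric(length(genes))
  for (ev in eventsList) {
    tot <- tot + ev$score[match(genes, ev$gene)]
  }
  data.frame(gene = genes, rf = 100 * tot / (2 * length(eventsList)))
}

#' Full rearrangement report against a reference order
#'
#' Convenience wrapper running [classifyEvents()] for every target,
#' collecting per-genome RS and per-gene RF.
#'
#' @param ref reference [GeneOrder-class].
#' @param targets list of target [GeneOrder-class] objects.
#' @param translocation passed to [classifyEvents()].
#' @return list with elements `reference` (id), `events` (named list of
#'   event tables), `rs` (named integer vector), `rf` (data.frame).
#' @export
rearrangementReport <- function(ref, targets,
                                translocation = c("predecessor", "position")) {
  translocation <- match.arg(translocation)
  if (is(targets, "GeneOrder")) targets <- list(targets)
  ids <- vapply(targets, genomeId, character(1))
  events <- lapply(targets, classifyEvents, ref = ref,
                   translocation = translocation)
  names(events) <- ids
  rs <- vapply(events, rearrangementScore, integer(1))
  list(reference = genomeId(ref), events = events, rs = rs,
       rf = rearrangementFrequency(events))
}

#' Rank contiguous reference blocks by mean RF (rearrangement hotspots)
#'
#' Slides a window of `k` consecutive reference genes over the RF table and
#' ranks blocks by mean RF, descending; ties break to the leftmost block.
#' The top block is the rearrangement hotspot of the gene order.
#'
#' @param rf data.frame with `gene` and `rf` in reference order (from
#'   [rearrangementFrequency()] or a report's `$rf`).
#' @param k block size in genes (default 3).
#' @return data.frame with columns `start` (index of first gene), `genes`
#'   (dash-joined labels), `meanRf`, sorted by decreasing mean RF.
#' @export
hotspotBlocks <- function(rf, k = 3L) {
  n <- nrow(rf)
  if (k < 1L || k > n) .stopf("k must be between 1 and the number of genes (%d)", n)
  starts <- seq_len(n - k + 1L)
  means <- vapply(starts, function(i) mean(rf$rf[i:(i + k - 1L)]), numeric(1))
  blocks <- vapply(starts, function(i)
    paste(rf$gene[i:(i + k - 1L)], collapse = "-"), character(1))
  out <- data.frame(start = starts, genes = blocks, meanRf = means)
  out <- out[order(-out$meanRf, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare RS distributions between taxa
#'
#' Pairwise Welch two-sided t-tests of per-genome RS values between groups
#' (e.g. genera), with group means and standard errors. When both groups
#' have zero variance the test is degenerate: equal means give t = 0,
#' p = 1; unequal means are exact separation (p reported as 0) and the pair
#' is flagged.
#'
#' @param rsGroups named list of numeric RS vectors, one per group.
#' @return data.frame with one row per group pair: `groupA`, `groupB`,
#'   `meanA`, `meanB`, `seA`, `seB`, `t`, `p`, `degenerate`.
#' @export
compareRsGroups <- function(rsGroups) {
  nm <- names(rsGroups)
  if (is.null(nm)) nm <- paste0("group", seq_along(rsGroups))
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  combs <- utils::combn(seq_along(rsGroups), 2L)
  rows <- apply(combs, 2L, function(idx) {
    a <- rsGroups[[idx[1L]]]; b <- rsGroups[[idx[2L]]]
    degen <- length(a) > 1L && length(b) > 1L &&
      stats::sd(a) == 0 && stats::sd(b) == 0
    if (degen) {
      tt <- list(statistic = if (mean(a) == mean(b)) 0 else NA_real_,
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else if (length(a) < 2L || length(b) < 2L) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(a, b)
    }
    data.frame(groupA = nm[idx[1L]], groupB = nm[idx[2L]],
               meanA = mean(a), meanB = mean(b),
               seA = se(a), seB = se(b),
               t = unname(tt$statistic), p = tt$p.value,
               degenerate = degen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write the gene-order exchange format
#'
#' One genome per line: the genome id followed by tab-separated signed gene
#' labels, e.g. `maupasi<TAB>+cox1<TAB>-trnY...`.
#'
#' @param path file path.
#' @return `readGeneOrders()`: a named list of [GeneOrder-class] objects.
#' @export
readGeneOrders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  orders <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    signed <- parts[-1L]
    strands <- substring(signed, 1L, 1L)
    if (!all(strands %in% c("+", "-")))
      .stopf("bad signed label '%s' for genome '%s'",
             signed[!strands %in% c("+", "-")][1L], parts[1L])
    GeneOrder(parts[1L], substring(signed, 2L), strands)
  })
  names(orders) <- vapply(orders, genomeId, character(1))
  orders
}

#' @param orders list of [GeneOrder-class] objects.
#' @rdname readGeneOrders
#' @export
writeGeneOrders <- function(orders, path) {
  if (is(orders, "GeneOrder")) orders <- list(orders)
  lines <- vapply(orders, function(o)
    paste(c(genomeId(o), paste0(orderStrands(o), orderGenes(o))),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
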