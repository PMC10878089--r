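#' @include AllClasses.R
NULL

# ---- NG86 lookup tables --------------------------------------------------
# For a genetic code, precompute per-codon synonymous site counts and the
# pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered codon pair. Mutations creating stop codons are excluded from site
# denominators, and mutation pathways passing through stop codons are
# excluded from the pathway average (all-blocked pairs fall back to counting
# stop-passing steps as nonsynonymous).
.ng86Tables <- function(codeTable = "4") {
  key <- paste0("ng86_", codeTable)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  code <- .geneticCode(codeTable)
  codons <- names(code)
  aa <- unname(code)
  nc <- length(codons)
  codChars <- do.call(rbind, strsplit(codons, "", fixed = TRUE))

  synSites <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    if (aa[i] == "*") next
    s <- 0
    for (pos in 1:3) {
      m <- 0L; sy <- 0L
      for (b in setdiff(.BASES, codChars[i, pos])) {
        mut <- codChars[i, ]; mut[pos] <- b
        j <- match(paste(mut, collapse = ""), codons)
        if (aa[j] == "*") next
        m <- m + 1L
        if (aa[j] == aa[i]) sy <- sy + 1L
      }
      if (m > 0L) s <- s + sy / m
    }
    synSites[i] <- s
  }

  stepSN <- function(c1, c2) {
    # returns c(syn, nonsyn) for one mutational step
    if (aa[c1] == "*" || aa[c2] == "*") return(c(0, 1))
    if (aa[c1] == aa[c2]) c(1, 0) else c(0, 1)
  }
  perms <- list(`1` = matrix(1L, 1L, 1L),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  synDiff <- matrix(0, nc, nc)
  nonDiff <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    if (aa[i] == "*") next
    for (j in seq_len(nc)) {
      if (j <= i || aa[j] == "*") next
      dpos <- which(codChars[i, ] != codChars[j, ])
      d <- length(dpos)
      if (d == 0L) next
      pm <- perms[[as.character(d)]]
      paths <- vector("list", nrow(pm))
      valid <- logical(nrow(pm))
      for (p in seq_len(nrow(pm))) {
        cur <- codChars[i, ]
        curIdx <- i
        sn <- c(0, 0)
        ok <- TRUE
        for (stp in pm[p, seq_len(d)]) {
          nxt <- cur
          nxt[dpos[stp]] <- codChars[j, dpos[stp]]
          nxtIdx <- match(paste(nxt, collapse = ""), codons)
          if (aa[nxtIdx] == "*" && nxtIdx != j) ok <- FALSE
          sn <- sn + stepSN(curIdx, nxtIdx)
          cur <- nxt
          curIdx <- nxtIdx
        }
        paths[[p]] <- sn
        valid[p] <- ok
      }
      use <- if (any(valid)) paths[valid] else paths
      avg <- Reduce(`+`, use) / length(use)
      synDiff[i, j] <- synDiff[j, i] <- avg[1L]
      nonDiff[i, j] <- nonDiff[j, i] <- avg[2L]
    }
  }
  tabs <- list(codons = codons, aa = aa, synSites = synSites,
               synDiff = synDiff, nonDiff = nonDiff)
  .cache[[key]] <- tabs
  tabs
}

# ---- codon alignment -----------------------------------------------------

#' Protein-guided pairwise codon alignment
#'
#' Globally aligns the translations of two coding sequences (BLOSUM62,
#' affine gaps) and back-translates the alignment to nucleotides, so gaps
#' occur only in whole codons -- the standard substrate for Ka/Ks estimation.
#'
#' @param cdsA,cdsB coding sequences (character or `DNAString`); trailing
#'   stop codons are removed before alignment.
#' @param codeTable NCBI genetic-code id (default `"4"`).
#' @param gene optional gene label carried into the result.
#' @param gapOpening,gapExtension affine gap penalties (defaults 10, 0.5).
#' @return a [CodonAlignment-class] with rows named `a` and `b` (or the
#'   input names).
#' @export
alignCodons <- function(cdsA, cdsB, codeTable = "4", gene = NA_character_,
                        gapOpening = 10, gapExtension = 0.5) {
  nmA <- if (!is.null(names(cdsA))) names(cdsA)[1L] else "a"
  nmB <- if (!is.null(names(cdsB))) names(cdsB)[1L] else "b"
  prep <- function(s, label) {
    s <- toupper(.asChar(s))
    s <- substring(s, 1L, nchar(s) - nchar(s) %% 3L)
    p <- suppressWarnings(translateCds(s, codeTable))
    if (!nzchar(p)) .stopf("CDS '%s' is not translatable", label)
    # drop codons after replacing internal stops is not needed; stops in the
    # middle indicate annotation problems and are kept as '*'
    list(nt = s, aa = p)
  }
  A <- prep(cdsA, nmA); B <- prep(cdsB, nmB)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(A$aa), Biostrings::AAString(B$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension)
  alnA <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  alnB <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  backTrans <- function(alnAa, nt) {
    cods <- .codons(nt)
    out <- character(length(alnAa))
    k <- 0L
    for (i in seq_along(alnAa)) {
      if (alnAa[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    paste(out, collapse = "")
  }
  seqs <- Biostrings::DNAStringSet(c(backTrans(alnA, A$nt),
                                     backTrans(alnB, B$nt)))
  names(seqs) <- c(nmA, nmB)
  CodonAlignment(seqs, gene = gene)
}

# ---- NG86 ----------------------------------------------------------------

#' Ka/Ks by the Nei-Gojobori (NG86) method with Jukes-Cantor correction
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (averaged over
#' the two sequences, with mutations to stop codons excluded from the site
#' denominators so that N + S = 3 x codons), averages
#' synonymous/nonsynonymous differences over all mutational pathways between
#' differing codons (pathways through stop codons excluded), and applies the
#' Jukes-Cantor multiple-hit correction to the proportions pS and pN.
#' Ka/Ks < 1 indicates purifying selection.
#'
#' @param aln a [CodonAlignment-class] (first two rows used) or a character
#'   vector of two aligned, equal-length, in-frame sequences.
#' @param codeTable NCBI genetic-code id (default `"4"`).
#' @return one-row data.frame: `ka`, `ks`, `ratio` (NA when Ks is 0 or
#'   either value is saturated), `nSites`, `sSites`, `nDiffs`, `sDiffs`,
#'   `pN`, `pS`, `codons` (gap-free codon columns used), `saturated`
#'   (TRUE when pN or pS >= 0.75 so the JC correction is undefined),
#'   `method` (`"NG86"`), `gene`.
#' @details Codon columns containing gaps, ambiguity codes or stop codons in
#'   either row are dropped before counting. The estimator is symmetric in
#'   its two sequences.
#' @examples
#' kaksNG86(c("AAAAAA", "AAAAAG"))  # Lys->Lys: Ks > 0, Ka = 0
#' @export
kaksNG86 <- function(aln, codeTable = "4") {
  gene <- NA_character_
  if (is(aln, "CodonAlignment")) {
    gene <- aln@gene
    rows <- as.character(aln@seqs)[1:2]
  } else rows <- toupper(as.character(aln))[1:2]
  tabs <- .ng86Tables(codeTable)
  ca <- .codons(rows[1L]); cb <- .codons(rows[2L])
  if (length(ca) != length(cb))
    .stopf("aligned rows must have equal codon length")
  ia <- match(ca, tabs$codons); ib <- match(cb, tabs$codons)
  keep <- !is.na(ia) & !is.na(ib) &
          !is.na(tabs$synSites[ia]) & !is.na(tabs$synSites[ib])
  ia <- ia[keep]; ib <- ib[keep]
  ncod <- length(ia)
  if (ncod == 0L) .stopf("no gap-free, unambiguous codon columns")
  S <- sum((tabs$synSites[ia] + tabs$synSites[ib]) / 2)
  N <- 3 * ncod - S
  Sd <- sum(tabs$synDiff[cbind(ia, ib)])
  Nd <- sum(tabs$nonDiff[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (saturated || ks == 0) NA_real_ else ka / ks
  data.frame(ka = ka, ks = ks, ratio = ratio,
             nSites = N, sSites = S, nDiffs = Nd, sDiffs = Sd,
             pN = pN, pS = pS, codons = ncod, saturated = saturated,
             method = "NG86", gene = gene)
}

#' Sliding-window Ka/Ks series along a codon alignment
#'
#' Applies [kaksNG86()] to successive windows of codon columns, the standard
#' view for localising conserved versus relaxed stretches within a gene.
#'
#' @param aln a [CodonAlignment-class] or two aligned sequences.
#' @param window window size in codons (default 30; must be >= 10).
#' @param step step in codons (default 6).
#' @param codeTable NCBI genetic-code id.
#' @return data.frame with one row per window: `start` (first codon column),
#'   `startNt` (first nucleotide, the x-coordinate used when plotting such
#'   series), plus the [kaksNG86()] columns. An alignment shorter than one
#'   window yields a single full-length window.
#' @export
slidingKaks <- function(aln, window = 30L, step = 6L, codeTable = "4") {
  if (window < 10L) .stopf("window must be >= 10 codons")
  rows <- if (is(aln, "CodonAlignment")) as.character(aln@seqs)[1:2]
          else toupper(as.character(aln))[1:2]
  W <- nchar(rows[1L]) %/% 3L
  starts <- if (W <= window) 1L else seq(1L, W - window + 1L, by = step)
  out <- lapply(starts, function(i) {
    a <- substring(rows[1L], 3L * i - 2L, 3L * min(i + window - 1L, W))
    b <- substring(rows[2L], 3L * i - 2L, 3L * min(i + window - 1L, W))
    res <- tryCatch(kaksNG86(c(a, b), codeTable),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.frame(start = i, startNt = 3L * i - 2L), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise Ka/Ks ratios per gene, gene family and species pair
#'
#' Arithmetic means over defined (non-missing) ratios, the summaries used to
#' compare selective constraint between mitochondrial gene families
#' (nad/cob/cox/atp versus rpg/ymf).
#'
#' @param results data.frame with at least `gene`, `pair`, `ratio` (e.g.
#'   rows of [kaksNG86()] results annotated with a `pair` id).
#' @param familyMap named character vector mapping gene -> family; genes not
#'   covered are labelled `"other"`. By default gene labels are mapped by
#'   their alphabetic prefix (`nad*` -> nad, `rps*`/`rpl*` -> rpg, etc.).
#' @return list of data.frames `perGene`, `perFamily`, `perPair`, each with
#'   `meanRatio` and `n` (contributing pairs).
#' @export
familySummary <- function(results, familyMap = NULL) {
  if (is.null(familyMap)) {
    fam <- function(g) {
      g <- tolower(g)
      if (grepl("^nad", g)) "nad" else if (grepl("^cob", g)) "cob"
      else if (grepl("^cox", g)) "cox" else if (grepl("^atp", g)) "atp"
      else if (grepl("^(rps|rpl|rpg)", g)) "rpg"
      else if (grepl("^ymf", g)) "ymf" else "other"
    }
    families <- vapply(as.character(results$gene), fam, character(1))
  } else {
    families <- unname(familyMap[as.character(results$gene)])
    families[is.na(families)] <- "other"
  }
  ok <- !is.na(results$ratio)
  agg <- function(key) {
    keys <- unique(key)
    data.frame(
      key = keys,
      meanRatio = vapply(keys, function(k)
        mean(results$ratio[ok & key == k]), numeric(1)),
      n = vapply(keys, function(k) sum(ok & key == k), integer(1)),
      row.names = NULL)
  }
  perGene <- agg(as.character(results$gene))
  names(perGene)[1L] <- "gene"
  perFam <- agg(families)
  names(perFam)[1L] <- "family"
  perPair <- agg(as.character(results$pair))
  names(perPair)[1L] <- "pair"
  list(perGene = perGene, perFamily = perFam, perPair = perPair)
}

#' Correlation between rearrangement frequency and selection
#'
#' Ordinary least squares of per-gene mean Ka/Ks on per-gene RF, reporting
#' R-squared and the two-sided p-value of the slope -- the test of whether
#' frequently rearranged genes are under weaker purifying selection.
#'
#' @param rf numeric per-gene RF values.
#' @param ratio numeric per-gene mean Ka/Ks values (same genes, same order).
#' @return list with `r2`, `p`, `slope`, `intercept`, `n`, `degenerate`
#'   (TRUE when RF has zero variance, in which case the fit is undefined).
#' @export
rfKaksCorrelation <- function(rf, ratio) {
  keep <- stats::complete.cases(rf, ratio)
  rf <- rf[keep]; ratio <- ratio[keep]
  if (length(rf) < 3L) .stopf("need at least 3 genes with both values")
  if (stats::var(rf) == 0)
    return(list(r2 = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(rf), degenerate = TRUE))
  fit <- stats::lm(ratio ~ rf)
  sm <- summary(fit)
  list(r2 = sm$r.squared,
       p = sm$coefficients["rf", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(rf), degenerate = FALSE)
}
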