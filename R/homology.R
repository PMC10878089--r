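#' @include AllClasses.R
NULL

#' Infer orthogroups across mitogenomes
#'
#' Groups homologous protein-coding genes across genomes either by shared
#' label (`by_name`, appropriate when annotations use a common nomenclature)
#' or by reciprocal best hits of global protein alignments (`rbh`, BLOSUM62
#' with affine gaps), clustering RBH edges by single linkage. Split-gene
#' parts (`_a`/`_b` suffixes) keep their full labels.
#'
#' @param genomes list of [Mitogenome-class] objects, or a named list of
#'   named character vectors of protein (or CDS) sequences per genome; for
#'   Mitogenome input, PCGs are extracted and translated with `codeTable`.
#' @param mode `"by_name"` or `"rbh"`.
#' @param codeTable genetic-code id used to translate CDS (default `"4"`).
#' @param gapOpening,gapExtension affine gap penalties for `rbh`.
#' @return data.frame with columns `orthogroup`, `genome`, `gene`; group ids
#'   are `OG0001`, ... ordered by decreasing size then first gene label.
#' @details Best-hit score ties break by lexicographic gene label, making the
#'   clustering deterministic.
#' @seealso [coreGenes()]
#' @export
inferOrthogroups <- function(genomes, mode = c("by_name", "rbh"),
                             codeTable = "4",
                             gapOpening = 10, gapExtension = 0.5) {
  mode <- match.arg(mode)
  prot <- .proteomes(genomes, codeTable)
  if (length(prot) < 2L) .stopf("need at least two genomes")
  empty <- vapply(prot, length, integer(1)) == 0L
  if (any(empty))
    .stopf("genome '%s' has an empty proteome", names(prot)[which(empty)[1L]])

  members <- data.frame(
    genome = rep(names(prot), vapply(prot, length, integer(1))),
    gene = unlist(lapply(prot, names), use.names = FALSE),
    stringsAsFactors = FALSE)
  n <- nrow(members)

  if (mode == "by_name") {
    key <- members$gene
  } else {
    # reciprocal best hits, single linkage via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union2 <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
    }
    idx <- split(seq_len(n), members$genome)
    gn <- names(prot)
    score <- function(a, b)
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
        substitutionMatrix = "BLOSUM62", gapOpening = gapOpening,
        gapExtension = gapExtension, scoreOnly = TRUE)
    for (gi in seq_along(gn)) for (gj in seq_along(gn)) {
      if (gj <= gi) next
      A <- idx[[gn[gi]]]; B <- idx[[gn[gj]]]
      sm <- matrix(0, length(A), length(B))
      for (a in seq_along(A)) for (b in seq_along(B))
        sm[a, b] <- score(prot[[gn[gi]]][[members$gene[A[a]]]],
                          prot[[gn[gj]]][[members$gene[B[b]]]])
      bestAB <- apply(sm, 1L, function(r) {
        top <- which(r == max(r))
        top[order(members$gene[B[top]])][1L]  # deterministic tie-break
      })
      bestBA <- apply(sm, 2L, function(cl) {
        top <- which(cl == max(cl))
        top[order(members$gene[A[top]])][1L]
      })
      for (a in seq_along(A))
        if (bestBA[bestAB[a]] == a) union2(A[a], B[bestAB[a]])
    }
    key <- vapply(seq_len(n), find, integer(1))
  }

  groups <- split(seq_len(n), key)
  sizes <- vapply(groups, length, integer(1))
  firstGene <- vapply(groups, function(ix) min(members$gene[ix]), character(1))
  o <- order(-sizes, firstGene)
  groups <- groups[o]
  og <- sprintf("OG%04d", seq_along(groups))
  out <- do.call(rbind, lapply(seq_along(groups), function(k)
    data.frame(orthogroup = og[k],
               genome = members$genome[groups[[k]]],
               gene = members$gene[groups[[k]]])))
  rownames(out) <- NULL
  out
}

.proteomes <- function(genomes, codeTable = "4") {
  if (length(genomes) && is(genomes[[1L]], "Mitogenome")) {
    prot <- lapply(genomes, function(g) {
      cds <- cdsSequences(g)
      vapply(cds, function(s) suppressWarnings(translateCds(s, codeTable)),
             character(1))
    })
    names(prot) <- vapply(genomes, genomeId, character(1))
  } else prot <- genomes
  prot
}

#' Identify core genes (universal single-copy orthogroups)
#'
#' @param orthogroups orthogroup table from [inferOrthogroups()].
#' @param nGenomes number of genomes compared.
#' @return list with `orthogroups` (ids with exactly one member in every
#'   genome), `count`, and `members` (the corresponding table subset).
#' @export
coreGenes <- function(orthogroups, nGenomes) {
  byOg <- split(orthogroups$genome, orthogroups$orthogroup)
  core <- names(byOg)[vapply(byOg, function(g)
    length(g) == nGenomes && !anyDuplicated(g), logical(1))]
  list(orthogroups = core, count = length(core),
       members = orthogroups[orthogroups$orthogroup %in% core, , drop = FALSE])
}

# protein MSA via the mafft command-line aligner
.mafft <- function(aas) {
  if (!nzchar(Sys.which("mafft")))
    .stopf("the 'mafft' aligner is required for multi-sequence alignment but was not found on PATH")
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aas), fin)
  status <- system2("mafft", c("--auto", "--quiet", "--amino", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) .stopf("mafft failed with status %d", status)
  out <- Biostrings::readAAStringSet(fout)
  stats::setNames(as.character(out), names(out))
}

#' Concatenated core-gene codon alignment
#'
#' For each core gene, aligns the translated CDS of all taxa (mafft,
#' protein-guided), back-translates to codons, and concatenates the per-gene
#' blocks, recording partition boundaries -- the input for core-gene
#' phylogenomics.
#'
#' @param geneCds named list: per gene, a named character vector of CDS by
#'   taxon. All genes must cover all taxa.
#' @param codeTable genetic-code id (default `"4"`).
#' @return list of class `ConcatAlignment`: `aln` (a `DNAStringSet`, one row
#'   per taxon), `partitions` (cumulative end columns, last equals total
#'   width), `genes`.
#' @export
concatCoreAlignment <- function(geneCds, codeTable = "4") {
  taxa <- sort(unique(unlist(lapply(geneCds, names))))
  missing <- list()
  for (g in names(geneCds))
    for (tx in setdiff(taxa, names(geneCds[[g]])))
      missing[[length(missing) + 1L]] <- c(tx, g)
  if (length(missing))
    .stopf("missing sequences: %s",
           paste(vapply(missing, paste, character(1), collapse = ":"),
                 collapse = ", "))
  blocks <- list()
  for (g in names(geneCds)) {
    cds <- geneCds[[g]][taxa]
    cds <- vapply(cds, function(s) {
      s <- toupper(.asChar(s)); substring(s, 1L, nchar(s) - nchar(s) %% 3L)
    }, character(1))
    aa <- vapply(cds, function(s)
      suppressWarnings(translateCds(s, codeTable)), character(1))
    if (length(unique(nchar(aa))) == 1L &&
        length(unique(nchar(cds))) == 1L) {
      alnAa <- aa  # equal lengths: identity alignment
    } else {
      alnAa <- .mafft(aa)[taxa]
    }
    block <- vapply(taxa, function(tx) {
      cods <- .codons(cds[[tx]])
      chars <- strsplit(alnAa[[tx]], "", fixed = TRUE)[[1L]]
      k <- 0L
      paste(vapply(chars, function(ch) {
        if (ch == "-") "---" else { k <<- k + 1L; cods[k] }
      }, character(1)), collapse = "")
    }, character(1))
    blocks[[g]] <- block
  }
  widths <- vapply(blocks, function(b) nchar(b[1L]), integer(1))
  rows <- vapply(taxa, function(tx)
    paste(vapply(blocks, `[[`, character(1), tx), collapse = ""),
    character(1))
  aln <- Biostrings::DNAStringSet(rows)
  names(aln) <- taxa
  structure(list(aln = aln, partitions = cumsum(widths),
                 genes = names(geneCds)),
            class = "ConcatAlignment")
}

#' Write an alignment and partition file for external tree tools
#'
#' @param concat a `ConcatAlignment` from [concatCoreAlignment()].
#' @param fastaPath,partitionPath output paths (either may be `NULL`).
#' @return invisibly, the written paths.
#' @export
writeConcatAlignment <- function(concat, fastaPath = NULL,
                                 partitionPath = NULL) {
  if (!is.null(fastaPath))
    Biostrings::writeXStringSet(concat$aln, fastaPath)
  if (!is.null(partitionPath)) {
    starts <- c(1L, utils::head(concat$partitions, -1L) + 1L)
    writeLines(sprintf("DNA, %s = %d-%d", concat$genes, starts,
                       concat$partitions), partitionPath)
  }
  invisible(c(fastaPath, partitionPath))
}

# pairwise distances from a character matrix of aligned sequences
.alnDistance <- function(mat, model = c("p", "jc69")) {
  model <- match.arg(model)
  nt <- nrow(mat)
  D <- matrix(0, nt, nt, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (j <= i) next
    ok <- mat[i, ] != "-" & mat[j, ] != "-" &
          mat[i, ] %in% .BASES & mat[j, ] %in% .BASES
    if (!any(ok))
      .stopf("taxa '%s' and '%s' share no aligned sites",
             rownames(mat)[i], rownames(mat)[j])
    p <- mean(mat[i, ok] != mat[j, ok])
    d <- if (model == "p") p
         else if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree with bootstrap support
#'
#' Distance-based (p-distance or JC69) neighbor-joining on an alignment,
#' with nonparametric bootstrap by column resampling under a fixed seed.
#' On additive distance matrices NJ recovers the generating topology
#' exactly; runs with the same seed are identical.
#'
#' @param aln a `ConcatAlignment`, `DNAStringSet`, named character vector of
#'   equal-length aligned sequences, or character matrix (taxa x columns).
#' @param distance `"p"` (default) or `"jc69"`.
#' @param bootstrapN bootstrap replicates (default 100; 0 disables support).
#' @param seed RNG seed for the resampling.
#' @return an [ape::phylo] tree; `node.label` holds bootstrap support as
#'   percentages when `bootstrapN > 0`.
#' @export
njTree <- function(aln, distance = c("p", "jc69"), bootstrapN = 100L,
                   seed = 1L) {
  distance <- match.arg(distance)
  mat <- .alnMatrix(aln)
  if (nrow(mat) < 3L) .stopf("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(.alnDistance(mat, distance)))
  if (bootstrapN > 0L) {
    set.seed(seed)
    nc <- ncol(mat)
    boots <- lapply(seq_len(bootstrapN), function(b) {
      cols <- sample.int(nc, nc, replace = TRUE)
      ape::nj(stats::as.dist(.alnDistance(mat[, cols, drop = FALSE],
                                          distance)))
    })
    counts <- ape::prop.clades(tr, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tr$node.label <- round(100 * counts / bootstrapN, 1)
  }
  tr
}

.alnMatrix <- function(aln) {
  if (inherits(aln, "ConcatAlignment")) aln <- aln$aln
  if (is(aln, "XStringSet")) aln <- stats::setNames(as.character(aln),
                                                    names(aln))
  if (is.matrix(aln)) return(aln)
  chars <- strsplit(toupper(aln), "", fixed = TRUE)
  if (length(unique(lengths(chars))) != 1L)
    .stopf("aligned sequences must have equal length")
  mat <- do.call(rbind, chars)
  rownames(mat) <- if (!is.null(names(aln))) names(aln)
                   else paste0("t", seq_along(aln))
  mat
}
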