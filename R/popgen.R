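#' @include AllClasses.R
NULL

#' Read / write an allele-depth matrix
#'
#' TSV exchange format, one row per strain x site: columns `strain`, `site`,
#' `ref`, `A`, `C`, `G`, `T`. This is the expected product of an upstream
#' pileup (e.g. `samtools mpileup` counts per base); read mapping itself is
#' out of scope.
#'
#' @param path file path.
#' @return `readAlleleDepths()`: a [VariantMatrix-class].
#' @export
readAlleleDepths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "site", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    .stopf("allele-depth table must have columns: %s",
           paste(need, collapse = ", "))
  strains <- sort(unique(df$strain))
  sites <- sort(unique(df$site))
  depths <- array(0L, dim = c(length(strains), length(sites), 4L))
  si <- match(df$strain, strains)
  pi_ <- match(df$site, sites)
  for (b in 1:4)
    depths[cbind(si, pi_, b)] <- as.integer(df[[.BASES[b]]])
  ref <- character(length(sites))
  ref[pi_] <- toupper(df$ref)
  VariantMatrix(strains, sites, ref, depths)
}

#' @param vm a [VariantMatrix-class].
#' @rdname readAlleleDepths
#' @export
writeAlleleDepths <- function(vm, path) {
  d <- alleleDepths(vm)
  rows <- expand.grid(strain = strainNames(vm), siteIdx = seq_along(siteCoords(vm)),
                      stringsAsFactors = FALSE)
  df <- data.frame(strain = rows$strain,
                   site = siteCoords(vm)[rows$siteIdx],
                   ref = refBases(vm)[rows$siteIdx],
                   A = d[cbind(match(rows$strain, strainNames(vm)), rows$siteIdx, 1L)],
                   C = d[cbind(match(rows$strain, strainNames(vm)), rows$siteIdx, 2L)],
                   G = d[cbind(match(rows$strain, strainNames(vm)), rows$siteIdx, 3L)],
                   T = d[cbind(match(rows$strain, strainNames(vm)), rows$siteIdx, 4L)])
  df <- df[order(df$strain, df$site), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus haplotypes from allele depths
#'
#' For each strain and site, the majority base; sites with total depth below
#' `minDepth` are masked as `N`. Ties involving the reference base resolve
#' to the reference (otherwise alphabetically first among the tied bases).
#'
#' @param vm a [VariantMatrix-class].
#' @param minDepth minimum total depth to call a base (default 10).
#' @return character matrix strains x sites of bases (`N` = masked), with
#'   dimnames (strains; site coordinates).
#' @export
consensusHaplotypes <- function(vm, minDepth = 10L) {
  if (minDepth < 1L) .stopf("minDepth must be >= 1")
  d <- alleleDepths(vm)
  ns <- length(strainNames(vm)); np <- length(siteCoords(vm))
  tot <- apply(d, c(1, 2), sum)
  if (any(rowSums(tot >= minDepth) == 0L))
    .stopf("strain '%s' has no site at depth >= %d",
           strainNames(vm)[which(rowSums(tot >= minDepth) == 0L)[1L]],
           minDepth)
  out <- matrix("N", ns, np,
                dimnames = list(strainNames(vm), siteCoords(vm)))
  ref <- refBases(vm)
  refIdx <- match(ref, .BASES)
  for (s in seq_len(ns)) {
    cnt <- d[s, , , drop = TRUE]
    if (np == 1L) cnt <- matrix(cnt, 1L, 4L)
    mx <- do.call(pmax, lapply(1:4, function(b) cnt[, b]))
    # first max column = alphabetically first tied base; reference wins
    # any tie it participates in
    call <- .BASES[max.col(cnt, ties.method = "first")]
    refTop <- !is.na(refIdx) & cnt[cbind(seq_len(np), refIdx)] == mx
    call[refTop] <- ref[refTop]
    call[tot[s, ] < minDepth] <- "N"
    out[s, ] <- call
  }
  out
}

#' Call SNP sites among consensus haplotypes
#'
#' A site is a SNP when at least two distinct unmasked bases occur among the
#' strains. Density is reported per covered kilobase (sites with >= 2
#' unmasked strains).
#'
#' @param consensuses character matrix strains x sites (from
#'   [consensusHaplotypes()]).
#' @return list with `sites` (coordinates or column indices of SNPs),
#'   `count`, `coveredSites` and `densityPerKb`.
#' @export
callSnps <- function(consensuses) {
  if (nrow(consensuses) < 2L) .stopf("need >= 2 strains")
  nAlleles <- apply(consensuses, 2L, function(col)
    length(unique(col[col %in% .BASES])))
  covered <- apply(consensuses, 2L, function(col)
    sum(col %in% .BASES) >= 2L)
  isSnp <- covered & nAlleles >= 2L
  coords <- colnames(consensuses)
  sites <- if (is.null(coords)) which(isSnp) else as.integer(coords[isSnp])
  list(sites = sites, count = sum(isSnp), coveredSites = sum(covered),
       densityPerKb = if (sum(covered)) 1000 * sum(isSnp) / sum(covered)
                      else NA_real_)
}

#' Call heteroplasmic sites within strains
#'
#' A strain x site combination is flagged as potentially heteroplasmic when
#' the minor-allele fraction (second most frequent base over total depth)
#' reaches `mafMin` at total depth >= `depthMin` -- the signature of
#' coexisting mitochondrial alleles within a clonal strain.
#'
#' @param vm a [VariantMatrix-class].
#' @param mafMin minimum minor-allele fraction (default 0.05).
#' @param depthMin minimum total depth (default 50).
#' @return data.frame with columns `strain`, `site`, `major`, `minor`,
#'   `maf`, `depth` (zero rows when nothing is called).
#' @export
callHeteroplasmy <- function(vm, mafMin = 0.05, depthMin = 50L) {
  d <- alleleDepths(vm)
  rows <- list()
  for (s in seq_along(strainNames(vm))) {
    cnt <- d[s, , , drop = TRUE]
    if (length(siteCoords(vm)) == 1L) cnt <- matrix(cnt, 1L, 4L)
    tot <- rowSums(cnt)
    ord <- t(apply(cnt, 1L, order, decreasing = TRUE))
    major <- .BASES[ord[, 1L]]
    minorCnt <- cnt[cbind(seq_len(nrow(cnt)), ord[, 2L])]
    maf <- ifelse(tot > 0, minorCnt / tot, 0)
    hit <- which(tot >= depthMin & maf >= mafMin & minorCnt > 0L)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strainNames(vm)[s], site = siteCoords(vm)[hit],
        major = major[hit], minor = .BASES[ord[hit, 2L]],
        maf = maf[hit], depth = tot[hit])
  }
  if (!length(rows))
    return(data.frame(strain = character(0), site = integer(0),
                      major = character(0), minor = character(0),
                      maf = numeric(0), depth = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nucleotide diversity (pi)
#'
#' Average over strain pairs of the per-site pairwise difference proportion
#' (differences / jointly covered sites). Optionally restricted to gene
#' intervals for per-gene pi.
#'
#' @param consensuses character matrix strains x sites; column names are
#'   site coordinates (required for interval restriction).
#' @param intervals optional data.frame with `gene`, `start`, `end` for
#'   per-gene pi (coordinates matching the column names).
#' @return list with `pi` (global) and, when intervals are given, `perGene`
#'   (data.frame gene, pi, sites). Pairs with zero jointly covered sites are
#'   excluded with a warning.
#' @export
nucleotideDiversity <- function(consensuses, intervals = NULL) {
  n <- nrow(consensuses)
  if (n < 2L) .stopf("need >= 2 strains")
  piOf <- function(mat) {
    pairs <- utils::combn(n, 2L)
    vals <- apply(pairs, 2L, function(ix) {
      a <- mat[ix[1L], ]; b <- mat[ix[2L], ]
      ok <- a %in% .BASES & b %in% .BASES
      if (!any(ok)) return(NA_real_)
      mean(a[ok] != b[ok])
    })
    if (anyNA(vals))
      warning(sprintf("%d strain pair(s) with zero jointly covered sites excluded",
                      sum(is.na(vals))), call. = FALSE)
    mean(vals, na.rm = TRUE)
  }
  out <- list(pi = piOf(consensuses))
  if (!is.null(intervals)) {
    coords <- as.integer(colnames(consensuses))
    out$perGene <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
      cols <- which(coords >= intervals$start[i] & coords <= intervals$end[i])
      data.frame(gene = intervals$gene[i],
                 pi = if (length(cols))
                        piOf(consensuses[, cols, drop = FALSE])
                      else NA_real_,
                 sites = length(cols))
    }))
  }
  out
}

# haploid r^2 between two site columns (bases per strain); NA if either
# site is not biallelic among jointly covered strains
.siteR2 <- function(a, b) {
  ok <- a %in% .BASES & b %in% .BASES
  a <- a[ok]; b <- b[ok]
  ua <- unique(a); ub <- unique(b)
  if (length(ua) != 2L || length(ub) != 2L) return(NA_real_)
  x <- as.numeric(a == ua[1L]); y <- as.numeric(b == ub[1L])
  pA <- mean(x); pB <- mean(y)
  D <- mean(x * y) - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom == 0) return(NA_real_)
  D^2 / denom
}

#' Linkage-disequilibrium decay across a mitogenome
#'
#' Computes haploid r-squared (D^2 / pA pa pB pb) for every pair of biallelic
#' sites among the consensus haplotypes and correlates r-squared with the
#' physical distance separating the sites. In the absence of recombination
#' (complete linkage) r-squared is independent of distance, so the
#' correlation p-value carries the recombination signal.
#'
#' @param consensuses character matrix strains x sites; column names are
#'   site coordinates (column index used when absent). Needs >= 4 strains.
#' @param maxPairs optional cap on the number of site pairs (the most
#'   distant pairs are kept deterministically by subsampling sites).
#' @return list with `pairs` (data.frame site1, site2, distance, r2),
#'   `pearson` and `spearman` (each a list with `estimate` and `p`).
#' @export
ldR2Decay <- function(consensuses, maxPairs = 50000L) {
  if (nrow(consensuses) < 4L) .stopf("need >= 4 strains")
  coords <- colnames(consensuses)
  coords <- if (is.null(coords)) seq_len(ncol(consensuses))
            else as.integer(coords)
  biallelic <- which(apply(consensuses, 2L, function(col)
    length(unique(col[col %in% .BASES])) == 2L))
  if (length(biallelic) < 2L)
    .stopf("need >= 2 biallelic sites")
  np <- length(biallelic) * (length(biallelic) - 1L) / 2
  if (np > maxPairs) {
    keep <- round(seq(1L, length(biallelic),
                      length.out = floor(sqrt(2 * maxPairs))))
    biallelic <- biallelic[unique(keep)]
  }
  cmb <- utils::combn(biallelic, 2L)
  r2 <- apply(cmb, 2L, function(ix)
    .siteR2(consensuses[, ix[1L]], consensuses[, ix[2L]]))
  dist <- abs(coords[cmb[2L, ]] - coords[cmb[1L, ]])
  ok <- !is.na(r2)
  pairs <- data.frame(site1 = coords[cmb[1L, ok]],
                      site2 = coords[cmb[2L, ok]],
                      distance = dist[ok], r2 = r2[ok])
  ctest <- function(method) {
    if (nrow(pairs) < 3L || stats::sd(pairs$r2) == 0 ||
        stats::sd(pairs$distance) == 0)
      return(list(estimate = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(pairs$r2, pairs$distance,
                                           method = method))
    list(estimate = unname(ct$estimate), p = ct$p.value)
  }
  list(pairs = pairs, pearson = ctest("pearson"),
       spearman = ctest("spearman"))
}

#' Identity-by-state matrix between strains
#'
#' @param consensuses character matrix strains x sites.
#' @return symmetric matrix of the fraction of jointly covered sites with
#'   identical bases (diagonal 1).
#' @export
ibsMatrix <- function(consensuses) {
  n <- nrow(consensuses)
  M <- diag(1, n)
  dimnames(M) <- list(rownames(consensuses), rownames(consensuses))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- consensuses[i, ]; b <- consensuses[j, ]
    ok <- a %in% .BASES & b %in% .BASES
    M[i, j] <- M[j, i] <- if (any(ok)) mean(a[ok] == b[ok]) else NA_real_
  }
  M
}

#' Great-circle distance matrix (haversine, Earth radius 6371 km)
#'
#' @param meta data.frame with columns `strain`, `lat`, `lon` (decimal
#'   degrees).
#' @return symmetric matrix of distances in kilometres.
#' @export
haversineKm <- function(meta) {
  if (any(abs(meta$lat) > 90) || any(abs(meta$lon) > 180))
    .stopf("latitudes must be within [-90, 90] and longitudes within [-180, 180]")
  p <- cbind(meta$lon, meta$lat)
  n <- nrow(p)
  M <- matrix(0, n, n, dimnames = list(meta$strain, meta$strain))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    M[i, j] <- M[j, i] <-
      geosphere::distHaversine(p[i, ], p[j, ], r = 6371000) / 1000
  }
  M
}

#' Isolation by distance: IBS versus geography (Mantel test)
#'
#' Correlates log(IBS) with log(geographic distance + 1 km) between strain
#' pairs using a Mantel test (Pearson statistic, row/column permutations via
#' \pkg{vegan}; the reported p is two-sided on the permutation distribution,
#' since IBS is a similarity and isolation by distance appears as a negative
#' correlation). A vanishing R-squared indicates that geography does not
#' structure mitogenome similarity.
#'
#' @param consensuses character matrix strains x sites.
#' @param meta data.frame with `strain`, `lat`, `lon`; rows are matched to
#'   `rownames(consensuses)`.
#' @param permutations Mantel permutations (default 999).
#' @param seed RNG seed (same seed, same p-value).
#' @return list with `ibs`, `km` (matrices), `mantelR`, `r2`, `p`, and
#'   `degenerate` (TRUE when either matrix is constant, e.g. identical
#'   coordinates for all strains, in which case the statistic is undefined).
#' @export
ibsVsGeography <- function(consensuses, meta, permutations = 999L,
                           seed = 1L) {
  if (nrow(consensuses) < 4L) .stopf("need >= 4 strains with coordinates")
  meta <- meta[match(rownames(consensuses), meta$strain), , drop = FALSE]
  if (anyNA(meta$strain)) .stopf("metadata missing for some strains")
  ibs <- ibsMatrix(consensuses)
  km <- haversineKm(meta)
  logIbs <- log(ibs)
  logKm <- log(km + 1)
  off <- upper.tri(ibs)
  sdI <- stats::sd(logIbs[off]); sdK <- stats::sd(logKm[off])
  if (!all(is.finite(logIbs[off])) || !is.finite(sdI) || !is.finite(sdK) ||
      sdI == 0 || sdK == 0)
    return(list(ibs = ibs, km = km, mantelR = NA_real_, r2 = NA_real_,
                p = NA_real_, degenerate = TRUE))
  set.seed(seed)
  mt <- suppressMessages(
    vegan::mantel(stats::as.dist(logKm), stats::as.dist(logIbs),
                  method = "pearson", permutations = permutations))
  r <- unname(mt$statistic)
  # two-sided permutation p: IBS is a similarity, so association with
  # distance appears as a negative Mantel r
  p <- if (length(mt$perm))
    (1 + sum(abs(mt$perm) >= abs(r))) / (1 + length(mt$perm))
  else NA_real_
  list(ibs = ibs, km = km, mantelR = r, r2 = r^2, p = p,
       degenerate = FALSE)
}
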