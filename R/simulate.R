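#' @include AllClasses.R
NULL

#' Evolve a gene order by known rearrangement events
#'
#' Applies a specified number of single-gene losses, strand inversions and
#' translocations (relocation to a uniform random position) to an ancestral
#' gene order, in random event order, recording a ground-truth event log
#' sufficient to replay the evolution exactly. This is the generator used to
#' validate the rearrangement classifier: with one planted inversion,
#' [classifyEvents()] must report exactly one inversion.
#'
#' @param ancestral a [GeneOrder-class].
#' @param nLoss,nInv,nTrans event counts (`nLoss` must be < gene count).
#' @param seed RNG seed.
#' @param newId id for the evolved order.
#' @return list with `order` (the evolved [GeneOrder-class], universe kept
#'   from the ancestor) and `truth` (list: `seed`, `log` -- a data.frame of
#'   `step`, `type`, `gene`, `position`).
#' @seealso [replayGeneOrder()]
#' @export
evolveGeneOrder <- function(ancestral, nLoss = 0L, nInv = 0L, nTrans = 0L,
                            seed = 1L, newId = NULL) {
  genes <- orderGenes(ancestral)
  strands <- orderStrands(ancestral)
  if (nLoss >= length(genes))
    .stopf("requested losses (%d) must be fewer than genes (%d)",
           nLoss, length(genes))
  set.seed(seed)
  types <- sample(c(rep("loss", nLoss), rep("inversion", nInv),
                    rep("translocation", nTrans)))
  log <- data.frame(step = integer(0), type = character(0),
                    gene = character(0), position = integer(0))
  for (k in seq_along(types)) {
    ty <- types[k]
    g <- sample(genes, 1L)
    i <- match(g, genes)
    pos <- NA_integer_
    if (ty == "loss") {
      genes <- genes[-i]; strands <- strands[-i]
    } else if (ty == "inversion") {
      strands[i] <- if (strands[i] == "+") "-" else "+"
    } else {
      st <- strands[i]
      genes <- genes[-i]; strands <- strands[-i]
      pos <- sample.int(length(genes) + 1L, 1L)
      genes <- append(genes, g, after = pos - 1L)
      strands <- append(strands, st, after = pos - 1L)
    }
    log <- rbind(log, data.frame(step = k, type = ty, gene = g,
                                 position = pos))
  }
  if (is.null(newId)) newId <- paste0(genomeId(ancestral), "_evolved")
  list(order = GeneOrder(newId, genes, strands,
                         universe = orderUniverse(ancestral)),
       truth = list(seed = seed, log = log))
}

#' Replay a recorded gene-order event log
#'
#' Deterministically reapplies an event log from [evolveGeneOrder()] to the
#' ancestral order; the result must equal the originally emitted order
#' (the generator's replay invariant).
#'
#' @param ancestral the ancestral [GeneOrder-class].
#' @param log event-log data.frame (`type`, `gene`, `position`).
#' @param newId id for the replayed order.
#' @return a [GeneOrder-class].
#' @export
replayGeneOrder <- function(ancestral, log, newId = "replayed") {
  genes <- orderGenes(ancestral)
  strands <- orderStrands(ancestral)
  for (k in seq_len(nrow(log))) {
    g <- log$gene[k]
    i <- match(g, genes)
    switch(log$type[k],
      loss = { genes <- genes[-i]; strands <- strands[-i] },
      inversion = { strands[i] <- if (strands[i] == "+") "-" else "+" },
      translocation = {
        st <- strands[i]
        genes <- genes[-i]; strands <- strands[-i]
        genes <- append(genes, g, after = log$position[k] - 1L)
        strands <- append(strands, st, after = log$position[k] - 1L)
      })
  }
  GeneOrder(newId, genes, strands, universe = orderUniverse(ancestral))
}

# M0-style codon substitution machinery for one genetic code:
# single-nucleotide neighbours among sense codons with transition and
# synonymy flags
.codonModel <- function(codeTable = "4") {
  key <- paste0("m0_", codeTable)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  code <- .geneticCode(codeTable)
  sense <- names(code)[code != "*"]
  aa <- unname(code[sense])
  chars <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  isTi <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
                         (a %in% c("C", "T") && b %in% c("C", "T"))
  nb <- vector("list", length(sense))
  for (i in seq_along(sense)) {
    tgt <- integer(0); ti <- logical(0); syn <- logical(0)
    for (pos in 1:3) for (b in setdiff(.BASES, chars[i, pos])) {
      mut <- chars[i, ]; mut[pos] <- b
      j <- match(paste(mut, collapse = ""), sense)
      if (is.na(j)) next  # stop codon: rejected
      tgt <- c(tgt, j)
      ti <- c(ti, isTi(chars[i, pos], b))
      syn <- c(syn, aa[j] == aa[i])
    }
    nb[[i]] <- list(tgt = tgt, ti = ti, syn = syn)
  }
  out <- list(sense = sense, aa = aa, nb = nb)
  .cache[[key]] <- out
  out
}

#' Simulate a pair of coding sequences under an M0 codon model
#'
#' Draws an ancestral sequence uniformly from the sense codons and evolves
#' two independent branches of length `t/2` under a continuous-time codon
#' process with transition/transversion ratio `kappa` and nonsynonymous rate
#' multiplier `omega`; substitutions that would create a stop codon are
#' rejected. Rates are scaled so that `t` is the expected number of
#' substitutions per codon along the whole path (at `omega = 1`). Codon
#' frequencies are uniform, the simplest parameterisation whose omega the
#' NG86 estimator should approximately recover.
#'
#' @param nCodons sequence length in codons.
#' @param omega nonsynonymous/synonymous rate ratio (> 0).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param t total divergence between the two sequences (> 0), expected
#'   substitutions per codon.
#' @param codeTable NCBI genetic-code id (default `"4"`).
#' @param seed RNG seed.
#' @return list with `cdsA`, `cdsB` (character strings) and `truth` (list:
#'   `ancestral`, `omega`, `kappa`, `t`, `substitutions` -- realised counts
#'   per branch).
#' @export
simulateCodonPair <- function(nCodons, omega, kappa = 2, t = 0.3,
                              codeTable = "4", seed = 1L) {
  if (omega <= 0 || t <= 0) .stopf("omega and t must be > 0")
  mod <- .codonModel(codeTable)
  set.seed(seed)
  ns <- length(mod$sense)
  rates <- lapply(mod$nb, function(x)
    ifelse(x$ti, kappa, 1) * ifelse(x$syn, 1, omega))
  total <- vapply(rates, sum, numeric(1))
  # scale so that one unit of t is one expected substitution per codon
  # under the neutral version of the same process
  neutralTotal <- vapply(mod$nb, function(x) sum(ifelse(x$ti, kappa, 1)),
                         numeric(1))
  scale <- mean(neutralTotal)
  anc <- sample.int(ns, nCodons, replace = TRUE)
  evolve <- function(idx, T) {
    nsub <- 0L
    for (p in seq_along(idx)) {
      i <- idx[p]
      time <- 0
      repeat {
        r <- total[i] / scale
        if (r <= 0) break
        time <- time + stats::rexp(1L, r)
        if (time > T) break
        i <- mod$nb[[i]]$tgt[sample.int(length(rates[[i]]), 1L,
                                        prob = rates[[i]])]
        nsub <- nsub + 1L
      }
      idx[p] <- i
    }
    attr(idx, "nsub") <- nsub
    idx
  }
  a <- evolve(anc, t / 2)
  b <- evolve(anc, t / 2)
  list(cdsA = paste(mod$sense[a], collapse = ""),
       cdsB = paste(mod$sense[b], collapse = ""),
       truth = list(ancestral = paste(mod$sense[anc], collapse = ""),
                    omega = omega, kappa = kappa, t = t,
                    substitutions = c(attr(a, "nsub"), attr(b, "nsub"))))
}

#' Simulate a strain population with SNPs, heteroplasmy and sequencing depth
#'
#' Generates per-strain haplotypes from a single reference (no
#' recombination), injects heteroplasmic sites at specified minor-allele
#' fractions, and emits a pileup-style allele-depth matrix with Poisson
#' depth and uniform sequencing error, plus geographic coordinates -- the
#' full input of the population-genetics stage, with ground truth attached.
#'
#' @param refLength reference length, bp.
#' @param nStrains number of strains.
#' @param thetaPerSite per-site per-strain mutation probability in
#'   `[0, 0.75)`.
#' @param hetSpec heteroplasmy specification: `NULL`, a data.frame with
#'   `strain` (index), `site`, `fraction`, or a list
#'   `list(n = , fraction = )` drawing that many random (strain, site)
#'   pairs.
#' @param depth mean sequencing depth (Poisson).
#' @param errorRate per-base sequencing error probability (errors spread
#'   uniformly over the three other bases).
#' @param coordsSpec list with `latRange`, `lonRange` (uniform draws).
#' @param genealogy `"star"` (independent strain lineages; default, which
#'   keeps expected SNP counts analytic) or `"chain"` (each strain inherits
#'   its predecessor's mutations, creating shared derived alleles).
#' @param atContent AT proportion of the reference (default 0.75, mimicking
#'   AT-rich mitogenomes).
#' @param seed RNG seed.
#' @param species species label written into the metadata.
#' @return list with `vm` (a [VariantMatrix-class]), `meta` (data.frame
#'   `strain`, `species`, `lat`, `lon`) and `truth` (list: `reference`,
#'   `haplotypes` -- strains x sites matrix, `het` -- the realised
#'   heteroplasmy table with minor bases, `theta`, `seed`).
#' @export
simulatePopulation <- function(refLength, nStrains, thetaPerSite,
                               hetSpec = NULL, depth = 100, errorRate = 0.005,
                               coordsSpec = list(latRange = c(18, 50),
                                                 lonRange = c(75, 130)),
                               genealogy = c("star", "chain"),
                               atContent = 0.75, seed = 1L,
                               species = "sim") {
  genealogy <- match.arg(genealogy)
  if (thetaPerSite < 0 || thetaPerSite >= 0.75)
    .stopf("thetaPerSite must be in [0, 0.75)")
  if (depth < 1) .stopf("depth must be >= 1")
  set.seed(seed)
  L <- as.integer(refLength)
  ref <- sample(.BASES, L, replace = TRUE,
                prob = c(atContent / 2, (1 - atContent) / 2,
                         (1 - atContent) / 2, atContent / 2))
  strains <- sprintf("S%02d", seq_len(nStrains))
  hap <- matrix(rep(ref, each = nStrains), nStrains, L)
  mutate <- function(row) {
    hit <- which(stats::runif(L) < thetaPerSite)
    if (length(hit)) {
      row[hit] <- vapply(row[hit], function(b)
        sample(setdiff(.BASES, b), 1L), character(1))
    }
    row
  }
  if (genealogy == "star") {
    for (s in seq_len(nStrains)) hap[s, ] <- mutate(ref)
  } else {
    prev <- ref
    for (s in seq_len(nStrains)) { prev <- mutate(prev); hap[s, ] <- prev }
  }

  # normalise heteroplasmy specification
  if (is.null(hetSpec)) {
    het <- data.frame(strain = integer(0), site = integer(0),
                      fraction = numeric(0))
  } else if (is.data.frame(hetSpec)) {
    het <- hetSpec
  } else {
    het <- data.frame(
      strain = sample.int(nStrains, hetSpec$n, replace = TRUE),
      site = sample.int(L, hetSpec$n, replace = FALSE),
      fraction = hetSpec$fraction)
  }
  het$minor <- vapply(seq_len(nrow(het)), function(r)
    sample(setdiff(.BASES, hap[het$strain[r], het$site[r]]), 1L),
    character(1))

  baseIdx <- function(b) match(b, .BASES)
  depths <- array(0L, dim = c(nStrains, L, 4L))
  otherIdx <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                    c(1L, 2L, 3L))
  for (s in seq_len(nStrains)) {
    tot <- stats::rpois(L, depth)
    f <- numeric(L)
    minorB <- integer(L)
    hs <- het[het$strain == s, , drop = FALSE]
    if (nrow(hs)) { f[hs$site] <- hs$fraction; minorB[hs$site] <- baseIdx(hs$minor) }
    minorReads <- stats::rbinom(L, tot, f)
    majorReads <- tot - minorReads
    # sequencing error pulls reads away from the true allele, spread
    # uniformly over the three other bases
    splitErr <- function(nTrue, trueB) {
      err <- stats::rbinom(L, nTrue, errorRate)
      keep <- nTrue - err
      e1 <- stats::rbinom(L, err, 1 / 3)
      e2 <- stats::rbinom(L, err - e1, 1 / 2)
      e3 <- err - e1 - e2
      cnt <- matrix(0L, L, 4L)
      cnt[cbind(seq_len(L), trueB)] <- keep
      oth <- otherIdx[trueB, , drop = FALSE]
      cnt[cbind(seq_len(L), oth[, 1L])] <- cnt[cbind(seq_len(L), oth[, 1L])] + e1
      cnt[cbind(seq_len(L), oth[, 2L])] <- cnt[cbind(seq_len(L), oth[, 2L])] + e2
      cnt[cbind(seq_len(L), oth[, 3L])] <- cnt[cbind(seq_len(L), oth[, 3L])] + e3
      cnt
    }
    majB <- baseIdx(hap[s, ])
    cnt <- splitErr(majorReads, majB)
    if (any(minorReads > 0L)) {
      mb <- ifelse(minorB > 0L, minorB, 1L)
      cnt <- cnt + splitErr(minorReads, mb)
    }
    depths[s, , ] <- cnt
  }
  vm <- VariantMatrix(strains, seq_len(L), ref, depths)
  meta <- data.frame(
    strain = strains, species = species,
    lat = stats::runif(nStrains, coordsSpec$latRange[1L], coordsSpec$latRange[2L]),
    lon = stats::runif(nStrains, coordsSpec$lonRange[1L], coordsSpec$lonRange[2L]))
  dimnames(hap) <- list(strains, seq_len(L))
  list(vm = vm, meta = meta,
       truth = list(reference = paste(ref, collapse = ""), haplotypes = hap,
                    het = het, theta = thetaPerSite, seed = seed))
}

#' Build a synthetic repeat-bearing linear mitogenome
#'
#' Assembles a genome as 5' telomere + AT-rich coding core (toy annotated
#' genes) + central repeat + more core + 3' telomere, with all planted
#' repeat parameters recorded as ground truth. Used to validate
#' [detectTelomere()] and [detectCentralRepeats()] across the observed
#' range of unit lengths (tens to ~150 bp) and copy numbers (tens to
#' hundreds).
#'
#' @param coreLength total coding-core length, bp (split around the CR).
#' @param telomere5,telomere3 `NULL` or a list `list(unitLength =, copies =,
#'   gc =)`; a random unit of that length and GC is tandem-repeated.
#' @param cr `NULL` or a list `list(length =, at =)` for the central repeat
#'   (an AT-rich tandem repeat of an 8-mer).
#' @param nGenes number of toy PCG features planted in the core.
#' @param coreGc GC proportion of the core (default 0.2, AT-rich).
#' @param seed RNG seed.
#' @param id genome id.
#' @return list with `genome` (a [Mitogenome-class]) and `truth` (planted
#'   telomere units/copies, CR interval, gene intervals).
#' @export
buildRepeatGenome <- function(coreLength = 6000L,
                              telomere5 = list(unitLength = 32L, copies = 17L,
                                               gc = 0.39),
                              telomere3 = telomere5,
                              cr = list(length = 500L, at = 1),
                              nGenes = 8L, coreGc = 0.2, seed = 1L,
                              id = "synthetic") {
  set.seed(seed)
  mkTel <- function(spec) {
    if (is.null(spec)) return(list(seq = "", unit = NULL))
    repeat {  # require a primitive (aperiodic) unit so the planted period
              # is the smallest period the detector can find
      unit <- .randSeq(spec$unitLength, spec$gc)
      if (spec$unitLength == 1L || !.isPeriodic(unit)) break
    }
    list(seq = strrep(unit, spec$copies), unit = unit)
  }
  t5 <- mkTel(telomere5); t3 <- mkTel(telomere3)
  half <- coreLength %/% 2L
  mkCore <- function(n) .randSeq(n, coreGc)
  core1 <- mkCore(half)
  core2 <- mkCore(coreLength - half)
  crSeq <- ""
  if (!is.null(cr)) {
    at <- cr$at
    unit8 <- paste(sample(c("A", "T"), 8L, replace = TRUE), collapse = "")
    crSeq <- strrep(unit8, ceiling(cr$length / 8L))
    crSeq <- substring(crSeq, 1L, cr$length)
    if (at < 1) {  # sprinkle G/C to reach the requested AT content
      nGc <- round((1 - at) * cr$length)
      if (nGc > 0) {
        pos <- sample.int(cr$length, nGc)
        v <- strsplit(crSeq, "", fixed = TRUE)[[1L]]
        v[pos] <- sample(c("G", "C"), nGc, replace = TRUE)
        crSeq <- paste(v, collapse = "")
      }
    }
  }
  seqStr <- paste0(t5$seq, core1, crSeq, core2, t3$seq)
  L <- nchar(seqStr)
  feats <- list()
  if (nzchar(t5$seq))
    feats[[length(feats) + 1L]] <- data.frame(
      gene = "telomere_5p", category = "telomere", start = 1L,
      end = nchar(t5$seq), strand = "+")
  if (nzchar(crSeq))
    feats[[length(feats) + 1L]] <- data.frame(
      gene = "CR", category = "central_repeat",
      start = nchar(t5$seq) + half + 1L,
      end = nchar(t5$seq) + half + nchar(crSeq), strand = "+")
  if (nzchar(t3$seq))
    feats[[length(feats) + 1L]] <- data.frame(
      gene = "telomere_3p", category = "telomere",
      start = L - nchar(t3$seq) + 1L, end = L, strand = "+")
  # toy genes tiled over the two core segments, strands switching at the CR
  geneLen <- max(60L, (coreLength %/% nGenes) %/% 2L)
  geneLen <- geneLen - geneLen %% 3L
  offsets <- round(seq(1L, coreLength - geneLen,
                       length.out = max(nGenes, 1L)))
  genes <- list()
  for (gi in seq_len(nGenes)) {
    off <- offsets[gi]
    # keep toy genes clear of the CR insertion point
    if (off <= half && off + geneLen - 1L > half) off <- half - geneLen
    gs <- nchar(t5$seq) + off + if (off > half) nchar(crSeq) else 0L
    genes[[gi]] <- data.frame(
      gene = sprintf("gene%02d", gi), category = "PCG",
      start = gs, end = gs + geneLen - 1L,
      strand = if (off > half) "-" else "+")
  }
  featDf <- do.call(rbind, c(feats, genes))
  genome <- Mitogenome(id, seqStr, featDf, topology = "linear",
                       source = "synthetic")
  list(genome = genome,
       truth = list(
         telomere5 = if (is.null(telomere5)) NULL
                     else c(telomere5, list(unit = t5$unit)),
         telomere3 = if (is.null(telomere3)) NULL
                     else c(telomere3, list(unit = t3$unit)),
         cr = if (is.null(cr)) NULL
              else c(nchar(t5$seq) + half + 1L,
                     nchar(t5$seq) + half + nchar(crSeq)),
         genes = do.call(rbind, genes), seed = seed))
}

# TRUE when a string equals a tandem repetition of a shorter unit
.isPeriodic <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n %/% 2L)) {
    if (n %% p != 0L) next
    if (strrep(substring(s, 1L, p), n %/% p) == s) return(TRUE)
  }
  FALSE
}
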