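# Independent oracle implementations used to cross-check the package.
# These deliberately use different mechanics (explicit loops, string
# mutation, recursive enumeration) from the implementations they test.

# ---- signed-permutation utilities ---------------------------------------

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in allPermutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# ---- rearrangement-event oracle -----------------------------------------
# Loop-based enumerator of per-gene loss/inversion/translocation following
# the predecessor-identity definition with a linear start sentinel.

oracleClassify <- function(refGenes, refStrands, tgtGenes, tgtStrands) {
  predecessorOf <- function(g, ordering) {
    i <- which(ordering == g)
    if (i == 1L) "<START>" else ordering[i - 1L]
  }
  refShared <- character(0)
  for (g in refGenes) if (g %in% tgtGenes) refShared <- c(refShared, g)
  tgtShared <- character(0)
  for (g in tgtGenes) if (g %in% refGenes) tgtShared <- c(tgtShared, g)
  scores <- integer(length(refGenes))
  lost <- inverted <- moved <- logical(length(refGenes))
  for (k in seq_along(refGenes)) {
    g <- refGenes[k]
    if (!(g %in% tgtGenes)) {
      lost[k] <- TRUE
    } else {
      if (refStrands[k] != tgtStrands[which(tgtGenes == g)]) inverted[k] <- TRUE
      if (predecessorOf(g, refShared) != predecessorOf(g, tgtShared))
        moved[k] <- TRUE
    }
    scores[k] <- sum(lost[k], inverted[k], moved[k])
  }
  list(lost = lost, inverted = inverted, translocated = moved,
       score = scores)
}

# ---- NG86 oracle ---------------------------------------------------------
# Recursive pathway enumeration and per-position site counting by explicit
# string surgery; no shared code with the package tables.

ng86Oracle <- function(a, b, codeTable = "4") {
  code <- Biostrings::getGeneticCode(codeTable)
  bases <- c("A", "C", "G", "T")
  codonsOf <- function(s) {
    n <- nchar(s) %/% 3L
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  synSitesOf <- function(codon) {
    total <- 0
    for (pos in 1:3) {
      orig <- substring(codon, pos, pos)
      nSyn <- 0; nOk <- 0
      for (nb in bases) {
        if (nb == orig) next
        mut <- codon
        substring(mut, pos, pos) <- nb
        if (code[[mut]] == "*") next
        nOk <- nOk + 1
        if (code[[mut]] == code[[codon]]) nSyn <- nSyn + 1
      }
      if (nOk > 0) total <- total + nSyn / nOk
    }
    total
  }
  # recursive enumeration of all mutational orders between two codons
  pathsBetween <- function(from, to) {
    dpos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(dpos)) return(list())
    recurse <- function(cur, remaining, steps) {
      if (!length(remaining)) return(list(steps))
      out <- list()
      for (p in remaining) {
        nxt <- cur
        substring(nxt, p, p) <- substring(to, p, p)
        out <- c(out, recurse(nxt, setdiff(remaining, p),
                              c(steps, list(c(cur, nxt)))))
      }
      out
    }
    recurse(from, dpos, list())
  }
  classifyPath <- function(path) {
    throughStop <- FALSE
    syn <- 0; non <- 0
    for (st in path) {
      aa1 <- code[[st[1]]]; aa2 <- code[[st[2]]]
      if (aa2 == "*" || aa1 == "*") { throughStop <- TRUE; non <- non + 1 }
      else if (aa1 == aa2) syn <- syn + 1
      else non <- non + 1
    }
    list(syn = syn, non = non, blocked = throughStop)
  }
  ca <- codonsOf(toupper(a)); cb <- codonsOf(toupper(b))
  stopifnot(length(ca) == length(cb))
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (code[[ca[i]]] == "*" || code[[cb[i]]] == "*") next
    used <- used + 1
    S <- S + (synSitesOf(ca[i]) + synSitesOf(cb[i])) / 2
    if (ca[i] != cb[i]) {
      paths <- pathsBetween(ca[i], cb[i])
      cls <- lapply(paths, classifyPath)
      # the final codon of a path is cb[i], never a blocked endpoint
      ok <- Filter(function(x) !x$blocked, cls)
      if (!length(ok)) ok <- cls
      Sd <- Sd + mean(sapply(ok, `[[`, "syn"))
      Nd <- Nd + mean(sapply(ok, `[[`, "non"))
    }
  }
  N <- 3 * used - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ks = jc(pS), ka = jc(pN))
}

# ---- six-frame ORF oracle ------------------------------------------------
# Brute force: every start-codon position, extended to the first in-frame
# stop; keep those whose start is the first after the previous stop.

orfOracle <- function(seq, minLen = 75L, codeTable = "4",
                      startCodon = "ATG") {
  code <- Biostrings::getGeneticCode(codeTable)
  stops <- names(code)[code == "*"]
  revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  scan1 <- function(s, strandLab, L) {
    found <- list()
    for (i in seq_len(max(0L, nchar(s) - 2L))) {
      if (substring(s, i, i + 2L) != startCodon) next
      # is there an in-frame stop (or a start of the same frame) before i?
      blocked <- FALSE
      j <- i - 3L
      while (j >= 1L) {
        cod <- substring(s, j, j + 2L)
        if (cod %in% stops) break
        if (cod == startCodon) { blocked <- TRUE; break }
        j <- j - 3L
      }
      if (blocked) next
      # extend to first stop
      j <- i
      endAt <- NA_integer_; open <- FALSE
      while (j + 2L <= nchar(s)) {
        if (substring(s, j, j + 2L) %in% stops) { endAt <- j + 2L; break }
        j <- j + 3L
      }
      if (is.na(endAt)) {
        endAt <- i - 1L + ((nchar(s) - i + 1L) %/% 3L) * 3L
        open <- TRUE
      }
      len <- endAt - i + 1L
      if (len < minLen) next
      if (strandLab == "+") pos <- c(i, endAt)
      else pos <- c(L - endAt + 1L, L - i + 1L)
      found[[length(found) + 1L]] <-
        data.frame(start = pos[1L], end = pos[2L], strand = strandLab,
                   lengthNt = len, open = open)
    }
    found
  }
  L <- nchar(seq)
  out <- c(scan1(toupper(seq), "+", L), scan1(revcomp(seq), "-", L))
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), lengthNt = integer(0),
                      open = logical(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

# Welch t statistic by the textbook formula
welchOracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}
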