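#' @include AllClasses.R
NULL

# category <-> GFF3 type maps
.CAT2TYPE <- c(PCG = "gene", tRNA = "tRNA", rRNA = "rRNA",
               telomere = "telomere", central_repeat = "repeat_region",
               other = "region")

.type2cat <- function(type) {
  type <- as.character(type)
  out <- rep("other", length(type))
  out[type %in% c("gene", "CDS", "mRNA", "protein_coding_gene")] <- "PCG"
  out[type %in% c("tRNA", "tRNA_gene")] <- "tRNA"
  out[type %in% c("rRNA", "rRNA_gene")] <- "rRNA"
  out[type %in% c("telomere", "telomeric_repeat")] <- "telomere"
  out[type %in% c("repeat_region", "central_repeat")] <- "central_repeat"
  out
}

#' Read a mitogenome from FASTA plus annotation
#'
#' Loads one linear mitochondrial genome from a FASTA file and its gene
#' features from either a GFF3 file (coordinates 1-based inclusive, imported
#' via \pkg{rtracklayer}) or a GenBank flat file (minimal parser supporting
#' `a..b` and `complement(a..b)` locations).
#'
#' @param fastaPath path to the FASTA file (first record used unless `id`
#'   names another).
#' @param annotationPath path to the annotation file.
#' @param dialect `"gff3"` or `"genbank"`.
#' @param id optional record id to select from a multi-FASTA.
#' @return a [Mitogenome-class] with features in coordinate order.
#' @details Annotation records referencing a contig absent from the FASTA, or
#'   with coordinates outside the sequence, raise a malformed-annotation
#'   error; unrecognised strand symbols raise an error naming the feature.
#'   A `topology=` token in the FASTA description is honoured
#'   (default linear).
#' @seealso [writeMitogenome()]
#' @export
readMitogenome <- function(fastaPath, annotationPath,
                           dialect = c("gff3", "genbank"), id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(fastaPath)) .stopf("FASTA file not found: %s", fastaPath)
  if (!file.exists(annotationPath))
    .stopf("annotation file not found: %s", annotationPath)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  pick <- if (is.null(id)) 1L else match(id, ids)
  if (is.na(pick)) .stopf("record '%s' not found in %s", id, fastaPath)
  topology <- if (grepl("topology=circular", headers[pick])) "circular"
              else "linear"
  gid <- ids[pick]
  seq <- seqs[[pick]]

  feat <- switch(dialect,
    gff3 = .readGff3Features(annotationPath, gid),
    genbank = .readGenBankFeatures(annotationPath, gid)
  )
  if (nrow(feat)) {
    if (any(feat$start < 1L) || any(feat$end > length(seq)) ||
        any(feat$start > feat$end))
      .stopf("malformed annotation: feature '%s' outside [1, %d] in %s",
             feat$gene[which(feat$start < 1L | feat$end > length(seq) |
                             feat$start > feat$end)[1L]],
             length(seq), annotationPath)
  }
  Mitogenome(gid, seq, if (nrow(feat)) feat else NULL, topology = topology,
             source = paste(fastaPath, annotationPath, sep = " + "))
}

.readGff3Features <- function(path, gid) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   .stopf("malformed annotation in %s: %s", path,
                          conditionMessage(e)))
  if (length(gr) == 0L)
    return(data.frame(gene = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  seqn <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqn == gid))
    .stopf("malformed annotation: %s references contig '%s' absent from FASTA record '%s'",
           path, setdiff(seqn, gid)[1L], gid)
  mc <- mcols(gr)
  lab <- rep(NA_character_, length(gr))
  for (col in c("Name", "gene", "ID")) {
    if (col %in% colnames(mc)) {
      v <- as.character(mc[[col]])
      lab[is.na(lab) & !is.na(v)] <- v[is.na(lab) & !is.na(v)]
    }
  }
  lab[is.na(lab)] <- paste0("feature_", which(is.na(lab)))
  strands <- as.character(GenomicRanges::strand(gr))
  bad <- !strands %in% c("+", "-")
  if (any(bad))
    .stopf("unknown strand symbol '%s' for feature '%s' in %s",
           strands[which(bad)[1L]], lab[which(bad)[1L]], path)
  data.frame(gene = lab, category = .type2cat(mc$type),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = strands)
}

# minimal GenBank flat-file feature parser: handles "a..b",
# "complement(a..b)" and (span of) join(); /gene, /product, /note labels
.readGenBankFeatures <- function(path, gid) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  if (!length(fstart)) .stopf("malformed annotation: no FEATURES in %s", path)
  fend <- min(fend[fend > fstart[1L]], length(lines) + 1L)
  block <- lines[(fstart[1L] + 1L):(fend - 1L)]
  isKey <- grepl("^ {5}\\S", block)
  keyIdx <- which(isKey)
  feats <- list()
  for (i in seq_along(keyIdx)) {
    from <- keyIdx[i]
    to <- if (i < length(keyIdx)) keyIdx[i + 1L] - 1L else length(block)
    key <- sub("^ +(\\S+).*$", "\\1", block[from])
    if (key %in% c("source")) next
    loc <- sub("^ +\\S+ +", "", block[from])
    qual <- block[(from + 1L):to]
    # continuation lines of the location have no '/'
    cont <- qual[!grepl("^ +/", qual)]
    if (length(cont)) loc <- paste0(loc, gsub(" ", "", paste(cont, collapse = "")))
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) < 2L) next
    lab <- NA_character_
    for (q in c("gene", "product", "note", "label")) {
      hit <- grep(sprintf("^ +/%s=", q), qual, value = TRUE)
      if (length(hit)) {
        lab <- gsub('"', "", sub(sprintf("^ +/%s=", q), "", hit[1L]))
        break
      }
    }
    if (is.na(lab)) lab <- paste0(tolower(key), "_", i)
    cat2 <- switch(key,
      CDS = "PCG", gene = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      telomere = "telomere", repeat_region = "central_repeat", "other")
    feats[[length(feats) + 1L]] <- data.frame(
      gene = lab, category = cat2, start = min(nums), end = max(nums),
      strand = strand)
  }
  if (!length(feats))
    return(data.frame(gene = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  df <- do.call(rbind, feats)
  # GenBank lists both gene and CDS records for a PCG; keep one per label
  df[!duplicated(df[c("gene", "start", "end")]), , drop = FALSE]
}

#' Write a mitogenome to FASTA + GFF3
#'
#' Inverse of [readMitogenome()] for the GFF3 dialect; a
#' read-write-read round trip reproduces the genome exactly.
#'
#' @param genome a [Mitogenome-class].
#' @param fastaPath,gffPath output paths.
#' @return invisibly, the two paths.
#' @export
writeMitogenome <- function(genome, fastaPath, gffPath) {
  set <- Biostrings::DNAStringSet(list(genome@sequence))
  names(set) <- paste0(genomeId(genome), " topology=", genomeTopology(genome))
  Biostrings::writeXStringSet(set, fastaPath)
  fx <- geneFeatures(genome)
  gr <- GRanges(seqnames = genomeId(genome),
                ranges = IRanges(start(fx), end(fx)),
                strand = strand(fx))
  mcols(gr)$source <- "MitoArch"
  mcols(gr)$type <- unname(.CAT2TYPE[as.character(mcols(fx)$category)])
  mcols(gr)$Name <- as.character(mcols(fx)$gene)
  rtracklayer::export(gr, gffPath, format = "gff3")
  invisible(c(fastaPath, gffPath))
}

#' Extract the signed gene order of a genome
#'
#' Orders features of the requested categories by start coordinate, giving the
#' signed gene permutation used for rearrangement analysis. Telomere and
#' central-repeat features are never part of a gene order.
#'
#' @param genome a [Mitogenome-class].
#' @param categories feature categories to include
#'   (default `c("PCG", "tRNA", "rRNA")`).
#' @return a [GeneOrder-class] with `universe` set to the included labels.
#' @export
extractGeneOrder <- function(genome, categories = c("PCG", "tRNA", "rRNA")) {
  categories <- setdiff(categories, c("telomere", "central_repeat"))
  fx <- geneFeatures(genome)
  keep <- as.character(mcols(fx)$category) %in% categories
  if (!any(keep))
    .stopf("genome '%s' has no features in categories: %s",
           genomeId(genome), paste(categories, collapse = ", "))
  fx <- fx[keep]
  o <- order(start(fx), end(fx))
  fx <- fx[o]
  GeneOrder(genomeId(genome), as.character(mcols(fx)$gene),
            as.character(strand(fx)))
}

#' Region-level composition statistics
#'
#' Partitions the genome into functional region classes (telomere, CR, PCG,
#' rRNA, tRNA, intergenic) and reports total length, fraction of the genome
#' and GC content per class. Overlapping features are counted once via
#' interval union; a base covered by several classes is attributed to the
#' highest-priority one (telomere > CR > PCG > rRNA > tRNA). Features of
#' category `"other"` count as intergenic.
#'
#' @param genome a [Mitogenome-class].
#' @param excludeTelomeres when `TRUE`, telomere bases are dropped and
#'   fractions are relative to the telomere-free length, the convention used
#'   when quoting coding fractions of telomere-capped linear mitogenomes.
#' @return data.frame with columns `class`, `length`, `fraction`, `gc`.
#'   Lengths always sum to the (telomere-free) genome length.
#' @export
regionStats <- function(genome, excludeTelomeres = FALSE) {
  L <- genomeLength(genome)
  fx <- geneFeatures(genome)
  cats <- as.character(mcols(fx)$category)
  classes <- c("telomere", "central_repeat", "PCG", "rRNA", "tRNA")
  taken <- IRanges()
  rows <- list()
  seqChar <- .asChar(genomeSequence(genome))
  classSlice <- function(ir) {
    if (!length(ir)) return(NA_real_)
    segs <- substring(seqChar, start(ir), end(ir))
    .gc(paste(segs, collapse = ""))
  }
  for (cl in classes) {
    ir <- IRanges::reduce(IRanges(start(fx)[cats == cl], end(fx)[cats == cl]))
    ir <- IRanges::setdiff(ir, taken)
    taken <- IRanges::reduce(c(taken, ir))
    rows[[cl]] <- data.frame(
      class = if (cl == "central_repeat") "CR" else cl,
      length = sum(width(ir)), gc = classSlice(ir))
  }
  inter <- IRanges::setdiff(IRanges(1L, L), taken)
  rows[["intergenic"]] <- data.frame(class = "intergenic",
                                     length = sum(width(inter)),
                                     gc = classSlice(inter))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (excludeTelomeres) {
    telLen <- df$length[df$class == "telomere"]
    df <- df[df$class != "telomere", , drop = FALSE]
    denom <- L - telLen
  } else denom <- L
  df$fraction <- if (denom > 0) df$length / denom else NA_real_
  df[c("class", "length", "fraction", "gc")]
}

#' Translate a coding sequence
#'
#' Translation under a chosen NCBI genetic code, defaulting to table 4
#' (mold/protozoan mitochondrial), under which TGA encodes tryptophan and the
#' only stop codons are TAA and TAG -- the two stops observed in ciliate
#' mitogenomes.
#'
#' @param seq nucleotide string (character or `DNAString`); a trailing
#'   partial codon is trimmed.
#' @param codeTable NCBI genetic-code id (default `"4"`).
#' @return the protein as a character string; a terminal stop is stripped;
#'   internal stops are kept as `*` and reported via a warning (an
#'   annotation-review case, not an error). Ambiguous codons translate to `X`.
#' @export
translateCds <- function(seq, codeTable = "4") {
  s <- toupper(.asChar(seq))
  code <- .geneticCode(codeTable)
  cods <- .codons(s)
  if (!length(cods)) return("")
  aa <- unname(code[cods])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    warning(sprintf("internal stop codon(s) at codon position(s) %s",
                    paste(which(aa == "*"), collapse = ",")), call. = FALSE)
  paste(aa, collapse = "")
}

#' Strand-aware coding sequences of a genome
#'
#' @param genome a [Mitogenome-class].
#' @param categories feature categories to extract (default PCG).
#' @return named character vector of gene sequences (reverse-complemented for
#'   minus-strand genes).
#' @export
cdsSequences <- function(genome, categories = "PCG") {
  fx <- geneFeatures(genome)
  keep <- as.character(mcols(fx)$category) %in% categories
  fx <- fx[keep]
  if (!length(fx)) return(setNames(character(0), character(0)))
  seqChar <- .asChar(genomeSequence(genome))
  out <- substring(seqChar, start(fx), end(fx))
  minus <- as.character(strand(fx)) == "-"
  out[minus] <- vapply(out[minus], .revcomp, character(1))
  setNames(out, as.character(mcols(fx)$gene))
}

#' Stop codon usage of annotated protein-coding genes
#'
#' Counts the terminal codons of all annotated PCGs per genome; in ciliate
#' mitogenomes only TAA and TAG occur.
#'
#' @param genomes a [Mitogenome-class] or a list of them.
#' @return data.frame with columns `genome`, `TAA`, `TAG`, `other`.
#' @export
stopCodonUsage <- function(genomes) {
  if (is(genomes, "Mitogenome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    cds <- cdsSequences(g)
    term <- vapply(cds, function(s) {
      n <- nchar(s)
      n <- n - n %% 3L
      if (n < 3L) return("")
      substring(s, n - 2L, n)
    }, character(1))
    data.frame(genome = genomeId(g),
               TAA = sum(term == "TAA"),
               TAG = sum(term == "TAG"),
               other = sum(term != "" & !term %in% c("TAA", "TAG")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
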