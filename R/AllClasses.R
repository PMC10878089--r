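#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges start end strand width
#' @importFrom IRanges IRanges
NULL

.FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "telomere", "central_repeat",
                         "other")

#' Mitogenome: a linear mitochondrial genome with its gene features
#'
#' Container for one assembled mitochondrial genome: the nucleotide sequence,
#' its topology (ciliate mitogenomes are typically linear), and an ordered set
#' of gene features held as a [GenomicRanges::GRanges] with metadata columns
#' `gene` (unique label per genome) and `category` (one of `"PCG"`, `"tRNA"`,
#' `"rRNA"`, `"telomere"`, `"central_repeat"`, `"other"`).
#'
#' Feature coordinates follow the Bioconductor convention (1-based, inclusive),
#' so a GFF3 record at `1..6` becomes a width-6 feature starting at 1.
#' Duplicate gene labels are disambiguated with positional suffixes
#' (`nad1_a`, `nad1_b`), mirroring the split-gene naming used for ciliate
#' `nad1`.
#'
#' @slot id single genome identifier.
#' @slot sequence a [Biostrings::DNAString].
#' @slot topology `"linear"` or `"circular"`.
#' @slot features a `GRanges` with `gene` and `category` metadata columns.
#' @slot source free-text provenance (file paths or `"synthetic"`).
#'
#' @seealso [readMitogenome()], [extractGeneOrder()], [regionStats()]
#' @exportClass Mitogenome
setClass("Mitogenome",
  slots = c(
    id = "character",
    sequence = "DNAString",
    topology = "character",
    features = "GRanges",
    source = "character"
  )
)

setValidity("Mitogenome", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "'sequence' must be non-empty")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "'topology' must be 'linear' or 'circular'")
  fx <- object@features
  if (length(fx)) {
    mc <- mcols(fx)
    if (!all(c("gene", "category") %in% colnames(mc))) {
      msg <- c(msg, "features need 'gene' and 'category' metadata columns")
    } else {
      if (anyDuplicated(mc$gene))
        msg <- c(msg, "feature gene labels must be unique within a genome")
      if (!all(mc$category %in% .FEATURE_CATEGORIES))
        msg <- c(msg, paste0("feature categories must be one of: ",
                             paste(.FEATURE_CATEGORIES, collapse = ", ")))
    }
    if (any(start(fx) < 1L) || any(end(fx) > length(object@sequence)))
      msg <- c(msg, "feature intervals must lie within the genome sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Mitogenome
#'
#' @param id genome identifier.
#' @param sequence nucleotide sequence (character or `DNAString`).
#' @param features a `GRanges` with metadata columns `gene` and `category`,
#'   or a data.frame with columns `gene`, `category`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param topology `"linear"` (default) or `"circular"`.
#' @param source provenance text.
#' @return a [Mitogenome-class] object, features sorted by start coordinate
#'   and duplicate labels suffixed `_a`, `_b`, ...
#' @examples
#' g <- Mitogenome("toy", "ATGAAATAAGGCC",
#'   data.frame(gene = "orf1", category = "PCG",
#'              start = 1, end = 9, strand = "+"))
#' genomeLength(g)
#' @export
Mitogenome <- function(id, sequence, features = NULL, topology = "linear",
                       source = "in-memory") {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (is.null(features)) {
    features <- GRanges()
    mcols(features)$gene <- character(0)
    mcols(features)$category <- character(0)
  } else if (is.data.frame(features)) {
    strands <- as.character(features$strand)
    bad <- !strands %in% c("+", "-")
    if (any(bad))
      .stopf("unknown strand symbol '%s' for feature '%s'",
             strands[which(bad)[1L]], features$gene[which(bad)[1L]])
    features <- GRanges(
      seqnames = id,
      ranges = IRanges(start = features$start, end = features$end),
      strand = strands,
      gene = as.character(features$gene),
      category = as.character(features$category)
    )
  }
  if (length(features)) {
    o <- order(start(features), end(features))
    features <- features[o]
    mcols(features)$gene <- .disambiguate(as.character(mcols(features)$gene))
  }
  new("Mitogenome", id = id, sequence = sequence, topology = topology,
      features = features, source = source)
}

#' GeneOrder: a signed gene permutation
#'
#' The ordered list of gene labels of one genome together with their coding
#' strands, the unit of comparison for rearrangement analysis. `universe`
#' records the reference gene complement against which losses are judged.
#'
#' @slot genomeId genome identifier.
#' @slot genes ordered gene labels (unique).
#' @slot strands `"+"`/`"-"` per gene.
#' @slot universe label set of the reference gene complement.
#' @seealso [extractGeneOrder()], [classifyEvents()]
#' @exportClass GeneOrder
setClass("GeneOrder",
  slots = c(
    genomeId = "character",
    genes = "character",
    strands = "character",
    universe = "character"
  )
)

setValidity("GeneOrder", function(object) {
  msg <- character(0)
  if (length(object@genes) != length(object@strands))
    msg <- c(msg, "'genes' and 'strands' must have equal length")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene labels must be unique")
  if (length(object@strands) && !all(object@strands %in% c("+", "-")))
    msg <- c(msg, "strands must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneOrder
#'
#' @param genomeId genome identifier.
#' @param genes ordered gene labels.
#' @param strands strand per gene (`"+"`/`"-"`); recycled if length 1.
#' @param universe reference gene complement (defaults to `genes`).
#' @return a [GeneOrder-class].
#' @examples
#' GeneOrder("ref", c("cox1", "cob", "trnY"), c("+", "+", "-"))
#' @export
GeneOrder <- function(genomeId, genes, strands = "+", universe = genes) {
  if (length(strands) == 1L) strands <- rep(strands, length(genes))
  new("GeneOrder", genomeId = genomeId, genes = as.character(genes),
      strands = as.character(strands), universe = as.character(universe))
}

#' VariantMatrix: per-strain allele depths across mitogenome sites
#'
#' Pileup-derived base counts for a population of strains: for each strain and
#' genome site, the number of reads supporting A, C, G and T, plus the
#' reference base per site. This is the entry point for all population-level
#' statistics (consensus haplotypes, SNPs, heteroplasmy, pi, LD, IBS).
#'
#' @slot strains strain identifiers.
#' @slot sites 1-based genome coordinates (strictly increasing).
#' @slot ref reference base per site.
#' @slot depths integer array `strain x site x base` with base dimension
#'   named `A`, `C`, `G`, `T`.
#' @seealso [readAlleleDepths()], [consensusHaplotypes()], [callHeteroplasmy()]
#' @exportClass VariantMatrix
setClass("VariantMatrix",
  slots = c(
    strains = "character",
    sites = "integer",
    ref = "character",
    depths = "array"
  )
)

setValidity("VariantMatrix", function(object) {
  msg <- character(0)
  d <- dim(object@depths)
  if (length(d) != 3L ||
      d[1L] != length(object@strains) ||
      d[2L] != length(object@sites) ||
      d[3L] != 4L)
    msg <- c(msg, "'depths' must be a strains x sites x 4 array")
  if (any(object@depths < 0))
    msg <- c(msg, "depths must be non-negative")
  if (length(object@sites) && is.unsorted(object@sites, strictly = TRUE))
    msg <- c(msg, "'sites' must be strictly increasing")
  if (length(object@ref) != length(object@sites))
    msg <- c(msg, "'ref' must have one base per site")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantMatrix
#'
#' @param strains strain identifiers.
#' @param sites 1-based genome coordinates.
#' @param ref reference base per site.
#' @param depths integer array `strain x site x 4` (bases A,C,G,T).
#' @return a [VariantMatrix-class].
#' @export
VariantMatrix <- function(strains, sites, ref, depths) {
  dimnames(depths) <- list(strains, NULL, .BASES)
  new("VariantMatrix", strains = as.character(strains),
      sites = as.integer(sites), ref = toupper(as.character(ref)),
      depths = depths)
}

#' CodonAlignment: codon-aware nucleotide alignment
#'
#' Two or more nucleotide rows aligned so that gaps occur in whole codons;
#' the substrate of NG86 Ka/Ks estimation.
#'
#' @slot seqs aligned rows as a [Biostrings::DNAStringSet] (equal widths,
#'   divisible by 3; gaps as `-`).
#' @slot gene source gene label.
#' @seealso [alignCodons()], [kaksNG86()]
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  slots = c(seqs = "DNAStringSet", gene = "character")
)

setValidity("CodonAlignment", function(object) {
  msg <- character(0)
  w <- Biostrings::width(object@seqs)
  if (length(w) < 2L) msg <- c(msg, "need at least two aligned rows")
  if (length(unique(w)) > 1L) msg <- c(msg, "rows must have equal length")
  if (length(w) && w[1L] %% 3L != 0L)
    msg <- c(msg, "alignment length must be divisible by 3")
  if (length(msg)) msg else TRUE
})

#' Construct a CodonAlignment
#'
#' @param seqs named character vector or `DNAStringSet` of aligned rows.
#' @param gene source gene label.
#' @return a [CodonAlignment-class].
#' @export
CodonAlignment <- function(seqs, gene = NA_character_) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  new("CodonAlignment", seqs = seqs, gene = gene)
}
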