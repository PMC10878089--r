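#' MitoArch: comparative architecture of linear mitochondrial genomes
#'
#' See the package vignette for the scientific background and a tour of the
#' analysis stages: mitogenome I/O and region accounting, telomere/CR/ORF
#' detection, orthogroups and core-gene phylogenies, gene-order
#' rearrangement scoring (RF/RS), k-mer synteny blocks, NG86 Ka/Ks, and
#' population statistics, each validated against a ground-truthed
#' synthetic-data generator.
#'
#' @keywords internal
#' @aliases MitoArch-package
"_PACKAGE"

#' @import methods
#' @importFrom stats setNames rexp rbinom rpois runif sd var lm t.test
#'   cor.test coef as.dist complete.cases
#' @importFrom utils head combn read.delim write.table
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readDNAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject getGeneticCode
#'   reverseComplement
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges width reduce
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom rtracklayer import export
#' @importFrom ape nj prop.clades
#' @importFrom vegan mantel
#' @importFrom geosphere distHaversine
NULL
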