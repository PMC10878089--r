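#' @include AllClasses.R
NULL

#' Accessors for MitoArch classes
#'
#' `genomeId()`, `genomeSequence()`, `genomeLength()`, `geneFeatures()` and
#' `genomeTopology()` read the corresponding parts of a [Mitogenome-class];
#' `orderGenes()`, `orderStrands()` and `orderUniverse()` read a
#' [GeneOrder-class]; `strainNames()`, `siteCoords()`, `refBases()` and
#' `alleleDepths()` read a [VariantMatrix-class].
#'
#' @param x the object.
#' @return the slot contents.
#' @name accessors
#' @aliases genomeId genomeSequence genomeLength geneFeatures genomeTopology
#'   orderGenes orderStrands orderUniverse strainNames siteCoords refBases
#'   alleleDepths
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))
#' @rdname accessors
#' @export
setGeneric("genomeTopology", function(x) standardGeneric("genomeTopology"))
#' @rdname accessors
#' @export
setGeneric("orderGenes", function(x) standardGeneric("orderGenes"))
#' @rdname accessors
#' @export
setGeneric("orderStrands", function(x) standardGeneric("orderStrands"))
#' @rdname accessors
#' @export
setGeneric("orderUniverse", function(x) standardGeneric("orderUniverse"))
#' @rdname accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname accessors
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))
#' @rdname accessors
#' @export
setGeneric("refBases", function(x) standardGeneric("refBases"))
#' @rdname accessors
#' @export
setGeneric("alleleDepths", function(x) standardGeneric("alleleDepths"))

setMethod("genomeId", "Mitogenome", function(x) x@id)
setMethod("genomeSequence", "Mitogenome", function(x) x@sequence)
setMethod("genomeLength", "Mitogenome", function(x) length(x@sequence))
setMethod("geneFeatures", "Mitogenome", function(x) x@features)
setMethod("genomeTopology", "Mitogenome", function(x) x@topology)
setMethod("genomeId", "GeneOrder", function(x) x@genomeId)
setMethod("orderGenes", "GeneOrder", function(x) x@genes)
setMethod("orderStrands", "GeneOrder", function(x) x@strands)
setMethod("orderUniverse", "GeneOrder", function(x) x@universe)
setMethod("strainNames", "VariantMatrix", function(x) x@strains)
setMethod("siteCoords", "VariantMatrix", function(x) x@sites)
setMethod("refBases", "VariantMatrix", function(x) x@ref)
setMethod("alleleDepths", "VariantMatrix", function(x) x@depths)

setMethod("show", "Mitogenome", function(object) {
  cat("Mitogenome '", object@id, "': ", length(object@sequence), " bp ",
      object@topology, ", ", length(object@features), " features",
      sep = "")
  if (length(object@features)) {
    tab <- table(mcols(object@features)$category)
    cat(" (", paste(paste0(names(tab), ":", tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

setMethod("show", "GeneOrder", function(object) {
  signed <- paste0(ifelse(object@strands == "+", "+", "-"), object@genes)
  cat("GeneOrder '", object@genomeId, "' (", length(object@genes),
      " genes): ", paste(utils::head(signed, 8L), collapse = " "),
      if (length(signed) > 8L) " ..." else "", "\n", sep = "")
})

setMethod("show", "VariantMatrix", function(object) {
  cat("VariantMatrix: ", length(object@strains), " strains x ",
      length(object@sites), " sites; mean depth ",
      round(mean(apply(object@depths, c(1, 2), sum)), 1), "\n", sep = "")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment", if (!is.na(object@gene)) paste0(" [", object@gene, "]"),
      ": ", length(object@seqs), " rows x ",
      Biostrings::width(object@seqs)[1L] %/% 3L, " codons\n", sep = "")
})
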