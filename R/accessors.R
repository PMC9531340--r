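#' Accessors for VariantSet and GeneModel
#'
#' `refAllele()`/`altAllele()` return per-site alleles; `genotypeCalls()`,
#' `alleleDepths()` and `gqValues()` return site-by-role matrices;
#' `readDepth()` is the per-role total depth (sum of the two allele depths,
#' which is what both the filters and the SNP index consume, keeping the two
#' consistent).  `exonRanges()`/`intronRanges()` return genomic-order
#' intervals of a gene model; intron ordinals in the rest of the package
#' follow transcription order.
#'
#' @param x a [VariantSet-class] or [GeneModel-class] object.
#' @return See details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("alleleDepths", function(x) standardGeneric("alleleDepths"))
#' @rdname accessors
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))
#' @rdname accessors
#' @export
setGeneric("gqValues", function(x) standardGeneric("gqValues"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
setMethod("refAllele", "VariantSet", function(x) mcols(rowRanges(x))$ref)
#' @rdname accessors
setMethod("altAllele", "VariantSet", function(x) mcols(rowRanges(x))$alt)
#' @rdname accessors
setMethod("genotypeCalls", "VariantSet", function(x) assay(x, "genotype"))
#' @rdname accessors
setMethod("alleleDepths", "VariantSet",
    function(x) list(ref = assay(x, "refDepth"), alt = assay(x, "altDepth")))
#' @rdname accessors
setMethod("readDepth", "VariantSet",
    function(x) assay(x, "refDepth") + assay(x, "altDepth"))
#' @rdname accessors
setMethod("gqValues", "VariantSet", function(x) assay(x, "gq"))

#' @rdname accessors
setMethod("exonRanges", "GeneModel", function(x) x@exons)

#' @rdname accessors
setMethod("intronRanges", "GeneModel", function(x) {
    ex <- x@exons
    if (length(ex) < 2L) return(IRanges())
    IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1L] - 1L)
})

#' @rdname accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)

## intron ordinal in transcription order -> genomic-order index
.intronGenomicIndex <- function(gene, ordinal) {
    n <- length(gene@exons) - 1L
    stopifnot(ordinal >= 1L, ordinal <= n)
    if (gene@strand == "+") ordinal else n - ordinal + 1L
}

## genomic-order intron index -> transcription ordinal
.intronOrdinal <- function(gene, genomicIndex) {
    n <- length(gene@exons) - 1L
    if (gene@strand == "+") genomicIndex else n - genomicIndex + 1L
}

.exonOrdinal <- function(gene, genomicIndex) {
    n <- length(gene@exons)
    if (gene@strand == "+") genomicIndex else n - genomicIndex + 1L
}
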