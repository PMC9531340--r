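#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<-
#' @importFrom BiocGenerics start end width strand sort unlist
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
NULL

## The three sequenced entities of a MutMap design.  Column order is fixed so
## that every assay matrix can be indexed by role name.
.ROLES <- c("wt_parent", "mut_parent", "bulk")

.GENO_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Set of biallelic SNPs with per-role genotype, allele depth and quality
#'
#' A `VariantSet` is a [SummarizedExperiment::RangedSummarizedExperiment] whose
#' three columns are the fixed sample roles `wt_parent` (wild-type parent line),
#' `mut_parent` (EMS mutant parent) and `bulk` (the pooled recessive-phenotype
#' F2 plants), and whose rows are biallelic SNP sites.  Assays:
#' \describe{
#'   \item{genotype}{character, one of `"hom_ref"`, `"het"`, `"hom_alt"`,
#'     `"missing"`}
#'   \item{refDepth, altDepth}{integer read counts supporting the reference and
#'     alternate allele (the VCF AD field split per allele)}
#'   \item{gq}{integer genotype quality}
#' }
#' `rowRanges()` carries `ref` and `alt` single-nucleotide alleles as metadata
#' columns.  All coordinates are 1-based inclusive.
#'
#' @export
setClass("VariantSet", contains = "RangedSummarizedExperiment")

setValidity("VariantSet", function(object) {
    msg <- character()
    if (!identical(colnames(object), .ROLES))
        msg <- c(msg, sprintf("columns must be exactly: %s",
                              paste(.ROLES, collapse = ", ")))
    need <- c("genotype", "refDepth", "altDepth", "gq")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, sprintf("assays must include: %s",
                              paste(need, collapse = ", ")))
    mc <- mcols(rowRanges(object))
    if (!all(c("ref", "alt") %in% names(mc))) {
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' columns")
    } else if (nrow(object) > 0L) {
        ref <- mc$ref; alt <- mc$alt
        if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
            msg <- c(msg, "only single-nucleotide alleles are representable")
        if (any(ref == alt))
            msg <- c(msg, "ref and alt alleles must differ")
        if ("genotype" %in% names(assays(object)) &&
            !all(assay(object, "genotype") %in% .GENO_LEVELS))
            msg <- c(msg, sprintf("genotypes must be one of: %s",
                                  paste(.GENO_LEVELS, collapse = ", ")))
        for (a in c("refDepth", "altDepth", "gq"))
            if (a %in% names(assays(object)) && any(assay(object, a) < 0L))
                msg <- c(msg, sprintf("assay '%s' must be non-negative", a))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a VariantSet
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @param genotype,refDepth,altDepth,gq matrices with one row per site and
#'   columns `wt_parent`, `mut_parent`, `bulk`.
#' @return A [VariantSet-class] object.
#' @examples
#' vs <- VariantSet("A10", 228525L, "C", "T",
#'     genotype = cbind(wt_parent = "hom_ref", mut_parent = "hom_alt",
#'                      bulk = "hom_alt"),
#'     refDepth = cbind(wt_parent = 30L, mut_parent = 0L, bulk = 0L),
#'     altDepth = cbind(wt_parent = 0L, mut_parent = 25L, bulk = 48L),
#'     gq = cbind(wt_parent = 99L, mut_parent = 99L, bulk = 99L))
#' @export
VariantSet <- function(chrom, pos, ref, alt, genotype, refDepth, altDepth, gq) {
    n <- length(pos)
    fix <- function(m, mode = "integer") {
        m <- matrix(m, nrow = n, ncol = 3L, dimnames = list(NULL, .ROLES))
        if (mode == "integer") storage.mode(m) <- "integer"
        m
    }
    rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(rr)$ref <- as.character(ref)
    mcols(rr)$alt <- as.character(alt)
    se <- SummarizedExperiment(
        assays = SimpleList(genotype = fix(genotype, "character"),
                            refDepth = fix(refDepth), altDepth = fix(altDepth),
                            gq = fix(gq)),
        rowRanges = rr,
        colData = DataFrame(role = .ROLES, row.names = .ROLES))
    new("VariantSet", se)
}

#' Gene model with exon/intron structure and CDS boundaries
#'
#' Exons are stored as 1-based inclusive genomic intervals in ascending
#' genomic order; introns are the gaps between consecutive exons.  Ordinals
#' (exon 1, intron 2, ...) follow transcription order, i.e. they run
#' right-to-left for minus-strand genes.  The spliced CDS must have positive
#' length divisible by 3.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon intervals.
#' @slot cdsStart,cdsEnd genomic coordinates of the translated span
#'   (`cdsStart` < `cdsEnd` in genomic coordinates regardless of strand).
#' @export
setClass("GeneModel",
    representation(geneId = "character", chrom = "character",
                   strand = "character", exons = "IRanges",
                   cdsStart = "integer", cdsEnd = "integer"))

setValidity("GeneModel", function(object) {
    msg <- character()
    ex <- object@exons
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(ex) == 0L)
        msg <- c(msg, "gene must have at least one exon")
    else {
        if (is.unsorted(start(ex), strictly = TRUE) ||
            any(start(ex)[-1L] <= end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be sorted and non-overlapping")
        if (!.inExons(object@cdsStart, ex) || !.inExons(object@cdsEnd, ex))
            msg <- c(msg, "CDS boundaries must fall inside exons")
        len <- .splicedCdsLength(ex, object@cdsStart, object@cdsEnd)
        if (len <= 0L || len %% 3L != 0L)
            msg <- c(msg, sprintf(
                "spliced CDS length (%d nt) must be a positive multiple of 3", len))
    }
    if (length(msg)) msg else TRUE
})

.inExons <- function(pos, exons)
    any(pos >= start(exons) & pos <= end(exons))

## exonic nucleotides between cdsStart and cdsEnd, both inclusive
.splicedCdsLength <- function(exons, cdsStart, cdsEnd) {
    s <- pmax(start(exons), cdsStart)
    e <- pmin(end(exons), cdsEnd)
    sum(pmax(e - s + 1L, 0L))
}

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds 1-based inclusive exon boundaries in ascending
#'   genomic order.
#' @param cdsStart,cdsEnd genomic CDS boundaries (`cdsStart <= cdsEnd`).
#' @return A [GeneModel-class] object; invalid structure (overlapping exons,
#'   CDS outside exons, spliced CDS not a multiple of 3) is an error.
#' @examples
#' gm <- GeneModel("toy", "A10", "+", c(1, 151), c(102, 300), 1, 300)
#' @export
GeneModel <- function(geneId, chrom, strand, exonStarts, exonEnds,
                      cdsStart, cdsEnd) {
    new("GeneModel", geneId = as.character(geneId), chrom = as.character(chrom),
        strand = strand,
        exons = IRanges(as.integer(exonStarts), as.integer(exonEnds)),
        cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' Six-rule SNP filtration parameters
#'
#' Defaults reproduce the published cascade: parent depth outside \[3, 100\]
#' or bulk depth outside \[5, 150\] fails (strict inequalities, so the bounds
#' themselves pass), genotype quality below 20 fails, and only
#' EMS-spectrum substitutions (wild-type to mutant C>T or G>A) are kept.
#'
#' @slot parentDepthMin,parentDepthMax,bulkDepthMin,bulkDepthMax depth bounds.
#' @slot gqMin minimum genotype quality.
#' @slot emsOnly apply the EMS transition-spectrum rule.
#' @export
setClass("FilterParam",
    representation(parentDepthMin = "integer", parentDepthMax = "integer",
                   bulkDepthMin = "integer", bulkDepthMax = "integer",
                   gqMin = "integer", emsOnly = "logical"),
    prototype(parentDepthMin = 3L, parentDepthMax = 100L,
              bulkDepthMin = 5L, bulkDepthMax = 150L,
              gqMin = 20L, emsOnly = TRUE))

setValidity("FilterParam", function(object) {
    msg <- character()
    if (object@parentDepthMin > object@parentDepthMax ||
        object@bulkDepthMin > object@bulkDepthMax)
        msg <- c(msg, "depth minima must not exceed maxima")
    if (object@gqMin < 0L) msg <- c(msg, "gqMin must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @rdname FilterParam-class
#' @param parentDepthMin,parentDepthMax,bulkDepthMin,bulkDepthMax,gqMin,emsOnly
#'   see slots.
#' @return A `FilterParam` object.
#' @export
FilterParam <- function(parentDepthMin = 3, parentDepthMax = 100,
                        bulkDepthMin = 5, bulkDepthMax = 150,
                        gqMin = 20, emsOnly = TRUE) {
    new("FilterParam", parentDepthMin = as.integer(parentDepthMin),
        parentDepthMax = as.integer(parentDepthMax),
        bulkDepthMin = as.integer(bulkDepthMin),
        bulkDepthMax = as.integer(bulkDepthMax),
        gqMin = as.integer(gqMin), emsOnly = isTRUE(emsOnly))
}

#' Sliding-window SNP-index scan parameters
#'
#' @slot windowBp window width in bp (default 2 Mb).
#' @slot stepBp step between window centres in bp (default 10 kb).
#' @slot minSnps windows with fewer contributing SNPs are masked (default 3).
#' @slot threshold SNP-index threshold for candidate regions (default 0.80).
#' @slot smoothed apply the threshold to the window-smoothed track (default);
#'   `FALSE` thresholds the raw per-SNP indices instead.
#' @export
setClass("ScanParam",
    representation(windowBp = "numeric", stepBp = "numeric",
                   minSnps = "integer", threshold = "numeric",
                   smoothed = "logical"),
    prototype(windowBp = 2e6, stepBp = 1e4, minSnps = 3L,
              threshold = 0.80, smoothed = TRUE))

setValidity("ScanParam", function(object) {
    msg <- character()
    if (object@stepBp <= 0 || object@windowBp < object@stepBp)
        msg <- c(msg, "need windowBp >= stepBp > 0")
    if (object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname ScanParam-class
#' @param windowBp,stepBp,minSnps,threshold,smoothed see slots.
#' @return A `ScanParam` object.
#' @export
ScanParam <- function(windowBp = 2e6, stepBp = 1e4, minSnps = 3,
                      threshold = 0.80, smoothed = TRUE) {
    new("ScanParam", windowBp = windowBp, stepBp = stepBp,
        minSnps = as.integer(minSnps), threshold = threshold,
        smoothed = isTRUE(smoothed))
}

#' Simulation parameters for the F2 bulked-segregant design
#'
#' The defaults emulate the mapped experiment at desk scale: a 30-plant
#' recessive bulk sequenced to ~50x, parents to ~30x, EMS transitions at
#' 5 per Mb over a 2 x 10 Mb genome (about 100 sites), Haldane recombination
#' at 3 cM/Mb, and a causal G>A site mid-chromosome.
#'
#' @slot nChrom number of chromosomes.
#' @slot chromLength chromosome length in bp.
#' @slot emsRate EMS mutations per bp.
#' @slot causalChrom,causalPos location of the causal site.
#' @slot bulkSize number of recessive plants pooled.
#' @slot meanDepth mean bulk sequencing depth per site (Poisson).
#' @slot parentDepth mean parent sequencing depth per site (Poisson).
#' @slot seqError per-base sequencing error rate.
#' @slot cmPerMb recombination map density (Haldane, no interference).
#' @slot seed integer seed used by [simulateBulkSegregant()].
#' @export
setClass("SimParam",
    representation(nChrom = "integer", chromLength = "numeric",
                   emsRate = "numeric", causalChrom = "character",
                   causalPos = "numeric", bulkSize = "integer",
                   meanDepth = "numeric", parentDepth = "numeric",
                   seqError = "numeric", cmPerMb = "numeric", seed = "integer"),
    prototype(nChrom = 2L, chromLength = 1e7, emsRate = 5e-6,
              causalChrom = "chr1", causalPos = 5e6, bulkSize = 30L,
              meanDepth = 50, parentDepth = 30, seqError = 0.001,
              cmPerMb = 3, seed = 1L))

setValidity("SimParam", function(object) {
    msg <- character()
    if (object@bulkSize < 1L) msg <- c(msg, "bulkSize must be >= 1")
    if (object@emsRate < 0 || object@emsRate > 1 ||
        object@seqError < 0 || object@seqError > 1)
        msg <- c(msg, "rates must be in [0, 1]")
    if (!object@causalChrom %in% paste0("chr", seq_len(object@nChrom)))
        msg <- c(msg, "causalChrom must be one of the simulated chromosomes")
    if (object@causalPos < 1 || object@causalPos > object@chromLength)
        msg <- c(msg, "causalPos must lie within the chromosome")
    if (length(msg)) msg else TRUE
})

#' @rdname SimParam-class
#' @param nChrom,chromLength,emsRate,causalChrom,causalPos,bulkSize,meanDepth,parentDepth,seqError,cmPerMb,seed
#'   see slots.
#' @return A `SimParam` object.
#' @export
SimParam <- function(nChrom = 2, chromLength = 1e7, emsRate = 5e-6,
                     causalChrom = "chr1", causalPos = 5e6, bulkSize = 30,
                     meanDepth = 50, parentDepth = 30, seqError = 0.001,
                     cmPerMb = 3, seed = 1) {
    new("SimParam", nChrom = as.integer(nChrom), chromLength = chromLength,
        emsRate = emsRate, causalChrom = causalChrom, causalPos = causalPos,
        bulkSize = as.integer(bulkSize), meanDepth = meanDepth,
        parentDepth = parentDepth, seqError = seqError, cmPerMb = cmPerMb,
        seed = as.integer(seed))
}

#' Ground truth of a simulated EMS population
#'
#' @slot sites [GenomicRanges::GRanges] of EMS sites with metadata columns
#'   `ref`, `alt`, `rToCausal` (recombination fraction to the causal site)
#'   and `isCausal`.
#' @slot param the [SimParam-class] used.
#' @export
setClass("SimTruth",
    representation(sites = "GRanges", param = "SimParam"))

setValidity("SimTruth", function(object) {
    mc <- mcols(object@sites)
    msg <- character()
    if (!all(c("ref", "alt", "rToCausal", "isCausal") %in% names(mc)))
        return("sites need ref, alt, rToCausal, isCausal columns")
    if (sum(mc$isCausal) != 1L)
        msg <- c(msg, "exactly one causal site required")
    if (length(object@sites)) {
        sub <- paste0(mc$ref, ">", mc$alt)
        if (!all(sub %in% c("G>A", "C>T")))
            msg <- c(msg, "EMS substitutions must be G>A or C>T")
        if (any(mc$rToCausal < 0 | mc$rToCausal > 0.5))
            msg <- c(msg, "recombination fractions must be in [0, 0.5]")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "VariantSet", function(object) {
    cat(sprintf("VariantSet with %d biallelic SNP site(s), roles: %s\n",
                nrow(object), paste(colnames(object), collapse = ", ")))
    if (nrow(object) > 0L) {
        rr <- rowRanges(object)
        cat(sprintf("  %s:%d %s>%s ... %s:%d %s>%s\n",
                    as.character(seqnames(rr))[1L], start(rr)[1L],
                    mcols(rr)$ref[1L], mcols(rr)$alt[1L],
                    as.character(seqnames(rr))[nrow(object)],
                    start(rr)[nrow(object)],
                    mcols(rr)$ref[nrow(object)], mcols(rr)$alt[nrow(object)]))
    }
})

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel %s (%s%s): %d exon(s), %d intron(s), CDS %d-%d\n",
                object@geneId, object@chrom, object@strand,
                length(object@exons), max(length(object@exons) - 1L, 0L),
                object@cdsStart, object@cdsEnd))
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d EMS site(s) on %d chromosome(s); causal %s:%d\n",
                length(object@sites), object@param@nChrom,
                object@param@causalChrom, as.integer(object@param@causalPos)))
})
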