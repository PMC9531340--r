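#' Pipeline configuration
#'
#' Bundles the stage parameters of the full workflow (simulate -> filter ->
#' scan -> segregation/co-segregation -> annotate).  Defaults carry the
#' published analysis values where one exists: parent depth bounds 3/100,
#' bulk bounds 5/150, genotype quality 20, SNP-index threshold 0.80, 30-plant
#' recessive bulk.
#'
#' @slot sim a [SimParam-class].
#' @slot filter a [FilterParam-class].
#' @slot scan a [ScanParam-class].
#' @slot yates use the continuity-corrected chi-square.
#' @slot nF2 plants in the simulated phenotype/genotype tables.
#' @slot outDir output directory (created if needed).
#' @export
setClass("PipelineParam",
    representation(sim = "SimParam", filter = "FilterParam",
                   scan = "ScanParam", yates = "logical", nF2 = "integer",
                   outDir = "character"),
    prototype(yates = TRUE, nF2 = 93L, outDir = "mutmap_run"))

#' @rdname PipelineParam-class
#' @param sim,filter,scan,yates,nF2,outDir see slots.
#' @return A `PipelineParam` object.
#' @export
PipelineParam <- function(sim = SimParam(), filter = FilterParam(),
                          scan = ScanParam(), yates = TRUE, nF2 = 93,
                          outDir = tempfile("mutmap_run")) {
    new("PipelineParam", sim = sim, filter = filter, scan = scan,
        yates = isTRUE(yates), nF2 = as.integer(nF2), outDir = outDir)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full bulked-segregant workflow on simulated data
#'
#' Executes, in order: simulation of the EMS population and pooled
#' sequencing (seeded from `param@sim@seed`, so reruns are identical),
#' VCF round-trip, the six-rule filter, the SNP-index sliding-window scan
#' and candidate-region calling, the F2 segregation chi-square (observed
#' phenotype classes against 3:1), the KASP-style co-segregation check at
#' the causal SNP, and consequence annotation of a splice-donor G>A on a
#' simulated toy gene.  Per-stage outputs are written under `param@outDir`
#' (VCF, truth/track/region/phenotype/genotype TSVs, GFF3 + FASTA, and a
#' JSON run report); an empty filtered set is a warning, not an error, and
#' yields zero regions.
#'
#' @param param a [PipelineParam-class].
#' @return The run report, invisibly: a list with `seed`, `counts`,
#'   `filter_report`, `regions`, `segregation`, `cosegregation`,
#'   `annotation`, every number a pure function of the stage outputs.
#' @export
runPipeline <- function(param = PipelineParam()) {
    dir.create(param@outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(param@outDir, f)

    sim <- .stage("simulate", simulateBulkSegregant(param@sim))
    .stage("simulate", {
        writeVariantVcf(sim$variants, out("variants.vcf"))
        utils::write.table(
            as.data.frame(sim$truth@sites),
            out("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    })

    vs <- .stage("read_vcf", readVariantVcf(out("variants.vcf")))
    filt <- .stage("filter", filterVariants(vs, param@filter))
    .stage("filter", writeVariantVcf(filt$kept, out("filtered.vcf")))

    scan <- .stage("scan", {
        if (nrow(filt$kept) == 0L) {
            warning("no variants passed filtering; scan reports zero regions")
            list(points = data.frame(), track = NULL,
                 regions = callCandidateRegions(NULL, data.frame(
                     chrom = character(), pos = integer(),
                     index = numeric()), param@scan))
        } else scanSnpIndex(filt$kept, param@scan)
    })
    .stage("scan", {
        if (!is.null(scan$track))
            utils::write.table(scan$track, out("track.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        utils::write.table(scan$regions, out("regions.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    })

    tables <- .stage("segtest", withr::with_seed(param@sim@seed + 1L,
        simulatePhenotypeTables(sim$truth, param@nF2)))
    .stage("segtest", {
        utils::write.table(tables$phenotypes, out("phenotypes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(tables$genotypes, out("genotypes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    })
    obs <- c(sum(tables$phenotypes$phenotype == "wild_type"),
             sum(tables$phenotypes$phenotype == "mutant"))
    seg <- .stage("segtest", chiSquareGof(obs, c(3, 1), yates = param@yates))

    causal <- sim$truth@sites[mcols(sim$truth@sites)$isCausal]
    coseg <- .stage("coseg", checkRecessiveCosegregation(
        tables$genotypes, tables$phenotypes, mcols(causal)$alt))

    ann <- .stage("annotate", withr::with_seed(param@sim@seed + 2L, {
        toy <- simulateCausalGene()
        writeGeneModelsGff3(list(toy$gene), out("toy_gene.gff3"))
        Biostrings::writeXStringSet(toy$genome, out("toy_genome.fa"))
        ve <- classifyEffect(toy$gene, toy$genome, toy$donorPos[1L], "G", "A")
        c(list(gene_id = geneId(toy$gene)), unclass(ve))
    }))

    report <- list(
        tool = "MutMapBSA", version = as.character(utils::packageVersion("MutMapBSA")),
        seed = param@sim@seed,
        counts = list(simulated_sites = length(sim$truth@sites),
                      filtered_sites = nrow(filt$kept),
                      regions = nrow(scan$regions)),
        filter_report = filt$report,
        regions = scan$regions,
        segregation = list(observed = obs, chi2 = round(seg$chi2, 3),
                           p_value = seg$p_value, yates = seg$yates),
        cosegregation = unclass(coseg),
        annotation = ann)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    invisible(report)
}
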