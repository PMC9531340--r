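#' Simulate EMS mutation sites over a synthetic genome
#'
#' Places `Poisson(emsRate x genome size)` sites uniformly along each
#' chromosome and assigns each the EMS transition spectrum: a reference G
#' mutated to A or a reference C mutated to T, drawn with equal probability
#' (under the simulator's uniform base composition, G and C positions are
#' exchangeable, so reference bases are drawn rather than read off a
#' materialised random genome).  The causal site is always included, as a
#' G>A transition at the configured position.  Recombination fractions to
#' the causal site come from the Haldane map at `cmPerMb`; sites on other
#' chromosomes get r = 0.5.
#'
#' Uses the current RNG state; seed via `set.seed()` or use
#' [simulateBulkSegregant()].
#'
#' @param param a [SimParam-class].
#' @return A [SimTruth-class].
#' @export
simulateEmsSites <- function(param = SimParam()) {
    stopifnot(is(param, "SimParam"))
    chroms <- paste0("chr", seq_len(param@nChrom))
    pieces <- lapply(chroms, function(ch) {
        n <- stats::rpois(1L, param@emsRate * param@chromLength)
        pos <- sort(sample.int(param@chromLength, min(n, param@chromLength)))
        data.frame(chrom = rep(ch, length(pos)), pos = pos,
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    df <- df[!(df$chrom == param@causalChrom & df$pos == param@causalPos), ,
             drop = FALSE]
    ref <- sample(c("G", "C"), nrow(df), replace = TRUE)
    df$ref <- ref
    df$alt <- ifelse(ref == "G", "A", "T")
    df <- rbind(df, data.frame(chrom = param@causalChrom,
                               pos = as.integer(param@causalPos),
                               ref = "G", alt = "A"))
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    dMorgan <- abs(df$pos - param@causalPos) / 1e6 * param@cmPerMb / 100
    r <- ifelse(df$chrom == param@causalChrom, haldaneR(dMorgan), 0.5)
    sites <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
    mcols(sites)$ref <- df$ref
    mcols(sites)$alt <- df$alt
    mcols(sites)$rToCausal <- r
    mcols(sites)$isCausal <- df$chrom == param@causalChrom &
        df$pos == param@causalPos
    new("SimTruth", sites = sites, param = param)
}

## one F1 gamete: logical mutant-haplotype carriage at `pos` (one chromosome),
## crossovers Poisson along a Haldane map with no interference
.gamete <- function(pos, chromLength, cmPerMb) {
    lenMorgan <- chromLength / 1e6 * cmPerMb / 100
    nco <- stats::rpois(1L, lenMorgan)
    xo <- sort(stats::runif(nco, 0, chromLength))
    k <- findInterval(pos, xo)
    startMut <- stats::rbinom(1L, 1L, 0.5)
    (startMut + k) %% 2L == 1L
}

#' Simulate a recessive F2 bulk and its per-site allele frequencies
#'
#' Each bulk plant is formed from two independent F1 gametes; gametes
#' recombine by a Poisson crossover process (Haldane, no interference).
#' Plants are accepted only if homozygous for the mutant allele at the causal
#' site — the phenotypic selection that builds the recessive pool — until
#' `bulkSize` plants are collected.  The per-site frequency is the fraction
#' of the `2 x bulkSize` pooled chromosomes carrying the mutant allele; it is
#' exactly 1 at the causal site and has expectation `1 - r` elsewhere.
#'
#' @param truth a [SimTruth-class].
#' @param bulkSize number of plants pooled (defaults to the parameter in
#'   `truth`).
#' @return Numeric vector of mutant-allele frequencies, aligned with
#'   `truth@sites`.
#' @export
simulateF2Bulk <- function(truth, bulkSize = truth@param@bulkSize) {
    stopifnot(is(truth, "SimTruth"))
    param <- truth@param
    sites <- truth@sites
    chrom <- as.character(seqnames(sites))
    pos <- start(sites)
    causal <- which(mcols(sites)$isCausal)
    byChrom <- split(seq_along(pos), chrom)
    mutCount <- integer(length(pos))
    accepted <- 0L; tries <- 0L
    while (accepted < bulkSize) {
        tries <- tries + 1L
        if (tries > 10000L * bulkSize)
            stop("recessive-plant rejection sampling did not converge")
        plant <- logical(0)
        carriage <- integer(length(pos))
        ok <- TRUE
        g1 <- integer(length(pos)); g2 <- integer(length(pos))
        for (idx in byChrom) {
            g1[idx] <- .gamete(pos[idx], param@chromLength, param@cmPerMb)
            g2[idx] <- .gamete(pos[idx], param@chromLength, param@cmPerMb)
        }
        if (g1[causal] == 1L && g2[causal] == 1L) {
            mutCount <- mutCount + g1 + g2
            accepted <- accepted + 1L
        }
    }
    mutCount / (2 * bulkSize)
}

## vectorised diploid genotype call from ref/alt read counts: majority call,
## het when the minor allele holds >= 20% of reads (simulator convention)
.callGenotype <- function(refC, altC) {
    total <- refC + altC
    minor <- ifelse(total == 0L, 0, pmin(refC, altC) / pmax(total, 1L))
    ifelse(total == 0L, "missing",
    ifelse(minor >= 0.2, "het",
    ifelse(altC > refC, "hom_alt", "hom_ref")))
}

#' Sample pooled read depths into a VariantSet
#'
#' Emulates short-read resequencing of the two parents and the bulk at desk
#' scale: per site the bulk depth is Poisson(`meanDepth`) and the
#' mutant-allele read count Binomial with success probability
#' `f(1 - e) + (1 - f)e` (true frequency `f`, per-base error `e`); parents
#' are homozygous at their true alleles with Poisson(`parentDepth`) depths
#' and error-rate cross-contamination.  Genotypes are called by majority
#' with a heterozygous call when the minor allele reaches 20% of reads, and
#' genotype quality is synthesised as `min(99, 4 x depth)` so that clean
#' sites are high-quality — both simulator conventions, not claims about any
#' particular caller.
#'
#' @param truth a [SimTruth-class].
#' @param freq per-site bulk mutant-allele frequencies from
#'   [simulateF2Bulk()].
#' @param param a [SimParam-class].
#' @return A [VariantSet-class] (the mutant allele is the alt allele by
#'   construction: the wild-type parent carries the reference).
#' @export
sampleReadDepths <- function(truth, freq, param = truth@param) {
    sites <- truth@sites
    n <- length(sites)
    stopifnot(length(freq) == n, all(freq >= 0 & freq <= 1))
    e <- param@seqError
    bulkD <- stats::rpois(n, param@meanDepth)
    bulkAlt <- stats::rbinom(n, bulkD, freq * (1 - e) + (1 - freq) * e)
    bulkRef <- bulkD - bulkAlt
    wtD <- stats::rpois(n, param@parentDepth)
    wtAlt <- stats::rbinom(n, wtD, e)
    wtRef <- wtD - wtAlt
    mutD <- stats::rpois(n, param@parentDepth)
    mutRef <- stats::rbinom(n, mutD, e)
    mutAlt <- mutD - mutRef
    gt <- cbind(wt_parent = .callGenotype(wtRef, wtAlt),
                mut_parent = .callGenotype(mutRef, mutAlt),
                bulk = .callGenotype(bulkRef, bulkAlt))
    gq <- cbind(wt_parent = pmin(99L, 4L * wtD),
                mut_parent = pmin(99L, 4L * mutD),
                bulk = pmin(99L, 4L * bulkD))
    VariantSet(as.character(seqnames(sites)), start(sites),
               mcols(sites)$ref, mcols(sites)$alt, gt,
               cbind(wt_parent = wtRef, mut_parent = mutRef, bulk = bulkRef),
               cbind(wt_parent = wtAlt, mut_parent = mutAlt, bulk = bulkAlt),
               gq)
}

#' Simulate per-plant phenotype and KASP genotype tables
#'
#' Draws F2 plants with single-locus genotypes at the causal site (allele
#' counts Binomial(2, 1/2), i.e. the 1:2:1 Mendelian classes) and the
#' recessive phenotype rule: mutant phenotype iff homozygous for the mutant
#' allele, giving the expected 3:1 phenotype ratio.  Genotypes are written
#' with the causal site's actual allele letters (`ref:ref`, `ref:alt`,
#' `alt:alt`), ready for [checkRecessiveCosegregation()].
#'
#' @param truth a [SimTruth-class].
#' @param nF2 number of F2 plants to draw (default 93, a typical KASP panel).
#' @return `list(phenotypes, genotypes)` of `data.frame`s keyed by
#'   `plant_id`.
#' @export
simulatePhenotypeTables <- function(truth, nF2 = 93) {
    causal <- truth@sites[mcols(truth@sites)$isCausal]
    refA <- mcols(causal)$ref; altA <- mcols(causal)$alt
    nMutAlleles <- stats::rbinom(nF2, 2L, 0.5)
    ids <- sprintf("F2_%04d", seq_len(nF2))
    genoStr <- c(paste0(refA, ":", refA), paste0(refA, ":", altA),
                 paste0(altA, ":", altA))[nMutAlleles + 1L]
    list(phenotypes = data.frame(
             plant_id = ids,
             phenotype = ifelse(nMutAlleles == 2L, "mutant", "wild_type"),
             stringsAsFactors = FALSE),
         genotypes = data.frame(plant_id = ids, genotype = genoStr,
                                stringsAsFactors = FALSE))
}

#' Run the full simulator under a fixed seed
#'
#' Seeds the RNG from `param@seed` (restoring the caller's RNG state
#' afterwards) and runs [simulateEmsSites()], [simulateF2Bulk()] and
#' [sampleReadDepths()]; identical parameters give byte-identical outputs.
#'
#' @param param a [SimParam-class].
#' @return `list(truth, freq, variants)`.
#' @export
simulateBulkSegregant <- function(param = SimParam()) {
    withr::with_seed(param@seed, {
        truth <- simulateEmsSites(param)
        freq <- simulateF2Bulk(truth)
        variants <- sampleReadDepths(truth, freq, param)
        list(truth = truth, freq = freq, variants = variants)
    })
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

## n random sense codons (uniform over the 61 non-stop codons)
.senseCodons <- function(n) {
    all <- as.character(Biostrings::DNAStringSet(
        names(Biostrings::GENETIC_CODE)))
    sense <- setdiff(all, .STOP_CODONS)
    sample(sense, n, replace = TRUE)
}

#' Construct a toy intron-bearing causal gene with its contig
#'
#' Builds a small plus-strand gene whose CDS spans all exons: an ATG, random
#' sense codons, and a single terminal stop, interrupted by GT..AG introns.
#' With `earlyStop = TRUE` each intron carries stop codons in all three
#' reading frames right after the donor, so any retention truncates the
#' protein — the configuration produced by a splice-junction mutation.  The
#' gene sits on a synthetic random contig with flanking padding.
#'
#' Uses the current RNG state; seed via `set.seed()`.
#'
#' @param exonLengths exon lengths in nt (sum must be divisible by 3).
#' @param intronLengths intron lengths in nt (`length(exonLengths) - 1` of
#'   them, each >= 20).
#' @param pad flanking contig padding in nt.
#' @param chrom contig name.
#' @param earlyStop embed all-frame stop codons at the start of each intron.
#' @return A list: `gene` ([GeneModel-class]), `genome`
#'   ([Biostrings::DNAStringSet]), `donorPos` (genomic position of each
#'   intron's donor G, transcription order).
#' @export
simulateCausalGene <- function(exonLengths = c(120, 99, 81),
                               intronLengths = c(98, 60), pad = 50,
                               chrom = "toy", earlyStop = TRUE) {
    stopifnot(sum(exonLengths) %% 3 == 0,
              length(intronLengths) == length(exonLengths) - 1L,
              all(intronLengths >= 20))
    nCodon <- sum(exonLengths) / 3
    cds <- paste0("ATG", paste(.senseCodons(nCodon - 2L), collapse = ""), "TAA")
    exonSeqs <- character(length(exonLengths))
    at <- 1L
    for (i in seq_along(exonLengths)) {
        exonSeqs[i] <- substr(cds, at, at + exonLengths[i] - 1L)
        at <- at + exonLengths[i]
    }
    intronSeqs <- vapply(intronLengths, function(L) {
        stops <- if (earlyStop) "TAAATAAATAA" else ""
        nFill <- L - 4L - nchar(stops)
        fill <- paste(sample(c("A", "C", "G", "T"), nFill, replace = TRUE),
                      collapse = "")
        paste0("GT", stops, fill, "AG")
    }, character(1))
    randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
    body <- exonSeqs[1L]
    for (i in seq_along(intronSeqs))
        body <- paste0(body, intronSeqs[i], exonSeqs[i + 1L])
    contig <- paste0(randSeq(pad), body, randSeq(pad))
    exonStarts <- integer(length(exonLengths)); exonEnds <- integer(length(exonLengths))
    atG <- pad + 1L
    for (i in seq_along(exonLengths)) {
        exonStarts[i] <- atG
        exonEnds[i] <- atG + exonLengths[i] - 1L
        atG <- exonEnds[i] + 1L
        if (i <= length(intronLengths)) atG <- atG + intronLengths[i]
    }
    gene <- GeneModel("toy_causal_gene", chrom, "+", exonStarts, exonEnds,
                      exonStarts[1L], exonEnds[length(exonEnds)])
    genome <- Biostrings::DNAStringSet(contig)
    names(genome) <- chrom
    list(gene = gene, genome = genome,
         donorPos = start(intronRanges(gene)))
}
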