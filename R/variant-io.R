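#' Read a three-role MutMap VCF into a VariantSet
#'
#' Reads a VCF v4.x file via [VariantAnnotation::readVcf] and maps the three
#' sequenced entities of the design (wild-type parent, mutant parent,
#' recessive bulk) onto the fixed roles of a [VariantSet-class].  Only
#' biallelic SNP records are representable: multiallelic sites are dropped
#' with a message reporting how many (the analysis compares SNP typings
#' between two inbred parents, which implies biallelic treatment), while an
#' indel ALT is an error.  A missing GQ FORMAT field defaults to 99 — absence
#' of a quality annotation should not silently delete data.
#'
#' How uncalled genotypes in the pools were handled upstream is rarely
#' documented, so the choice is explicit here: `missingGenotypes = "keep"`
#' (default) retains such sites as `"missing"` calls for the genotype rules
#' to judge, while `"drop"` removes any site with an uncalled sample at read
#' time (with a message).
#'
#' @param path VCF file.
#' @param roles named character vector mapping each role to the sample name in
#'   the VCF header, e.g. `c(wt_parent = "FT", mut_parent = "lhd1",
#'   bulk = "Dpool")`.
#' @param missingGenotypes `"keep"` or `"drop"` (see above).
#' @return A [VariantSet-class].
#' @export
readVariantVcf <- function(path,
                           roles = c(wt_parent = "wt_parent",
                                     mut_parent = "mut_parent",
                                     bulk = "bulk"),
                           missingGenotypes = c("keep", "drop")) {
    missingGenotypes <- match.arg(missingGenotypes)
    stopifnot(identical(sort(names(roles)), sort(.ROLES)))
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    have <- colnames(vcf)
    missing <- setdiff(unname(roles), have)
    if (length(missing))
        stop("sample(s) not in VCF header: ", paste(missing, collapse = ", "))
    vcf <- vcf[, unname(roles[.ROLES])]

    alt <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(alt)
    if (any(nAlt != 1L)) {
        message(sum(nAlt != 1L), " multiallelic site(s) dropped")
        vcf <- vcf[nAlt == 1L]
        alt <- VariantAnnotation::alt(vcf)
    }
    if (nrow(vcf) == 0L)
        return(VariantSet(character(), integer(), character(), character(),
                          matrix(character(), 0, 3), matrix(integer(), 0, 3),
                          matrix(integer(), 0, 3), matrix(integer(), 0, 3)))
    refc <- as.character(VariantAnnotation::ref(vcf))
    altc <- as.character(unlist(alt))
    if (any(nchar(refc) != 1L | nchar(altc) != 1L))
        stop("non-SNP record(s) present; only single-nucleotide variants ",
             "are supported")

    g <- VariantAnnotation::geno(vcf)
    if (!"GT" %in% names(g)) stop("VCF FORMAT must contain GT")
    if (!"AD" %in% names(g)) stop("VCF FORMAT must contain AD")
    gt <- .decodeGt(g$GT)
    adr <- matrix(0L, nrow(vcf), 3L); ada <- matrix(0L, nrow(vcf), 3L)
    for (j in seq_len(3L)) {
        adj <- g$AD[, j]
        bad <- S4Vectors::elementNROWS(adj) != 2L
        if (any(bad)) stop("malformed AD field (expected 2 values per sample)")
        m <- matrix(unlist(adj), ncol = 2L, byrow = TRUE)
        m[is.na(m)] <- 0L
        adr[, j] <- m[, 1L]; ada[, j] <- m[, 2L]
    }
    gq <- if ("GQ" %in% names(g)) {
        m <- g$GQ; m[is.na(m)] <- 99L; storage.mode(m) <- "integer"; m
    } else matrix(99L, nrow(vcf), 3L)

    rr <- SummarizedExperiment::rowRanges(vcf)
    out <- VariantSet(as.character(GenomicRanges::seqnames(rr)),
                      GenomicRanges::start(rr), refc, altc, gt, adr, ada, gq)
    if (missingGenotypes == "drop") {
        anyMissing <- rowSums(genotypeCalls(out) == "missing") > 0L
        if (any(anyMissing))
            message(sum(anyMissing),
                    " site(s) with uncalled genotype(s) dropped")
        out <- out[!anyMissing, ]
    }
    out
}

.decodeGt <- function(gtm) {
    dec <- function(s) {
        s <- gsub("|", "/", s, fixed = TRUE)
        ifelse(s %in% c("0/0"), "hom_ref",
        ifelse(s %in% c("0/1", "1/0"), "het",
        ifelse(s %in% c("1/1"), "hom_alt", "missing")))
    }
    matrix(dec(gtm), nrow = nrow(gtm), ncol = ncol(gtm))
}

#' Write a VariantSet as a VCF v4.2 file
#'
#' Emits a deterministic VCF v4.2 with FORMAT `GT:AD:DP:GQ` and sample columns
#' in role order (wild-type parent, mutant parent, bulk).  Output re-read by
#' [readVariantVcf()] reproduces the object exactly; missing genotypes are
#' emitted as `./.`.
#'
#' @param x a [VariantSet-class].
#' @param path output file.
#' @param sampleNames sample column names, in role order.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(x, path,
                            sampleNames = c("wt_parent", "mut_parent", "bulk")) {
    stopifnot(is(x, "VariantSet"), length(sampleNames) == 3L)
    rr <- rowRanges(x)
    chroms <- unique(as.character(seqnames(rr)))
    hdr <- c("##fileformat=VCFv4.2",
        "##source=MutMapBSA",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
        sprintf("##contig=<ID=%s>", chroms),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", sampleNames), collapse = "\t"))
    gtCode <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
    gt <- genotypeCalls(x); adr <- assay(x, "refDepth")
    ada <- assay(x, "altDepth"); gq <- gqValues(x)
    body <- character(nrow(x))
    if (nrow(x) > 0L) {
        cols <- vapply(seq_len(3L), function(j)
            sprintf("%s:%d,%d:%d:%d", gtCode[gt[, j]], adr[, j], ada[, j],
                    adr[, j] + ada[, j], gq[, j]), character(nrow(x)))
        cols <- matrix(cols, nrow = nrow(x))
        body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:AD:DP:GQ\t%s\t%s\t%s",
                        as.character(seqnames(rr)), start(rr),
                        mcols(rr)$ref, mcols(rr)$alt,
                        cols[, 1L], cols[, 2L], cols[, 3L])
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read gene models from GFF3 plus genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features (via [rtracklayer::import]) into
#' [GeneModel-class] objects and loads the genome (via
#' [Biostrings::readDNAStringSet]).  GFF3 phase fields are ignored; the
#' reading frame is derived from the CDS start.  Each model's invariants are
#' enforced on construction (spliced CDS a positive multiple of 3, CDS inside
#' exons); an exon outside its contig is an error.
#'
#' @param gff3Path GFF3 file with gene models.
#' @param fastaPath genome FASTA covering all models.
#' @return A list with elements `models` (named list of [GeneModel-class]) and
#'   `genome` ([Biostrings::DNAStringSet]).
#' @export
readGeneModels <- function(gff3Path, fastaPath) {
    gr <- rtracklayer::import(gff3Path, format = "gff3")
    genome <- Biostrings::readDNAStringSet(fastaPath)
    names(genome) <- sub("\\s.*", "", names(genome))
    genes <- gr[gr$type == "gene"]
    models <- lapply(seq_along(genes), function(i) {
        gid <- genes$ID[i]
        mrna <- gr[gr$type == "mRNA" & vapply(gr$Parent, function(p)
            gid %in% p, logical(1))]
        parentIds <- if (length(mrna)) mrna$ID else gid
        kids <- gr[vapply(gr$Parent, function(p)
            any(parentIds %in% p), logical(1))]
        ex <- sort(kids[kids$type == "exon"])
        cds <- kids[kids$type == "CDS"]
        if (length(ex) == 0L) ex <- sort(cds)
        if (length(cds) == 0L)
            stop("gene ", gid, " has no CDS features")
        chrom <- as.character(seqnames(genes))[i]
        if (!chrom %in% names(genome))
            stop("contig ", chrom, " missing from FASTA")
        if (max(end(ex)) > length(genome[[chrom]]))
            stop("gene ", gid, " has exon(s) outside contig ", chrom)
        GeneModel(gid, chrom, as.character(GenomicRanges::strand(genes))[i],
                  start(ex), end(ex), min(start(cds)), max(end(cds)))
    })
    names(models) <- genes$ID
    list(models = models, genome = genome)
}

#' Write gene models as GFF3
#'
#' @param models list of [GeneModel-class].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(models, path) {
    grl <- lapply(models, function(gm) {
        ex <- gm@exons
        cs <- pmax(start(ex), gm@cdsStart); ce <- pmin(end(ex), gm@cdsEnd)
        keep <- cs <= ce
        gid <- gm@geneId; mid <- paste0(gid, ".1")
        GRanges(gm@chrom,
            IRanges(c(min(start(ex)), min(start(ex)), start(ex), cs[keep]),
                    c(max(end(ex)), max(end(ex)), end(ex), ce[keep])),
            strand = gm@strand,
            type = c("gene", "mRNA", rep("exon", length(ex)),
                     rep("CDS", sum(keep))),
            ID = c(gid, mid, rep(NA_character_, length(ex) + sum(keep))),
            Parent = c(NA_character_, gid,
                       rep(mid, length(ex) + sum(keep))))
    })
    gr <- do.call(c, unname(grl))
    gr$source <- "MutMapBSA"
    ## phase is derived from the CDS start on reading, not stored
    suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
    invisible(path)
}

#' Extract the spliced CDS of a gene model
#'
#' Concatenates the exonic sequence between the CDS boundaries in genomic
#' order and reverse-complements for minus-strand genes, so the result always
#' starts at the initiator codon.
#'
#' @param gene a [GeneModel-class].
#' @param genome a [Biostrings::DNAStringSet] containing the gene's contig.
#' @return A [Biostrings::DNAString] of the coding sequence.
#' @export
splicedCds <- function(gene, genome) {
    .extractSpliced(gene, genome, gene@cdsStart, gene@cdsEnd)
}

## concatenate exonic sequence restricted to [from, to]; strand-aware
.extractSpliced <- function(gene, genome, from, to, extraRanges = NULL) {
    contig <- genome[[gene@chrom]]
    ex <- gene@exons
    s <- pmax(start(ex), from); e <- pmin(end(ex), to)
    keep <- s <= e
    pieces <- IRanges(s[keep], e[keep])
    if (!is.null(extraRanges)) pieces <- sort(c(pieces, extraRanges))
    seqs <- Biostrings::extractAt(contig, pieces)
    out <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
    if (gene@strand == "-") Biostrings::reverseComplement(out) else out
}

#' Read phenotype / genotype tables
#'
#' Plain TSV readers for the per-plant tables used by the segregation and
#' co-segregation analyses.  The phenotype table needs columns `plant_id` and
#' `phenotype` (`wild_type` or `mutant`); the genotype table needs `plant_id`
#' and `genotype` written as `allele:allele` (e.g. `C:T`), allele letters free.
#'
#' @param path TSV file.
#' @return A `data.frame`.
#' @export
readPhenotypeTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("plant_id", "phenotype") %in% names(df)))
    if (!all(df$phenotype %in% c("wild_type", "mutant")))
        stop("phenotype must be 'wild_type' or 'mutant'")
    df
}

#' @rdname readPhenotypeTable
#' @export
readGenotypeTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("plant_id", "genotype") %in% names(df)))
    if (!all(grepl("^[A-Za-z]:[A-Za-z]$", df$genotype)))
        stop("genotype must be written as 'allele:allele'")
    df
}
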