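#' Locate a SNP within a gene model
#'
#' Assigns a position to an exon, an intron interior, or a splice window —
#' the first two or last two nucleotides of an intron, which hold the
#' near-invariant GT donor and AG acceptor dinucleotides.  Ordinals follow
#' transcription order, so for a minus-strand gene the donor window of
#' intron 1 sits at the genomically rightmost intron's right edge.
#'
#' @param gene a [GeneModel-class].
#' @param pos 1-based genomic position (on the gene's chromosome).
#' @return A list with `feature` (`"exon"`, `"intron"`, `"splice_donor"`,
#'   `"splice_acceptor"` or `"intergenic"`) and `ordinal` (transcription
#'   order; `NA` for intergenic).
#' @export
locateSnp <- function(gene, pos) {
    pos <- as.integer(pos)
    ex <- gene@exons
    hitEx <- which(pos >= start(ex) & pos <= end(ex))
    if (length(hitEx))
        return(list(feature = "exon", ordinal = .exonOrdinal(gene, hitEx)))
    intr <- intronRanges(gene)
    hitIn <- which(pos >= start(intr) & pos <= end(intr))
    if (!length(hitIn))
        return(list(feature = "intergenic", ordinal = NA_integer_))
    s <- start(intr)[hitIn]; e <- end(intr)[hitIn]
    leftWindow <- pos <= s + 1L; rightWindow <- pos >= e - 1L
    ord <- .intronOrdinal(gene, hitIn)
    feature <- if (!leftWindow && !rightWindow) "intron"
        else if (gene@strand == "+") {
            if (leftWindow) "splice_donor" else "splice_acceptor"
        } else {
            if (rightWindow) "splice_donor" else "splice_acceptor"
        }
    list(feature = feature, ordinal = ord)
}

#' Assemble a mature transcript, optionally retaining introns
#'
#' Concatenates the exon sequences in transcription order; introns listed in
#' `retainedIntrons` (transcription-order ordinals) are left in place, as
#' happens when a splice-junction mutation abolishes splicing of that
#' intron.  Minus-strand genes are reverse-complemented.
#'
#' @param gene a [GeneModel-class].
#' @param retainedIntrons integer ordinals of retained introns (may be empty).
#' @param genome a [Biostrings::DNAStringSet] with the gene's contig.
#' @return A [Biostrings::DNAString] of the mature transcript.
#' @export
spliceTranscript <- function(gene, retainedIntrons = integer(), genome) {
    intr <- intronRanges(gene)
    extra <- NULL
    if (length(retainedIntrons)) {
        gidx <- vapply(as.integer(retainedIntrons), function(o)
            .intronGenomicIndex(gene, o), integer(1))
        extra <- intr[gidx]
    }
    .extractSpliced(gene, genome, min(start(gene@exons)),
                    max(end(gene@exons)), extraRanges = extra)
}

#' Translate a coding sequence up to the first stop codon
#'
#' Standard genetic code, reading frame fixed at the first base.  The
#' returned residue count excludes the stop codon.  A sequence not starting
#' with ATG is flagged `start_lost`; a sequence whose frame runs off the end
#' without a stop is flagged `non_stop` (its trailing partial codon is
#' dropped).
#'
#' @param cds a [Biostrings::DNAString] or character coding sequence.
#' @return A list: `protein` (character residues), `n_residues`, `non_stop`,
#'   `start_lost`.
#' @examples
#' translateCds("ATGAAATAA")$protein  # "MK"
#' @export
translateCds <- function(cds) {
    dna <- Biostrings::DNAString(as.character(cds))
    startLost <- length(dna) < 3L ||
        as.character(Biostrings::subseq(dna, 1L, 3L)) != "ATG"
    nCodon <- length(dna) %/% 3L
    if (nCodon == 0L)
        return(list(protein = "", n_residues = 0L, non_stop = TRUE,
                    start_lost = startLost))
    aa <- as.character(Biostrings::translate(
        Biostrings::subseq(dna, 1L, nCodon * 3L)))
    stopAt <- regexpr("*", aa, fixed = TRUE)
    if (stopAt < 0L)
        list(protein = aa, n_residues = nchar(aa), non_stop = TRUE,
             start_lost = startLost)
    else
        list(protein = substr(aa, 1L, stopAt - 1L),
             n_residues = as.integer(stopAt - 1L), non_stop = FALSE,
             start_lost = startLost)
}

#' Classify the consequence of a point mutation on a gene model
#'
#' Reproduces the reasoning that links a splice-junction transition to a
#' truncated protein: a SNP in a splice window (2 nt at either intron end)
#' abolishes splicing of that intron only, the retained intron is left in the
#' transcript, and translation is re-run through the retained sequence — a
#' retained length not divisible by 3 shifts the downstream frame
#' (`frameshift`), typically exposing a premature stop.  An exonic SNP inside
#' the CDS substitutes one base and re-translates, yielding `stop_gained`,
#' `missense`, `synonymous`, `start_lost` or (if the terminal stop is
#' destroyed) `stop_lost`.  Intron-interior SNPs are `intronic`, exonic SNPs
#' outside the CDS `noncoding_exonic`, and positions outside the gene
#' `intergenic`.
#'
#' @param gene a [GeneModel-class].
#' @param genome a [Biostrings::DNAStringSet] with the gene's contig.
#' @param pos 1-based genomic position of the SNP.
#' @param ref,alt reference and alternate alleles on the plus strand (as in a
#'   VCF); `ref` must match the genome.
#' @return A list of class `VariantEffect`: `effect_class`, `feature` (e.g.
#'   `"intron 2"`), `wt_protein_length`, `mut_protein_length` (residues, stop
#'   excluded), `wt_transcript_length`, `mut_transcript_length` (nt),
#'   `frameshift`, `non_stop`.
#' @export
classifyEffect <- function(gene, genome, pos, ref, alt) {
    pos <- as.integer(pos)
    contig <- genome[[gene@chrom]]
    if (as.character(Biostrings::subseq(contig, pos, pos)) != ref)
        stop("ref allele does not match the genome at ", gene@chrom, ":", pos)
    if (ref == alt) stop("ref and alt alleles must differ")

    wtCds <- splicedCds(gene, genome)
    wtTr <- translateCds(wtCds)
    wtTranscriptLen <- sum(width(gene@exons))
    loc <- locateSnp(gene, pos)

    eff <- function(class, feature, mutLen = wtTr$n_residues,
                    mutTrLen = wtTranscriptLen, frameshift = FALSE,
                    nonStop = FALSE) {
        structure(list(effect_class = class, feature = feature,
                       wt_protein_length = wtTr$n_residues,
                       mut_protein_length = as.integer(mutLen),
                       wt_transcript_length = as.integer(wtTranscriptLen),
                       mut_transcript_length = as.integer(mutTrLen),
                       frameshift = frameshift, non_stop = nonStop),
                  class = "VariantEffect")
    }

    if (loc$feature == "intergenic")
        return(eff("intergenic", "intergenic"))
    if (loc$feature == "intron")
        return(eff("intronic", paste("intron", loc$ordinal)))

    ## mutated contig for re-translation
    mutGenome <- genome
    mutContig <- Biostrings::replaceLetterAt(contig, pos, alt)
    mutGenome[[gene@chrom]] <- mutContig

    if (loc$feature %in% c("splice_donor", "splice_acceptor")) {
        gidx <- .intronGenomicIndex(gene, loc$ordinal)
        intron <- intronRanges(gene)[gidx]
        intronLen <- width(intron)
        ## coding sequence from the start codon through the end of the
        ## transcript with the intron retained (a frameshift reads through
        ## the original stop, so translation must see the full 3' sequence)
        from <- if (gene@strand == "+") gene@cdsStart else min(start(gene@exons))
        to <- if (gene@strand == "+") max(end(gene@exons)) else gene@cdsEnd
        mutCds <- .extractSpliced(gene, mutGenome, from, to,
                                  extraRanges = intron)
        mutTr <- translateCds(mutCds)
        return(eff("splice_disruption_intron_retention",
                   paste("intron", loc$ordinal),
                   mutLen = mutTr$n_residues,
                   mutTrLen = wtTranscriptLen + intronLen,
                   frameshift = intronLen %% 3L != 0L,
                   nonStop = mutTr$non_stop))
    }

    ## exonic
    feature <- paste("exon", loc$ordinal)
    if (pos < gene@cdsStart || pos > gene@cdsEnd)
        return(eff("noncoding_exonic", feature))
    mutTr <- translateCds(splicedCds(gene, mutGenome))
    if (mutTr$start_lost)
        return(eff("start_lost", feature, mutLen = 0L))
    cls <- if (identical(mutTr$protein, wtTr$protein)) "synonymous"
        else if (mutTr$n_residues < wtTr$n_residues) "stop_gained"
        else if (mutTr$n_residues > wtTr$n_residues || mutTr$non_stop) "stop_lost"
        else "missense"
    eff(cls, feature, mutLen = mutTr$n_residues, nonStop = mutTr$non_stop)
}

#' @export
print.VariantEffect <- function(x, ...) {
    cat(sprintf(
        "%s (%s): protein %d -> %d aa, transcript %d -> %d nt%s%s\n",
        x$effect_class, x$feature, x$wt_protein_length, x$mut_protein_length,
        x$wt_transcript_length, x$mut_transcript_length,
        if (x$frameshift) ", frameshift" else "",
        if (x$non_stop) ", non-stop" else ""))
    invisible(x)
}

#' Annotate the SNPs of a VariantSet against gene models
#'
#' Classifies each SNP against the gene model that contains it (first match
#' by genomic span); SNPs outside every model are reported as intergenic.
#'
#' @param x a [VariantSet-class].
#' @param models list of [GeneModel-class].
#' @param genome a [Biostrings::DNAStringSet].
#' @return A `data.frame` with one row per SNP: `chrom`, `pos`, `gene_id`,
#'   `effect_class`, `feature`, `wt_protein_length`, `mut_protein_length`,
#'   `frameshift`.
#' @export
annotateVariants <- function(x, models, genome) {
    rr <- rowRanges(x)
    rows <- lapply(seq_len(nrow(x)), function(i) {
        chrom <- as.character(seqnames(rr))[i]; pos <- start(rr)[i]
        gm <- NULL
        for (m in models)
            if (m@chrom == chrom && pos >= min(start(m@exons)) &&
                pos <= max(end(m@exons))) { gm <- m; break }
        if (is.null(gm))
            return(data.frame(chrom = chrom, pos = pos, gene_id = NA_character_,
                              effect_class = "intergenic", feature = "intergenic",
                              wt_protein_length = NA_integer_,
                              mut_protein_length = NA_integer_,
                              frameshift = FALSE, stringsAsFactors = FALSE))
        ve <- classifyEffect(gm, genome, pos, mcols(rr)$ref[i], mcols(rr)$alt[i])
        data.frame(chrom = chrom, pos = pos, gene_id = geneId(gm),
                   effect_class = ve$effect_class, feature = ve$feature,
                   wt_protein_length = ve$wt_protein_length,
                   mut_protein_length = ve$mut_protein_length,
                   frameshift = ve$frameshift, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
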