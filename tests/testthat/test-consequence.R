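# toy plus-strand gene: exons (1,102) and (151,300), intron 103-150
toyGene <- function(strand = "+")
    GeneModel("g", "c", strand, c(1, 151), c(102, 300), 1, 300)

test_that("SNP location distinguishes exons, intron interiors and splice windows", {
    gm <- toyGene("+")
    expect_equal(locateSnp(gm, 50), list(feature = "exon", ordinal = 1L))
    expect_equal(locateSnp(gm, 103),
                 list(feature = "splice_donor", ordinal = 1L))
    expect_equal(locateSnp(gm, 104),
                 list(feature = "splice_donor", ordinal = 1L))
    expect_equal(locateSnp(gm, 125), list(feature = "intron", ordinal = 1L))
    expect_equal(locateSnp(gm, 149),
                 list(feature = "splice_acceptor", ordinal = 1L))
    expect_equal(locateSnp(gm, 150),
                 list(feature = "splice_acceptor", ordinal = 1L))
    expect_equal(locateSnp(gm, 400),
                 list(feature = "intergenic", ordinal = NA_integer_))
    # minus strand: ordinals and donor/acceptor flip
    gmM <- toyGene("-")
    expect_equal(locateSnp(gmM, 150),
                 list(feature = "splice_donor", ordinal = 1L))
    expect_equal(locateSnp(gmM, 103),
                 list(feature = "splice_acceptor", ordinal = 1L))
    expect_equal(locateSnp(gmM, 50), list(feature = "exon", ordinal = 2L))
})

test_that("transcript assembly with retained introns has additive length", {
    set.seed(121)
    toy <- simulateCausalGene(exonLengths = c(120, 99, 81),
                              intronLengths = c(98, 60))
    gm <- toy$gene; genome <- toy$genome
    spliced <- spliceTranscript(gm, integer(), genome)
    expect_equal(length(spliced), 300L)  # exon total
    one <- spliceTranscript(gm, 1L, genome)
    expect_equal(length(one), 398L)      # + 98-nt intron
    all2 <- spliceTranscript(gm, c(1L, 2L), genome)
    expect_equal(length(all2), 300L + 98L + 60L)  # genomic span of the gene
    expect_equal(length(all2),
                 max(end(exonRanges(gm))) - min(start(exonRanges(gm))) + 1L)
})

test_that("a 1896-nt ORF translates to 631 residues; retaining 98 nt gives 1994 nt", {
    set.seed(131)
    big <- simulateCausalGene(exonLengths = c(900, 996), intronLengths = 98,
                              earlyStop = FALSE)
    expect_equal(length(spliceTranscript(big$gene, integer(), big$genome)),
                 1896L)
    expect_equal(length(spliceTranscript(big$gene, 1L, big$genome)), 1994L)
    tr <- translateCds(splicedCds(big$gene, big$genome))
    expect_equal(tr$n_residues, 631L)
    expect_false(tr$non_stop)
})

test_that("translation stops at the first in-frame stop codon", {
    expect_equal(translateCds("ATGAAATAA")$protein, "MK")
    expect_equal(translateCds("ATGAAATAA")$n_residues, 2L)
    expect_true(translateCds("ATGAAACCC")$non_stop)
    expect_true(translateCds("TTGAAATAA")$start_lost)
})

test_that("translation agrees with an independent codon-table oracle", {
    skip_if_not_installed("seqinr")
    set.seed(141)
    for (rep in 1:10) {
        orf <- randomOrf(sample(20:200, 1))
        got <- translateCds(orf)
        aa <- seqinr::translate(strsplit(orf, "")[[1]])
        stopAt <- which(aa == "*")[1]
        expProt <- paste(aa[seq_len(stopAt - 1L)], collapse = "")
        expect_equal(got$protein, expProt)
    }
})

test_that("splice-window mutation retains its intron and truncates the protein", {
    set.seed(151)
    toy <- simulateCausalGene(exonLengths = c(120, 99, 81),
                              intronLengths = c(98, 60))
    ve <- classifyEffect(toy$gene, toy$genome, toy$donorPos[1L], "G", "A")
    expect_equal(ve$effect_class, "splice_disruption_intron_retention")
    expect_equal(ve$feature, "intron 1")
    expect_true(ve$frameshift)                      # 98 %% 3 != 0
    expect_equal(ve$wt_protein_length, 99L)         # 300/3 - 1
    expect_lt(ve$mut_protein_length, 99L)
    expect_equal(ve$mut_transcript_length - ve$wt_transcript_length, 98L)
    # the truncated length matches re-translating the retained transcript
    mutCds <- spliceTranscript(toy$gene, 1L, local({
        g <- toy$genome
        g[["toy"]] <- Biostrings::replaceLetterAt(g[["toy"]],
                                                  toy$donorPos[1L], "A")
        g
    }))
    expect_equal(ve$mut_protein_length, translateCds(mutCds)$n_residues)
})

test_that("in-frame stop-free intron retention preserves the reading frame", {
    # hand-built intron: 99 nt, starts GT, ends AG, no stop in the retained
    # frame (exon 1 length divisible by 3 keeps the intron in frame 0)
    set.seed(161)
    sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
    intron <- paste0("GTT",
                     paste(sample(setdiff(sense, "TAA"), 31, TRUE), collapse = ""),
                     "AAG")  # codons GTT, 31 sense, AAG -> 99 nt
    exon1 <- randomOrf(40)                    # 120 nt incl. terminal TAA
    exon1 <- substr(exon1, 1, 117)            # strip the stop: 117 nt, %3 == 0
    exon2 <- paste0(paste(sample(sense, 20, TRUE), collapse = ""), "TAA")
    contig <- paste0(exon1, intron, exon2)
    genome <- Biostrings::DNAStringSet(contig); names(genome) <- "c"
    gm <- GeneModel("g", "c", "+", c(1, 118 + 99), c(117, nchar(contig)),
                    1, nchar(contig))
    ve <- classifyEffect(gm, genome, 118, "G", "A")  # donor G of the intron
    expect_equal(ve$effect_class, "splice_disruption_intron_retention")
    expect_false(ve$frameshift)
    # 33 in-frame residues inserted, downstream frame intact
    expect_equal(ve$mut_protein_length, ve$wt_protein_length + 33L)
    expect_equal(ve$mut_transcript_length - ve$wt_transcript_length, 99L)
})

test_that("exonic substitutions classify as stop_gained/missense/synonymous", {
    # explicit CDS: ATG TGG CTG AAA TAA on a single exon
    contig <- "ATGTGGCTGAAATAA"
    genome <- Biostrings::DNAStringSet(contig); names(genome) <- "c"
    gm <- GeneModel("g", "c", "+", 1, 15, 1, 15)
    # TGG -> TGA: premature stop after 1 residue
    sg <- classifyEffect(gm, genome, 6, "G", "A")
    expect_equal(sg$effect_class, "stop_gained")
    expect_equal(sg$wt_protein_length, 4L)
    expect_equal(sg$mut_protein_length, 1L)
    expect_false(sg$frameshift)
    # CTG -> CTA: both leucine (wobble position)
    syn <- classifyEffect(gm, genome, 9, "G", "A")
    expect_equal(syn$effect_class, "synonymous")
    expect_equal(syn$mut_protein_length, syn$wt_protein_length)
    # TGG -> TCG: tryptophan -> serine
    mis <- classifyEffect(gm, genome, 5, "G", "C")
    expect_equal(mis$effect_class, "missense")
    expect_equal(mis$mut_protein_length, 4L)
    # ATG -> ATA: start lost
    sl <- classifyEffect(gm, genome, 3, "G", "A")
    expect_equal(sl$effect_class, "start_lost")
    # ref mismatch is an error
    expect_error(classifyEffect(gm, genome, 6, "C", "A"), "does not match")
})

test_that("effect classification is strand-symmetric on mirrored fixtures", {
    set.seed(171)
    toy <- simulateCausalGene(exonLengths = c(120, 99, 81),
                              intronLengths = c(98, 60))
    cases <- list(
        list(pos = toy$donorPos[1L], ref = "G", alt = "A"),   # splice donor
        list(pos = 60L + 50L, ref = NA, alt = NA),            # exonic
        list(pos = toy$donorPos[1L] + 20L, ref = NA, alt = NA))  # intronic
    for (cs in cases) {
        base <- as.character(Biostrings::subseq(toy$genome[["toy"]],
                                                cs$pos, cs$pos))
        alt <- setdiff(c("A", "C", "G", "T"), base)[1]
        fwd <- classifyEffect(toy$gene, toy$genome, cs$pos, base, alt)
        m <- mirrorFixture(toy$gene, toy$genome, cs$pos, base, alt)
        rev <- classifyEffect(m$gene, m$genome, m$pos, m$ref, m$alt)
        expect_equal(rev$effect_class, fwd$effect_class)
        expect_equal(rev$feature, fwd$feature)
        expect_equal(rev$wt_protein_length, fwd$wt_protein_length)
        expect_equal(rev$mut_protein_length, fwd$mut_protein_length)
        expect_equal(rev$mut_transcript_length, fwd$mut_transcript_length)
        expect_equal(rev$frameshift, fwd$frameshift)
    }
})

test_that("variant annotation table covers contained and intergenic SNPs", {
    set.seed(181)
    toy <- simulateCausalGene()
    outsideRef <- as.character(Biostrings::subseq(toy$genome[["toy"]], 1L, 1L))
    outsideAlt <- setdiff(c("A", "C", "G", "T"), outsideRef)[1]
    vs <- makeVs(2L, chrom = c("toy", "toy"),
                 pos = c(toy$donorPos[1L], 1L),
                 ref = c("G", outsideRef), alt = c("A", outsideAlt))
    ann <- annotateVariants(vs, list(toy$gene), toy$genome)
    expect_equal(ann$effect_class[1], "splice_disruption_intron_retention")
    expect_equal(ann$gene_id[1], "toy_causal_gene")
    expect_equal(ann$effect_class[2], "intergenic")
})
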