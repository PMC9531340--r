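## Fixture builders shared across test files.  Everything is generated in
## code; no data files are shipped.

## One-call VariantSet builder: defaults describe a clean EMS candidate site
## (parents homozygous-divergent G>A, deep bulk fixed for the mutant allele)
## that passes all six filter rules; override any piece per record.
makeVs <- function(n = 1L,
                   chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
                   ref = rep("G", n), alt = rep("A", n),
                   wtGeno = rep("hom_ref", n), mutGeno = rep("hom_alt", n),
                   bulkGeno = rep("hom_alt", n),
                   wtRef = rep(30L, n), wtAlt = rep(0L, n),
                   mutRef = rep(0L, n), mutAlt = rep(30L, n),
                   bulkRef = rep(0L, n), bulkAlt = rep(50L, n),
                   wtGq = rep(99L, n), mutGq = rep(99L, n),
                   bulkGq = rep(99L, n)) {
    VariantSet(chrom, pos, ref, alt,
               genotype = cbind(wt_parent = wtGeno, mut_parent = mutGeno,
                                bulk = bulkGeno),
               refDepth = cbind(wt_parent = wtRef, mut_parent = mutRef,
                                bulk = bulkRef),
               altDepth = cbind(wt_parent = wtAlt, mut_parent = mutAlt,
                                bulk = bulkAlt),
               gq = cbind(wt_parent = wtGq, mut_parent = mutGq,
                          bulk = bulkGq))
}

## Randomised records spanning the whole state space the filters see.
randomVs <- function(n) {
    genoLevels <- c("hom_ref", "het", "hom_alt", "missing")
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    rdep <- function() sample(0:200, n, replace = TRUE)
    makeVs(n, pos = sort(sample.int(1e6, n)), ref = ref, alt = unname(alt),
           wtGeno = sample(genoLevels, n, TRUE),
           mutGeno = sample(genoLevels, n, TRUE),
           bulkGeno = sample(genoLevels, n, TRUE),
           wtRef = rdep(), wtAlt = rdep(), mutRef = rdep(), mutAlt = rdep(),
           bulkRef = rdep(), bulkAlt = rdep(),
           wtGq = sample(0:99, n, TRUE), mutGq = sample(0:99, n, TRUE),
           bulkGq = sample(0:99, n, TRUE))
}

## Independent scalar re-statement of the six filter rules, written straight
## from their verbal definitions; used as the brute-force oracle against the
## vectorised implementation.
oracleFilterVerdict <- function(vs, i) {
    gt <- genotypeCalls(vs)[i, ]
    adr <- assay(vs, "refDepth")[i, ]
    ada <- assay(vs, "altDepth")[i, ]
    gq <- gqValues(vs)[i, ]
    ref <- refAllele(vs)[i]; alt <- altAllele(vs)[i]
    dep <- adr + ada
    if (dep["wt_parent"] < 3 || dep["wt_parent"] > 100 ||
        dep["mut_parent"] < 3 || dep["mut_parent"] > 100 ||
        dep["bulk"] < 5 || dep["bulk"] > 150) return("i")
    if (any(gq < 20)) return("ii")
    if (!(gt["wt_parent"] %in% c("hom_ref", "hom_alt"))) return("iii")
    carried <- function(g) switch(g, hom_ref = ref, het = c(ref, alt),
                                  hom_alt = alt, missing = character())
    crossAlleles <- union(carried(gt[["wt_parent"]]),
                          carried(gt[["mut_parent"]]))
    bulkObserved <- c(ref[adr["bulk"] > 0], alt[ada["bulk"] > 0])
    if (length(bulkObserved) &&
        !any(bulkObserved %in% crossAlleles)) return("iv")
    hom <- c("hom_ref", "hom_alt")
    if (!(gt["wt_parent"] %in% hom && gt["mut_parent"] %in% hom &&
          gt["wt_parent"] != gt["mut_parent"])) return("v")
    wtA <- if (gt["wt_parent"] == "hom_ref") ref else alt
    mutA <- if (gt["mut_parent"] == "hom_ref") ref else alt
    if (!paste0(wtA, ">", mutA) %in% c("C>T", "G>A")) return("vi")
    "pass"
}

## Mirror a (gene, genome, SNP) fixture onto the opposite strand: the contig
## is reverse-complemented and all coordinates flipped, so the biological
## object is identical and every consequence call must agree.
mirrorFixture <- function(gene, genome, pos, ref, alt) {
    contig <- genome[[gene@chrom]]
    L <- length(contig)
    rcGenome <- Biostrings::DNAStringSet(
        list(Biostrings::reverseComplement(contig)))
    names(rcGenome) <- gene@chrom
    ex <- exonRanges(gene)
    newStarts <- rev(L - end(ex) + 1L); newEnds <- rev(L - start(ex) + 1L)
    newStrand <- if (gene@strand == "+") "-" else "+"
    mGene <- GeneModel(geneId(gene), gene@chrom, newStrand,
                       newStarts, newEnds,
                       L - gene@cdsEnd + 1L, L - gene@cdsStart + 1L)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    list(gene = mGene, genome = rcGenome, pos = L - pos + 1L,
         ref = unname(comp[ref]), alt = unname(comp[alt]))
}

## Random clean ORF: ATG + sense codons + TAA.
randomOrf <- function(nCodons) {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    paste0("ATG", paste(sample(sense, nCodons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
}
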