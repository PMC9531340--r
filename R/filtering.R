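#' Six-rule SNP filtration cascade
#'
#' Reduces a raw [VariantSet-class] to candidate EMS mutations that are
#' homozygous-divergent between the parents.  The rules, applied in order
#' with first-failing-rule attribution, remove sites that are:
#' \describe{
#'   \item{i}{supported by fewer than 3 or more than 100 reads in either
#'     parent, or fewer than 5 or more than 150 reads in the bulk (strict
#'     inequalities: a depth exactly at a bound passes);}
#'   \item{ii}{of genotype quality below 20 in any role;}
#'   \item{iii}{heterozygous (or missing) in the wild-type parent;}
#'   \item{iv}{covered in the bulk only by alleles carried by neither parent
#'     (vacuous for most biallelic records — see Details);}
#'   \item{v}{not homozygous-divergent between the two parents (identical
#'     typings, or any non-homozygous parent);}
#'   \item{vi}{not an EMS-spectrum transition, i.e. the wild-type-to-mutant
#'     substitution is neither C>T nor G>A.}
#' }
#' Depth is the sum of the two allele depths (AD), not the DP field, so the
#' filter and the downstream SNP index consume the same read counts.
#'
#' @details Rule iv targets sites where the pool is "heterogeneous and both
#' alleles inconsistent" with the cross.  After biallelic decomposition the
#' bulk's observable alleles are the record's ref and alt, so the rule can
#' only fire when both parents are homozygous for one allele and every bulk
#' read carries the other — a configuration that also fails rule v, but is
#' attributed to iv because iv is tested first.  The predicate is kept
#' explicit so that decomposed multiallelic input exercises it.
#'
#' @param x a [VariantSet-class].
#' @param param a [FilterParam-class].
#' @return `filterVariants()` returns `list(kept = VariantSet, report = list)`
#'   where `report` has `input`, `kept` and `removed` (named i..vi); the
#'   counts always satisfy `input == kept + sum(removed)`.  The individual
#'   `rule*()` functions return a logical pass vector, one element per site.
#' @examples
#' vs <- VariantSet("chr1", c(100L, 200L), c("G", "A"), c("A", "G"),
#'     genotype = matrix(c("hom_ref", "hom_alt", "hom_alt",
#'                         "hom_ref", "hom_alt", "hom_alt"),
#'                       2, 3, byrow = TRUE),
#'     refDepth = matrix(c(20L, 0L, 2L, 20L, 0L, 2L), 2, 3, byrow = TRUE),
#'     altDepth = matrix(c(0L, 20L, 48L, 0L, 20L, 48L), 2, 3, byrow = TRUE),
#'     gq = matrix(99L, 2, 3))
#' filterVariants(vs)$report$kept  # G>A passes the EMS rule, A>G does not
#' @export
filterVariants <- function(x, param = FilterParam()) {
    stopifnot(is(x, "VariantSet"), is(param, "FilterParam"))
    n <- nrow(x)
    rules <- cbind(i = ruleDepth(x, param), ii = ruleGq(x, param),
                   iii = ruleParentHet(x), iv = ruleBulkForeignAllele(x),
                   v = ruleParentsIdentical(x),
                   vi = if (param@emsOnly) ruleEmsSpectrum(x) else rep(TRUE, n))
    firstFail <- apply(rules, 1L, function(p)
        if (all(p)) NA_integer_ else which(!p)[1L])
    removed <- vapply(seq_len(ncol(rules)), function(k)
        sum(firstFail == k, na.rm = TRUE), integer(1))
    names(removed) <- colnames(rules)
    kept <- x[is.na(firstFail), ]
    list(kept = kept,
         report = list(input = n, kept = nrow(kept), removed = as.list(removed)))
}

#' @rdname filterVariants
#' @export
ruleDepth <- function(x, param = FilterParam()) {
    d <- readDepth(x)
    unname(d[, "wt_parent"] >= param@parentDepthMin &
        d[, "wt_parent"] <= param@parentDepthMax &
        d[, "mut_parent"] >= param@parentDepthMin &
        d[, "mut_parent"] <= param@parentDepthMax &
        d[, "bulk"] >= param@bulkDepthMin & d[, "bulk"] <= param@bulkDepthMax)
}

#' @rdname filterVariants
#' @export
ruleGq <- function(x, param = FilterParam()) {
    gq <- gqValues(x)
    unname(rowSums(gq < param@gqMin) == 0L)
}

#' @rdname filterVariants
#' @export
ruleParentHet <- function(x) {
    wt <- genotypeCalls(x)[, "wt_parent"]
    unname(wt %in% c("hom_ref", "hom_alt"))
}

#' @rdname filterVariants
#' @export
ruleBulkForeignAllele <- function(x) {
    gt <- genotypeCalls(x)
    adr <- assay(x, "refDepth"); ada <- assay(x, "altDepth")
    bulkRef <- adr[, "bulk"] > 0L; bulkAlt <- ada[, "bulk"] > 0L
    carriesRef <- function(g) g %in% c("hom_ref", "het")
    carriesAlt <- function(g) g %in% c("hom_alt", "het")
    crossRef <- carriesRef(gt[, "wt_parent"]) | carriesRef(gt[, "mut_parent"])
    crossAlt <- carriesAlt(gt[, "wt_parent"]) | carriesAlt(gt[, "mut_parent"])
    observed <- bulkRef | bulkAlt
    consistent <- (bulkRef & crossRef) | (bulkAlt & crossAlt)
    unname(!observed | consistent)
}

#' @rdname filterVariants
#' @export
ruleParentsIdentical <- function(x) {
    gt <- genotypeCalls(x)
    wt <- gt[, "wt_parent"]; mut <- gt[, "mut_parent"]
    hom <- c("hom_ref", "hom_alt")
    unname(wt %in% hom & mut %in% hom & wt != mut)
}

#' @rdname filterVariants
#' @export
ruleEmsSpectrum <- function(x) {
    gt <- genotypeCalls(x)
    ref <- refAllele(x); alt <- altAllele(x)
    homAllele <- function(g) ifelse(g == "hom_ref", ref,
                             ifelse(g == "hom_alt", alt, NA_character_))
    wtA <- homAllele(gt[, "wt_parent"]); mutA <- homAllele(gt[, "mut_parent"])
    sub <- paste0(wtA, ">", mutA)
    unname(!is.na(wtA) & !is.na(mutA) & sub %in% c("C>T", "G>A"))
}

#' Per-site mutant-allele orientation
#'
#' The mutant allele at a site is the mutant parent's homozygous allele
#' (not the VCF alt), which makes the SNP index robust to reference polarity.
#'
#' @param x a [VariantSet-class].
#' @return character vector of mutant alleles (`NA` where the mutant parent
#'   is not homozygous).
#' @export
mutantAllele <- function(x) {
    g <- genotypeCalls(x)[, "mut_parent"]
    ifelse(g == "hom_alt", altAllele(x),
    ifelse(g == "hom_ref", refAllele(x), NA_character_))
}
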