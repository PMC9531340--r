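#' Mendelian segregation ratio
#'
#' @param observed length-2 non-negative counts `(class A, class B)`, e.g.
#'   wild-type and mutant phenotype counts.
#' @param digits decimals for the reported ratio (3, matching the convention
#'   of published segregation tables).
#' @return The ratio `A / B`, rounded.
#' @examples
#' segregationRatio(c(321, 89))  # 3.607
#' segregationRatio(c(18, 20))   # 0.9
#' @export
segregationRatio <- function(observed, digits = 3) {
    stopifnot(length(observed) == 2L, all(observed >= 0))
    if (observed[2L] == 0) stop("class B count is zero; ratio undefined")
    round(observed[1L] / observed[2L], digits)
}

#' Chi-square goodness-of-fit test for a two-class Mendelian ratio
#'
#' Tests observed counts against an expected ratio (3:1 for an F2 recessive
#' trait, 1:1 for a backcross) with one degree of freedom.  By default the
#' Yates continuity correction is applied with a floor at zero:
#' \deqn{\chi^2 = \sum_i \frac{\max(|O_i - E_i| - 0.5,\, 0)^2}{E_i}}
#' which corrects the discreteness of counts against the continuous
#' chi-square reference distribution.  Without correction the statistic is
#' the classical \eqn{\sum (O_i - E_i)^2 / E_i}.
#'
#' @param observed length-2 counts `(class A, class B)`.
#' @param ratio expected ratio shares, e.g. `c(3, 1)` or `c(1, 1)`.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return An object of class `SegregationTest` (a list) with fields
#'   `observed`, `expected`, `ratio`, `chi2` (full precision; print shows 3
#'   decimals), `df` (= 1), `p_value` (upper tail of \eqn{\chi^2_1}) and
#'   `yates`.
#' @examples
#' chiSquareGof(c(321, 89), c(3, 1))$chi2          # 2.198 (rounded)
#' chiSquareGof(c(18, 20), c(1, 1))$chi2           # 0.026 (rounded)
#' chiSquareGof(c(321, 89), c(3, 1), yates = FALSE)$chi2  # 2.371 (rounded)
#' @export
chiSquareGof <- function(observed, ratio = c(3, 1), yates = TRUE) {
    stopifnot(length(observed) == 2L, length(ratio) == 2L,
              all(observed >= 0))
    if (any(ratio <= 0)) stop("ratio shares must be positive")
    total <- sum(observed)
    if (total <= 0) stop("total count must be positive")
    expected <- total * ratio / sum(ratio)
    dev <- abs(observed - expected)
    chi2 <- if (isTRUE(yates)) sum(pmax(dev - 0.5, 0)^2 / expected)
            else sum(dev^2 / expected)
    structure(list(observed = observed, expected = expected, ratio = ratio,
                   chi2 = chi2, df = 1L,
                   p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                   yates = isTRUE(yates)),
              class = "SegregationTest")
}

#' @export
print.SegregationTest <- function(x, ...) {
    cat(sprintf(
        "Segregation %d:%d vs %s:%s  ratio %.3f:1  chi2 = %.3f (df=1%s)  p = %.3g\n",
        x$observed[1L], x$observed[2L], format(x$ratio[1L]),
        format(x$ratio[2L]), x$observed[1L] / x$observed[2L], x$chi2,
        if (x$yates) ", Yates" else "", x$p_value))
    invisible(x)
}

#' Recessive genotype-phenotype co-segregation check
#'
#' KASP-style validation of a candidate SNP: the mutation co-segregates with
#' a recessive trait when every mutant-phenotype plant is homozygous for the
#' mutant allele and every wild-type-phenotype plant is heterozygous or
#' homozygous wild type.
#'
#' @param genotypes `data.frame` with `plant_id` and `genotype` written as
#'   `allele:allele` (order-insensitive, e.g. `"C:T"`).
#' @param phenotypes `data.frame` with `plant_id` and `phenotype`
#'   (`"wild_type"` or `"mutant"`).
#' @param mutantAllele the mutant allele letter, e.g. `"T"`.
#' @return A list of class `CosegregationResult`: `n_plants`,
#'   `n_mutant_phenotype`, `n_concordant`, `consistent`, `discordant_ids`.
#'   A plant present in only one table is an error.
#' @export
checkRecessiveCosegregation <- function(genotypes, phenotypes, mutantAllele) {
    stopifnot(all(c("plant_id", "genotype") %in% names(genotypes)),
              all(c("plant_id", "phenotype") %in% names(phenotypes)))
    only <- c(setdiff(genotypes$plant_id, phenotypes$plant_id),
              setdiff(phenotypes$plant_id, genotypes$plant_id))
    if (length(only))
        stop("plant(s) present in only one table: ",
             paste(only, collapse = ", "))
    m <- merge(genotypes, phenotypes, by = "plant_id")
    alleles <- strsplit(m$genotype, ":", fixed = TRUE)
    nMut <- vapply(alleles, function(a) sum(a == mutantAllele), integer(1))
    concordant <- ifelse(m$phenotype == "mutant", nMut == 2L, nMut < 2L)
    structure(list(n_plants = nrow(m),
                   n_mutant_phenotype = sum(m$phenotype == "mutant"),
                   n_concordant = sum(concordant),
                   consistent = all(concordant),
                   discordant_ids = m$plant_id[!concordant]),
              class = "CosegregationResult")
}

#' @export
print.CosegregationResult <- function(x, ...) {
    cat(sprintf(
        "Co-segregation over %d plants (%d mutant-phenotype): %s (%d/%d concordant)\n",
        x$n_plants, x$n_mutant_phenotype,
        if (x$consistent) "consistent" else "NOT consistent",
        x$n_concordant, x$n_plants))
    if (length(x$discordant_ids))
        cat("  discordant:", paste(x$discordant_ids, collapse = ", "), "\n")
    invisible(x)
}
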