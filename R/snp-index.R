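#' Per-SNP index from bulk allele depths
#'
#' The SNP index at a site is the fraction of bulk reads carrying the mutant
#' allele — the allele for which the mutant parent is homozygous.  For a
#' recessive bulk it is expected to be 1.0 at the causal site, 0.5 at
#' unlinked sites and \eqn{1 - r} at recombination fraction \eqn{r}.  Sites
#' with zero bulk depth, or where the mutant parent is not homozygous, are
#' excluded with a message.
#'
#' @param x a filtered [VariantSet-class].
#' @return A `data.frame` with columns `chrom`, `pos`, `index`, `bulk_depth`,
#'   sorted by chromosome and position.
#' @examples
#' # bulk AD (7, 21) with alt as the mutant allele -> 21/28 = 0.75
#' @export
snpIndex <- function(x) {
    stopifnot(is(x, "VariantSet"))
    mut <- mutantAllele(x)
    adr <- assay(x, "refDepth")[, "bulk"]
    ada <- assay(x, "altDepth")[, "bulk"]
    depth <- adr + ada
    mutReads <- ifelse(mut == altAllele(x), ada, adr)
    drop <- depth == 0L | is.na(mut)
    if (any(drop))
        message(sum(drop), " site(s) excluded (zero bulk depth or ",
                "non-homozygous mutant parent)")
    rr <- rowRanges(x)
    out <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      index = mutReads / depth, bulk_depth = depth,
                      stringsAsFactors = FALSE)[!drop, , drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Sliding-window smoothing of the SNP-index track
#'
#' Each window of width `windowBp` centred every `stepBp` along a chromosome
#' receives the arithmetic mean of the raw indices of the SNPs it contains;
#' windows with fewer than `minSnps` SNPs are masked (`NA`).  Centres span
#' the range of observed SNP positions on each chromosome.
#'
#' @param points `data.frame` from [snpIndex()].
#' @param param a [ScanParam-class] (window 2 Mb, step 10 kb, `minSnps` 3 by
#'   default).
#' @return A `data.frame` with columns `chrom`, `center`, `index`, `n_snps`;
#'   masked windows carry `NA` index.  Window geometry is attached as
#'   attributes `windowBp` and `stepBp`.
#' @export
slidingWindowTrack <- function(points, param = ScanParam()) {
    stopifnot(is(param, "ScanParam"))
    w2 <- param@windowBp / 2
    res <- lapply(split(points, points$chrom), function(p) {
        p <- p[order(p$pos), , drop = FALSE]
        lo <- floor(min(p$pos) / param@stepBp) * param@stepBp
        hi <- ceiling(max(p$pos) / param@stepBp) * param@stepBp
        centers <- seq(lo, hi, by = param@stepBp)
        idx <- findInterval(c(centers - w2 - 1, centers + w2), p$pos)
        nIn <- idx[-seq_along(centers)] - idx[seq_along(centers)]
        means <- vapply(seq_along(centers), function(k) {
            if (nIn[k] < param@minSnps) return(NA_real_)
            mean(p$index[(idx[k] + 1L):idx[k + length(centers)]])
        }, numeric(1))
        data.frame(chrom = p$chrom[1L], center = centers, index = means,
                   n_snps = nIn, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "windowBp") <- param@windowBp
    attr(out, "stepBp") <- param@stepBp
    out
}

#' Call candidate regions above the SNP-index threshold
#'
#' Finds, per chromosome, maximal runs of consecutive unmasked windows whose
#' smoothed index is at or above the threshold (0.80 by default, the fixed
#' threshold of the mapping design) and snaps each run to the first and last
#' raw SNP within its genomic span.  With `param@smoothed = FALSE` the
#' threshold is applied to the raw per-SNP indices instead and runs are
#' maximal stretches of consecutive above-threshold SNPs.
#'
#' @param track `data.frame` from [slidingWindowTrack()] (ignored when
#'   `param@smoothed` is `FALSE`).
#' @param points raw `data.frame` from [snpIndex()].
#' @param param a [ScanParam-class].
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `length_mb`
#'   (`(end - start) / 1e6`, rounded to 2 decimals), `peak_index`, `n_snps`,
#'   sorted by `peak_index` decreasing.  Empty input gives zero rows.
#' @examples
#' pts <- data.frame(chrom = "A10", pos = c(228525, 5e6, 9905099),
#'                   index = 1, bulk_depth = 50L)
#' trk <- slidingWindowTrack(pts, ScanParam(minSnps = 1))
#' callCandidateRegions(trk, pts)  # one region of 9.68 Mb
#' @export
callCandidateRegions <- function(track, points, param = ScanParam()) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), length_mb = numeric(),
                        peak_index = numeric(), n_snps = integer(),
                        stringsAsFactors = FALSE)
    if (!param@smoothed) {
        regs <- lapply(split(points, points$chrom), function(p) {
            p <- p[order(p$pos), , drop = FALSE]
            .runsToRegions(p$index >= param@threshold, p$pos, p$pos, p)
        })
    } else {
        if (is.null(track) || nrow(track) == 0L) return(empty)
        w2 <- attr(track, "windowBp") / 2
        regs <- lapply(split(track, track$chrom), function(tr) {
            p <- points[points$chrom == tr$chrom[1L], , drop = FALSE]
            p <- p[order(p$pos), , drop = FALSE]
            hot <- !is.na(tr$index) & tr$index >= param@threshold
            .runsToRegions(hot, tr$center - w2, tr$center + w2, p,
                           smoothIdx = tr$index)
        })
    }
    out <- do.call(rbind, c(regs, list(empty)))
    out <- out[order(-out$peak_index), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## turn a logical run vector into SNP-snapped regions; spanLo/spanHi give the
## genomic span of each run element; p holds the raw SNPs of that chromosome
.runsToRegions <- function(hot, spanLo, spanHi, p, smoothIdx = NULL) {
    out <- list()
    r <- rle(hot)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
        lo <- spanLo[starts[k]]; hi <- spanHi[ends[k]]
        inSpan <- p$pos >= lo & p$pos <= hi
        if (!any(inSpan)) next
        pk <- if (is.null(smoothIdx)) max(p$index[inSpan]) else
            max(smoothIdx[starts[k]:ends[k]])
        s <- min(p$pos[inSpan]); e <- max(p$pos[inSpan])
        out[[length(out) + 1L]] <- data.frame(
            chrom = p$chrom[1L], start = s, end = e,
            length_mb = round((e - s) / 1e6, 2), peak_index = pk,
            n_snps = sum(inSpan), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' One-call SNP-index scan
#'
#' Convenience wrapper running [snpIndex()], [slidingWindowTrack()] and
#' [callCandidateRegions()] on a filtered [VariantSet-class].
#'
#' @param x a filtered [VariantSet-class].
#' @param param a [ScanParam-class].
#' @return `list(points, track, regions)`.
#' @export
scanSnpIndex <- function(x, param = ScanParam()) {
    points <- snpIndex(x)
    track <- if (nrow(points)) slidingWindowTrack(points, param) else NULL
    regions <- if (nrow(points))
        callCandidateRegions(track, points, param)
    else
        callCandidateRegions(NULL, points, param)
    list(points = points, track = track, regions = regions)
}

#' Expected SNP index at a linked marker
#'
#' Among F2 individuals homozygous for the recessive causal allele, a marker
#' at recombination fraction \eqn{r} from the causal locus carries the
#' mutant allele with probability \eqn{1 - r} per chromosome: each selected
#' chromosome is an F1 gamete that carried the causal allele, and stays
#' parental at the marker unless a recombination separated the two loci.
#'
#' @param r recombination fraction in \[0, 0.5\].
#' @return The expected mutant-allele frequency `1 - r`.
#' @export
expectedIndexAtLinkedMarker <- function(r) {
    if (any(r < 0 | r > 0.5)) stop("r must be in [0, 0.5]")
    1 - r
}

#' Haldane map function
#'
#' Converts genetic distance `d` (Morgans) to recombination fraction assuming
#' crossovers arrive as a Poisson process with no interference.
#'
#' @param d genetic distance in Morgans.
#' @return Recombination fraction \eqn{(1 - e^{-2d})/2}.
#' @export
haldaneR <- function(d) (1 - exp(-2 * d)) / 2

#' Plot a per-chromosome SNP-index track
#'
#' Raw indices as points, smoothed track as a line, threshold as a dashed
#' horizontal line — the conventional bulked-segregant index plot.
#'
#' @param points,track from [scanSnpIndex()].
#' @param threshold index threshold to draw.
#' @return `NULL`, invisibly.
#' @export
plotSnpIndex <- function(points, track = NULL, threshold = 0.80) {
    chroms <- unique(points$chrom)
    op <- graphics::par(mfrow = c(length(chroms), 1),
                        mar = c(3.5, 4, 1.5, 1))
    on.exit(graphics::par(op))
    for (ch in chroms) {
        p <- points[points$chrom == ch, ]
        plot(p$pos / 1e6, p$index, pch = 16, cex = 0.5, ylim = c(0, 1),
             xlab = "position (Mb)", ylab = "SNP index", main = ch)
        if (!is.null(track)) {
            tr <- track[track$chrom == ch, ]
            graphics::lines(tr$center / 1e6, tr$index, col = "steelblue")
        }
        graphics::abline(h = threshold, lty = 2, col = "deeppink")
    }
    invisible(NULL)
}
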