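#' Weighted average correct association percentage
#'
#' Region-level score averaging sensitivity and specificity across
#' replicates:
#' \deqn{\tfrac12\Big[\frac{\sum_r P(\mathrm{selected}\mid r\ \mathrm{assoc})}
#'   {\#\ \mathrm{assoc}} +
#'   \frac{\sum_r P(\mathrm{unselected}\mid r\ \mathrm{unassoc})}
#'   {\#\ \mathrm{unassoc}}\Big]}
#' where the per-region selection probabilities are the selection rates
#' over replicates.
#'
#' @param selected logical matrix, replicates x regions: region selected in
#'   that replicate.
#' @param associated logical vector, one entry per region: truly
#'   disease-associated.
#' @return Fraction in `[0, 1]` (multiply by 100 for percent).
#' @export
wacap <- function(selected, associated) {
    selected <- as.matrix(selected)
    stopifnot(ncol(selected) == length(associated))
    if (!any(associated) || all(associated))
        stop("need at least one associated and one unassociated region")
    rate <- colMeans(selected)
    (mean(rate[associated]) + mean(1 - rate[!associated])) / 2
}

#' Average true and false positive rates for individual variants
#'
#' Per replicate dataset, the true (false) positive rate is the fraction of
#' associated (unassociated) variants selected among those polymorphic in
#' that dataset; rates are then averaged over replicates.  With
#' `restrict = "allPolymorphic"` only variants polymorphic in every
#' replicate enter the denominators.  Replicates with an empty denominator
#' are skipped for the affected rate, with a warning.
#'
#' @param selected logical matrix, replicates x variants.
#' @param causal logical vector, one entry per variant.
#' @param polymorphic logical matrix, replicates x variants (default: all
#'   polymorphic).
#' @param restrict `"perDataset"` or `"allPolymorphic"`.
#' @return Named numeric: `ATPR` and `AFPR`, both in `[0, 1]`.
#' @export
atprAfpr <- function(selected, causal, polymorphic = NULL,
                     restrict = c("perDataset", "allPolymorphic")) {
    restrict <- match.arg(restrict)
    selected <- as.matrix(selected)
    D <- nrow(selected)
    stopifnot(ncol(selected) == length(causal))
    if (is.null(polymorphic))
        polymorphic <- matrix(TRUE, D, length(causal))
    polymorphic <- as.matrix(polymorphic)
    if (restrict == "allPolymorphic") {
        always <- apply(polymorphic, 2L, all)
        polymorphic <- matrix(rep(always, each = D), D)
    }
    rateOf <- function(mask) {
        vals <- vapply(seq_len(D), function(d) {
            den <- sum(mask & polymorphic[d, ])
            if (den == 0L) return(NA_real_)
            sum(selected[d, ] & mask & polymorphic[d, ]) / den
        }, numeric(1))
        if (anyNA(vals))
            warning(sum(is.na(vals)),
                    " replicate(s) had no polymorphic variant in a class",
                    " and were skipped")
        mean(vals, na.rm = TRUE)
    }
    c(ATPR = rateOf(causal), AFPR = rateOf(!causal))
}

#' MAF-stratified true/false positive rates
#'
#' Computes [atprAfpr()] within bins of (median) minor allele frequency.
#'
#' @param selected,causal,polymorphic,restrict as in [atprAfpr()].
#' @param maf per-variant MAF used for binning (typically the median sample
#'   MAF across replicates).
#' @param breaks bin breakpoints (default `c(0, 0.01, 0.05, Inf)`).
#' @return data.frame with one row per bin: the bin label, counts of
#'   associated/unassociated variants in the bin, and ATPR/AFPR (`NA` when
#'   a bin has no members of the class).
#' @export
mafStratifiedReport <- function(selected, causal, maf, polymorphic = NULL,
                                breaks = c(0, 0.01, 0.05, Inf),
                                restrict = c("perDataset",
                                             "allPolymorphic")) {
    restrict <- match.arg(restrict)
    selected <- as.matrix(selected)
    bin <- cut(maf, breaks, right = FALSE, include.lowest = FALSE)
    out <- lapply(levels(bin), function(lv) {
        idx <- which(!is.na(bin) & bin == lv)
        row <- data.frame(bin = lv, nAssociated = sum(causal[idx]),
                          nUnassociated = sum(!causal[idx]),
                          ATPR = NA_real_, AFPR = NA_real_)
        if (!length(idx)) return(row)
        rates <- suppressWarnings(atprAfpr(
            selected[, idx, drop = FALSE], causal[idx],
            if (is.null(polymorphic)) NULL
            else polymorphic[, idx, drop = FALSE], restrict))
        row$ATPR <- if (row$nAssociated) rates[["ATPR"]] else NA_real_
        row$AFPR <- if (row$nUnassociated) rates[["AFPR"]] else NA_real_
        row
    })
    do.call(rbind, out)
}
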