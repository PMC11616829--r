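#' @include AllClasses.R
NULL

#' Build a synthetic admixed haplotype pool
#'
#' Parametric stand-in for a coalescent haplotype pool: a panel of variants
#' partitioned into equal-sized gene regions, with per-subpopulation allele
#' frequencies whose admixture-weighted average (folded to at most 0.5) is
#' the variant's weighted minor allele frequency.  Defaults follow a
#' two-subpopulation 25%/75% admixture over 12 regions of 2700 bp, with a
#' handful of common sites per region and rare sites drawn from a
#' log-uniform frequency spectrum; one designated "sentinel" rare site of
#' weighted MAF 0.026 is placed in region 1 as a benchmark variant.
#'
#' @param nRegions number of gene regions (default 12).
#' @param commonPerRegion common sites per region (default 2).
#' @param admixWeights admixture proportions, one per subpopulation.
#' @param regionSize region length in base pairs (default 2700).
#' @param commonRange weighted-MAF range for common sites (drawn uniformly).
#' @param rareBinBreaks,rareBinCounts rare-site frequency spectrum: per
#'   region, `rareBinCounts[k]` sites are drawn log-uniformly inside MAF
#'   bin `[rareBinBreaks[k], rareBinBreaks[k+1])`.  The default (5 sites in
#'   `[1e-4, 1e-3)`, 2 in `[1e-3, 0.01)`, 1 in `[0.01, 0.04)`) is
#'   bottom-heavy: most rare variation is very rare, as in sequencing
#'   panels.
#' @param sentinelMAF weighted MAF of the sentinel rare site (`NULL` for
#'   none); `sentinelRegion` places it.
#' @param divergence relative spread of subpopulation frequencies around
#'   the weighted MAF (0 = identical subpopulations).
#' @param rareThreshold weighted-MAF cutoff for the `isCommon` flag.
#' @param seed RNG seed; the pool is reproducible given the seed.
#' @return A [TrioPool-class] object; its variant table carries an extra
#'   `sentinel` column.
#' @export
buildPool <- function(nRegions = 12L, commonPerRegion = 2L,
                      rareBinBreaks = c(1e-4, 1e-3, 0.01, 0.04),
                      rareBinCounts = c(5L, 2L, 1L),
                      admixWeights = c(0.25, 0.75),
                      regionSize = 2700L, commonRange = c(0.1, 0.4),
                      sentinelMAF = 0.026, sentinelRegion = 1L,
                      divergence = 0.5, rareThreshold = 0.05, seed = 1L) {
    stopifnot(nRegions >= 1, commonPerRegion >= 0, all(admixWeights > 0),
              length(rareBinBreaks) == length(rareBinCounts) + 1L,
              !is.unsorted(rareBinBreaks, strictly = TRUE))
    if (abs(sum(admixWeights) - 1) > 1e-8)
        stop("admixture weights must sum to 1")
    set.seed(seed)
    rarePerRegion <- sum(rareBinCounts)
    perRegion <- commonPerRegion + rarePerRegion
    region <- rep(seq_len(nRegions), each = perRegion)
    p <- length(region)
    maf <- numeric(p)
    sentinel <- logical(p)
    for (r in seq_len(nRegions)) {
        idx <- which(region == r)
        mafC <- stats::runif(commonPerRegion, commonRange[1], commonRange[2])
        mafR <- unlist(lapply(seq_along(rareBinCounts), function(k)
            exp(stats::runif(rareBinCounts[k], log(rareBinBreaks[k]),
                             log(rareBinBreaks[k + 1L])))))
        if (!is.null(sentinelMAF) && r == sentinelRegion &&
            rarePerRegion > 0) {
            j <- which.min(abs(mafR - sentinelMAF))
            mafR[j] <- sentinelMAF
            sentinel[idx[commonPerRegion + j]] <- TRUE
        }
        maf[idx] <- c(mafC, mafR)
    }
    position <- integer(p)
    for (r in seq_len(nRegions)) {
        idx <- which(region == r)
        position[idx] <- sort(sample.int(regionSize, length(idx))) +
            (r - 1L) * regionSize
    }
    # subpopulation frequencies consistent with the weighted MAF
    nSub <- length(admixWeights)
    freqs <- matrix(0, nSub, p)
    for (j in seq_len(p)) {
        u <- stats::runif(nSub, 1 - divergence, 1 + divergence)
        f <- maf[j] * u
        f <- f * maf[j] / sum(admixWeights * f)   # renormalise exactly
        freqs[, j] <- pmin(pmax(f, 0), 1)
    }
    id <- sprintf("R%02dV%02d", region, stats::ave(region, region,
                                                   FUN = seq_along))
    variants <- data.frame(id = id, position = position, region = region,
                           maf = maf, isCommon = maf >= rareThreshold,
                           sentinel = sentinel)
    new("TrioPool", freqs = freqs, weights = admixWeights,
        variants = variants)
}

#' Weighted minor allele frequency
#'
#' Admixture-weighted average of subpopulation allele frequencies, folded
#' to the minor allele (at most 0.5).
#'
#' @param freqs per-subpopulation allele frequencies (vector, or matrix
#'   with one row per subpopulation).
#' @param weights admixture proportions summing to one.
#' @return Weighted MAF(s) in `[0, 0.5]`.
#' @export
weightedMAF <- function(freqs, weights) {
    if (is.matrix(freqs)) f <- as.numeric(weights %*% freqs)
    else f <- sum(weights * freqs)
    pmin(f, 1 - f)
}

#' Attach a causal disease model to a pool
#'
#' Designates causal variants and their log-odds effects.  Two common
#' variants (the highest-MAF common site of each region in
#' `commonRegions`) receive effects `commonEffects`.  Causal rare variants
#' are drawn per region among sites with weighted MAF below
#' `rareEligibleMAF`, with counts `rareCausalPerRegion`; each receives an
#' effect of magnitude `rareEffectScale * |log10(weighted MAF)|`, so rarer
#' variants act more strongly.  Signs are split equally between risk and
#' protective (an odd count is resolved by a seeded coin), except that a
#' sentinel site is always causal and risk-increasing.  Alternatively,
#' `causalFraction` selects that fraction of all eligible sites at random
#' instead of the per-region counts.
#'
#' @param pool a [TrioPool-class] object.
#' @param intercept logistic intercept (default -2.2, a low-prevalence
#'   disease).
#' @param commonEffects,commonRegions effects and host regions of the
#'   causal common variants.
#' @param rareCausalPerRegion causal rare counts for regions 1, 2, ...
#'   (default `c(3, 1, 2, 2, 1, 2)`: causal variation confined to the first
#'   six regions).
#' @param causalFraction if non-`NULL`, overrides `rareCausalPerRegion`.
#' @param rareEligibleMAF eligibility cutoff (default 0.03).
#' @param rareEffectScale magnitude coefficient `c` (default 0.4).
#' @param seed RNG seed for the causal draw.
#' @return A [TrioSimModel-class] object.
#' @export
assignEffects <- function(pool, intercept = -2.2,
                          commonEffects = c(0.9, -0.9),
                          commonRegions = c(3L, 6L),
                          rareCausalPerRegion = c(3L, 1L, 2L, 2L, 1L, 2L),
                          causalFraction = NULL, rareEligibleMAF = 0.03,
                          rareEffectScale = 0.4, seed = 1L) {
    set.seed(seed)
    v <- pool@variants
    effects <- numeric(nrow(v))
    stopifnot(length(commonEffects) == length(commonRegions))
    for (k in seq_along(commonRegions)) {
        idx <- which(v$isCommon & v$region == commonRegions[k])
        if (!length(idx))
            stop("no common variant available in region ", commonRegions[k])
        pick <- idx[which.max(v$maf[idx])]
        effects[pick] <- commonEffects[k]
    }
    eligible <- which(!v$isCommon & v$maf < rareEligibleMAF)
    sent <- if ("sentinel" %in% names(v)) which(v$sentinel) else integer(0)
    causalRare <- integer(0)
    if (!is.null(causalFraction)) {
        nC <- round(causalFraction * length(eligible))
        causalRare <- sort(sample(eligible, min(nC, length(eligible))))
    } else {
        for (r in seq_along(rareCausalPerRegion)) {
            nR <- rareCausalPerRegion[r]
            if (nR == 0L) next
            cand <- intersect(eligible, which(v$region == r))
            if (length(cand) < nR)
                stop("region ", r, " has only ", length(cand),
                     " eligible rare site(s), need ", nR)
            must <- intersect(cand, sent)
            extra <- setdiff(cand, must)
            pick <- c(must, sample(extra, nR - length(must)))
            causalRare <- c(causalRare, pick)
        }
        causalRare <- sort(causalRare)
    }
    if (!is.null(causalFraction) && length(sent))
        causalRare <- sort(union(causalRare, intersect(sent, eligible)))
    if (!length(causalRare) && is.null(causalFraction) &&
        sum(rareCausalPerRegion) > 0)
        stop("no eligible rare sites for the causal draw")
    if (length(causalRare)) {
        mag <- rareEffectScale * abs(log10(v$maf[causalRare]))
        sgn <- rep(NA, length(causalRare))
        sgn[causalRare %in% sent] <- 1
        free <- which(is.na(sgn))
        nFree <- length(free)
        nPos <- floor(nFree / 2)
        if (nFree %% 2 == 1 && stats::runif(1) < 0.5) nPos <- nPos + 1L
        signs <- sample(c(rep(1, nPos), rep(-1, nFree - nPos)))
        sgn[free] <- signs
        effects[causalRare] <- sgn * mag
    }
    names(effects) <- v$id
    new("TrioSimModel", pool = pool, intercept = intercept,
        effects = effects)
}

setMethod("show", "TrioSimModel", function(object) {
    v <- object@pool@variants
    causal <- object@effects != 0
    cat("TrioSimModel:", nrow(v), "variants in",
        length(unique(v$region)), "regions; intercept",
        object@intercept, "\n")
    cat("  causal:", sum(causal & v$isCommon), "common,",
        sum(causal & !v$isCommon), "rare\n")
})

setMethod("show", "TrioPool", function(object) {
    v <- object@variants
    cat("TrioPool:", nrow(v), "variants (", sum(v$isCommon), "common,",
        sum(!v$isCommon), "rare ) in", length(unique(v$region)),
        "regions;", length(object@weights), "subpopulations\n")
})

#' Sample ascertained case-parent trios
#'
#' Draws candidate families (each wholly from one subpopulation, chosen
#' with the admixture weights), forms the child by random transmission of
#' one haplotype per parent, and accepts the family with the child's
#' disease probability under the logistic model -- rejection sampling that
#' reproduces ascertainment through the affected child.
#'
#' @param model a [TrioSimModel-class] object.
#' @param n number of accepted trios required.
#' @param seed RNG seed.
#' @return list of `n`-row matrices/vectors: parental haplotypes `mh1`,
#'   `mh2`, `fh1`, `fh2` (n x p, 0/1), transmission flags `tm`, `tf`
#'   (`TRUE` = first haplotype transmitted), `subpop`, and the realised
#'   `acceptanceRate` (accepted / candidates drawn).
#' @export
sampleCaseTrios <- function(model, n, seed = 1L) {
    set.seed(seed)
    pool <- model@pool
    p <- nrow(pool@variants)
    if (n == 0L) {
        e <- matrix(0L, 0L, p)
        return(list(mh1 = e, mh2 = e, fh1 = e, fh2 = e,
                    tm = logical(0), tf = logical(0), subpop = integer(0),
                    acceptanceRate = NA_real_))
    }
    causal <- which(model@effects != 0)
    eff <- model@effects[causal]
    keep <- list()
    nAcc <- 0L
    nCand <- 0L
    while (nAcc < n) {
        B <- min(max(1000L, ceiling((n - nAcc) * 15)), 40000L)
        sub <- sample.int(length(pool@weights), B, replace = TRUE,
                          prob = pool@weights)
        Fr <- pool@freqs[sub, , drop = FALSE]
        draw <- function() matrix(stats::runif(B * p) < Fr, B, p) + 0L
        mh1 <- draw(); mh2 <- draw(); fh1 <- draw(); fh2 <- draw()
        tm <- stats::runif(B) < 0.5
        tf <- stats::runif(B) < 0.5
        childM <- mh1; childM[!tm, ] <- mh2[!tm, ]
        childF <- fh1; childF[!tf, ] <- fh2[!tf, ]
        if (length(causal)) {
            G <- childM[, causal, drop = FALSE] +
                 childF[, causal, drop = FALSE]
            eta <- model@intercept + as.numeric(G %*% eff)
        } else eta <- rep(model@intercept, B)
        acc <- stats::runif(B) < stats::plogis(eta)
        nCand <- nCand + B
        if (any(acc)) {
            keep[[length(keep) + 1L]] <-
                list(mh1 = mh1[acc, , drop = FALSE],
                     mh2 = mh2[acc, , drop = FALSE],
                     fh1 = fh1[acc, , drop = FALSE],
                     fh2 = fh2[acc, , drop = FALSE],
                     tm = tm[acc], tf = tf[acc], subpop = sub[acc])
            nAcc <- nAcc + sum(acc)
        }
        if (nCand > 1e7 && nAcc == 0L)
            stop("acceptance probability is effectively zero; ",
                 "check the disease model")
    }
    out <- list(
        mh1 = do.call(rbind, lapply(keep, `[[`, "mh1"))[seq_len(n), , drop = FALSE],
        mh2 = do.call(rbind, lapply(keep, `[[`, "mh2"))[seq_len(n), , drop = FALSE],
        fh1 = do.call(rbind, lapply(keep, `[[`, "fh1"))[seq_len(n), , drop = FALSE],
        fh2 = do.call(rbind, lapply(keep, `[[`, "fh2"))[seq_len(n), , drop = FALSE],
        tm = do.call(c, lapply(keep, `[[`, "tm"))[seq_len(n)],
        tf = do.call(c, lapply(keep, `[[`, "tf"))[seq_len(n)],
        subpop = do.call(c, lapply(keep, `[[`, "subpop"))[seq_len(n)])
    out$acceptanceRate <- nAcc / nCand
    out
}

#' Simulate an analysis-ready trio dataset
#'
#' Draws `n` ascertained trios from the generating model, recodes each
#' variant to its minor allele in the parental pool (ties at 0.5 keep the
#' original coding), computes sample MAFs from the parental haplotypes
#' (four independent haplotypes per family), flags variants that are
#' monomorphic in the sample, classifies common versus rare by sample MAF,
#' and assembles the pseudo-sibling contrast matrix.
#'
#' @param model a [TrioSimModel-class] object.
#' @param n number of trios.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @param mafThreshold rare/common classification cutoff on sample MAF.
#' @param minMAC variants whose minor-allele count in the parental
#'   haplotype pool is at most this value are excluded from the contrast
#'   object (they stay in the truth table, flagged).  The default 3 omits
#'   monomorphic sites, singletons, doubletons and tripletons, the usual
#'   exclusion for individual-variant analysis; 0 drops only monomorphic
#'   sites.
#' @param keepHaplotypes retain the raw haplotypes (needed by
#'   [writeTrioData()]).
#' @return list with `contrasts` (a [TrioContrasts-class]), `truth`
#'   (data.frame: id, position, region, weightedMAF, sampleMAF, effect,
#'   causal, polymorphic, isCommon, flipped), `haplotypes` (or `NULL`) and
#'   `acceptanceRate`.
#' @export
simulateTrios <- function(model, n, seed = 1L, mafThreshold = 0.05,
                          minMAC = 3L, keepHaplotypes = FALSE) {
    trios <- sampleCaseTrios(model, n, seed)
    v <- model@pool@variants
    p <- nrow(v)
    freq <- if (n > 0) (colSums(trios$mh1) + colSums(trios$mh2) +
             colSums(trios$fh1) + colSums(trios$fh2)) / (4 * n)
            else rep(0, p)
    flip <- freq > 0.5
    for (m in c("mh1", "mh2", "fh1", "fh2"))
        trios[[m]][, flip] <- 1L - trios[[m]][, flip]
    sampleMAF <- ifelse(flip, 1 - freq, freq)
    mT <- trios$mh1; mT[!trios$tm, ] <- trios$mh2[!trios$tm, ]
    mU <- trios$mh2; mU[!trios$tm, ] <- trios$mh1[!trios$tm, ]
    fT <- trios$fh1; fT[!trios$tf, ] <- trios$fh2[!trios$tf, ]
    fU <- trios$fh2; fU[!trios$tf, ] <- trios$fh1[!trios$tf, ]
    dM <- mT - mU
    dF <- fT - fU
    X <- matrix(0L, 3L * n, p)
    if (n > 0) {
        X[seq(1L, 3L * n, by = 3L), ] <- dM
        X[seq(2L, 3L * n, by = 3L), ] <- dF
        X[seq(3L, 3L * n, by = 3L), ] <- dM + dF
    }
    polymorphic <- sampleMAF > 0
    truth <- data.frame(id = v$id, position = v$position,
                        region = v$region, weightedMAF = v$maf,
                        sampleMAF = sampleMAF,
                        effect = unname(model@effects),
                        causal = model@effects != 0,
                        polymorphic = polymorphic,
                        isCommon = sampleMAF >= mafThreshold,
                        flipped = flip)
    keep <- if (n > 0) sampleMAF * 4 * n > minMAC else rep(TRUE, p)
    variants <- data.frame(id = v$id, position = v$position,
                           region = v$region, maf = sampleMAF,
                           isCommon = sampleMAF >= mafThreshold)[keep, ]
    contrasts <- TrioContrasts(X[, keep, drop = FALSE],
                               sprintf("fam%04d", seq_len(n)), variants)
    list(contrasts = contrasts, truth = truth,
         haplotypes = if (keepHaplotypes) trios else NULL,
         acceptanceRate = trios$acceptanceRate)
}
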