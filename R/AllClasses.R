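#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom vcfR vcfR
#' @useDynLib trioEMVS, .registration = TRUE
NULL

.variantCols <- c("id", "position", "region", "maf", "isCommon")

.checkVariantTable <- function(v) {
    if (!is.data.frame(v))
        return("'variants' must be a data.frame")
    miss <- setdiff(.variantCols, names(v))
    if (length(miss))
        return(paste0("variant table lacks column(s): ",
                      paste(miss, collapse = ", ")))
    if (any(v$maf < 0 | v$maf > 1))
        return("variant MAF outside [0, 1]")
    if (any(is.na(v$region)))
        return("every variant needs a region id")
    TRUE
}

#' Per-family pseudo-sibling contrasts for a set of trios
#'
#' Holds the case-minus-pseudo-sibling genotype differences that feed the
#' conditional logistic likelihood, three rows per family, together with the
#' variant annotation.  Columns are ordered with common variants first, then
#' rare variants grouped by region.
#'
#' @slot contrasts integer-valued matrix (3 rows per family, one column per
#'   variant) with entries in -2..2.
#' @slot familyID character vector of family identifiers, one per trio.
#' @slot variants data.frame with columns `id`, `position`, `region`, `maf`,
#'   `isCommon` aligned to the matrix columns.
#' @exportClass TrioContrasts
setClass("TrioContrasts",
    representation(contrasts = "matrix", familyID = "character",
                   variants = "data.frame"),
    validity = function(object) {
        v <- .checkVariantTable(object@variants)
        if (!isTRUE(v)) return(v)
        X <- object@contrasts
        if (nrow(X) != 3L * length(object@familyID))
            return("contrast matrix must have 3 rows per family")
        if (ncol(X) != nrow(object@variants))
            return("one contrast column per variant required")
        if (ncol(X) > 0 && nrow(X) > 0 &&
            (anyNA(X) || any(X < -2 | X > 2 | X != round(X))))
            return("contrast entries must be integers in -2..2")
        iv <- object@variants
        if (any(diff(c(rep(0L, sum(iv$isCommon)),
                       iv$region[!iv$isCommon])) < 0))
            return("rare variant columns must be grouped by ascending region")
        if (sum(iv$isCommon) > 0 &&
            any(which(iv$isCommon) > sum(iv$isCommon)))
            return("common variants must come before rare variants")
        TRUE
    })

#' Spike-and-slab prior specification
#'
#' Variance parameters of the normal spike/slab mixtures on the coefficients
#' (`v0`/`v1` for common variants, `v2`/`v3` for rare variants) and the
#' Beta(a, b) hyper-parameters of the three inclusion probabilities: common
#' variants, regions, and rare variants within a selected region.  `b` values
#' left as `NA` are filled at fit time with the counts S (common variants),
#' R (regions) and L (rare variants), which balances power against
#' multiplicity.
#'
#' @slot v0,v1 spike and slab variances for common-variant coefficients.
#' @slot v2,v3 spike and slab variances for rare-variant coefficients.
#' @slot a,b numeric(3) Beta hyper-parameters for (pi1, pi2, pi3).
#' @exportClass TrioPrior
setClass("TrioPrior",
    representation(v0 = "numeric", v1 = "numeric", v2 = "numeric",
                   v3 = "numeric", a = "numeric", b = "numeric"),
    validity = function(object) {
        for (s in c("v0", "v1", "v2", "v3")) {
            x <- slot(object, s)
            if (length(x) != 1L || !is.finite(x) || x <= 0)
                return(paste0("'", s, "' must be a positive scalar"))
        }
        if (object@v0 >= object@v1)
            return("need v0 < v1 (spike tighter than slab, common variants)")
        if (object@v2 >= object@v3)
            return("need v2 < v3 (spike tighter than slab, rare variants)")
        if (length(object@a) != 3L || any(object@a <= 0))
            return("'a' must be 3 positive values")
        if (length(object@b) != 3L || any(!is.na(object@b) & object@b <= 0))
            return("'b' must be 3 positive values (NA = set from data)")
        TRUE
    })

#' Converged DAEM fit
#'
#' Posterior-mode coefficients, inclusion probabilities and mixing weights
#' returned by [fitTrioEMVS()].
#'
#' @slot coef named coefficient vector at the posterior mode (length S + L).
#' @slot pS common-variant inclusion probabilities (length S).
#' @slot qRJ rare-variant inclusion probabilities given the region is in the
#'   model (length L).
#' @slot gR region inclusion probabilities (one per region with rare
#'   variants, named by region id).
#' @slot pi numeric(3): converged mixing weights (pi1, pi2, pi3).
#' @slot prior the completed [TrioPrior-class] used for the fit.
#' @slot variants variant annotation, as in the input [TrioContrasts-class].
#' @slot trace per-iteration data.frame (iteration, temperature, objective,
#'   pi1..pi3).
#' @slot converged logical; `FALSE` when the iteration cap was hit.
#' @slot iterations total EM iterations performed.
#' @exportClass TrioFit
setClass("TrioFit",
    representation(coef = "numeric", pS = "numeric", qRJ = "numeric",
                   gR = "numeric", pi = "numeric", prior = "TrioPrior",
                   variants = "data.frame", trace = "data.frame",
                   converged = "logical", iterations = "integer"))

#' Synthetic admixed haplotype pool
#'
#' Per-subpopulation allele frequencies for a panel of variants partitioned
#' into gene regions, with admixture weights.  The weighted minor allele
#' frequency of each variant is the admixture-weighted average of the
#' subpopulation frequencies, folded to be at most 0.5.
#'
#' @slot freqs matrix (subpopulations x variants) of allele frequencies.
#' @slot weights admixture proportions, summing to one.
#' @slot variants data.frame with `id`, `position`, `region`, `maf`
#'   (weighted MAF), `isCommon`.
#' @exportClass TrioPool
setClass("TrioPool",
    representation(freqs = "matrix", weights = "numeric",
                   variants = "data.frame"),
    validity = function(object) {
        v <- .checkVariantTable(object@variants)
        if (!isTRUE(v)) return(v)
        if (abs(sum(object@weights) - 1) > 1e-8)
            return("admixture weights must sum to 1")
        if (nrow(object@freqs) != length(object@weights))
            return("one frequency row per subpopulation required")
        if (ncol(object@freqs) != nrow(object@variants))
            return("one frequency column per variant required")
        if (any(object@freqs < 0 | object@freqs > 1))
            return("allele frequencies must lie in [0, 1]")
        TRUE
    })

#' Generating disease model for synthetic trios
#'
#' A [TrioPool-class] plus the logistic disease model used to ascertain
#' affected children: logit P(affected) = intercept + sum of causal genotype
#' effects.
#'
#' @slot pool the haplotype pool.
#' @slot intercept logistic intercept (controls disease prevalence).
#' @slot effects per-variant log-odds effects (0 for non-causal variants).
#' @exportClass TrioSimModel
setClass("TrioSimModel",
    representation(pool = "TrioPool", intercept = "numeric",
                   effects = "numeric"),
    validity = function(object) {
        if (length(object@effects) != nrow(object@pool@variants))
            return("one effect per pool variant required")
        if (!all(is.finite(object@effects)) ||
            !is.finite(object@intercept))
            return("effects and intercept must be finite")
        TRUE
    })

#' Regularization path over exclusion-variance candidates
#'
#' One converged fit per candidate value of the spike (exclusion) variance,
#' used by [stableWindow()] and [tunePriors()].
#'
#' @slot grid increasing candidate exclusion variances.
#' @slot stage `"joint"` (v0 = v2 moved together) or `"rare"` (v2 alone).
#' @slot fits list of [TrioFit-class], one per grid value.
#' @slot selected list of character vectors: selected variant ids per fit.
#' @slot ok logical; fits that completed without error.
#' @exportClass TrioRegPath
setClass("TrioRegPath",
    representation(grid = "numeric", stage = "character", fits = "list",
                   selected = "list", ok = "logical"),
    validity = function(object) {
        if (is.unsorted(object@grid, strictly = TRUE))
            return("grid values must be strictly increasing")
        if (length(object@fits) != length(object@grid) ||
            length(object@selected) != length(object@grid))
            return("one record per grid value required")
        TRUE
    })
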