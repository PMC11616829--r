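#' @include AllClasses.R
NULL

#' Prior specification constructor
#'
#' @param v0,v1 spike and slab variances for common variants (defaults
#'   0.003 and 0.4; `v0` is the tuning target of [tunePriors()], and its
#'   default is the central value of the default tuning grid).
#' @param v2,v3 spike and slab variances for rare variants (defaults 0.003
#'   and 0.5).  The slab defaults correspond to 95% prior coverage of
#'   odds ratios of roughly 0.29-3.45 (common) and 0.27-4.3 (rare).
#' @param a,b Beta hyper-parameters for the inclusion probabilities
#'   (pi1, pi2, pi3).  `b = NA` means "fill with the counts S, R, L at fit
#'   time", the multiplicity-balancing default.
#' @return A [TrioPrior-class] object.
#' @export
TrioPrior <- function(v0 = 0.003, v1 = 0.4, v2 = 0.003, v3 = 0.5,
                      a = c(1, 1, 1), b = c(NA, NA, NA)) {
    new("TrioPrior", v0 = v0, v1 = v1, v2 = v2, v3 = v3,
        a = as.numeric(a), b = as.numeric(b))
}

setMethod("show", "TrioPrior", function(object) {
    cat(sprintf("TrioPrior: v0=%g v1=%g (common), v2=%g v3=%g (rare)\n",
                object@v0, object@v1, object@v2, object@v3))
    b <- ifelse(is.na(object@b), "<count>", format(object@b))
    cat("  pi_i ~ Beta(a, b): a =", paste(format(object@a), collapse = ", "),
        "; b =", paste(b, collapse = ", "), "\n")
})

# fill NA Beta b-parameters with the data counts S, R, L
.completePrior <- function(prior, S, R, L) {
    b <- prior@b
    fill <- c(S, R, L)
    b[is.na(b)] <- fill[is.na(b)]
    b[b <= 0] <- 1
    initialize(prior, b = b)
}

.logNorm <- function(x, v) stats::dnorm(x, 0, sqrt(v), log = TRUE)

.logSumExp2 <- function(a, b) {
    m <- pmax(a, b)
    m + log(exp(a - m) + exp(b - m))
}

#' E-step inclusion probabilities
#'
#' Conditional expectations of the binary inclusion indicators given the
#' current coefficients and mixing weights, tempered by the annealing
#' exponent `t`.  All density ratios are formed in log space.
#'
#' `estepCommon` returns, per common variant, the posterior probability that
#' its indicator is 1: `a_s^t / (a_s^t + b_s^t)` with
#' `a_s = N(beta_s; 0, v1) pi1` and `b_s = N(beta_s; 0, v0) (1 - pi1)`.
#'
#' @param beta coefficients of the common variants.
#' @param pi1 current prior inclusion weight for common variants.
#' @param prior a [TrioPrior-class].
#' @param t annealing exponent in (0, 1]; `t = 1` is the plain EM E-step.
#' @return Probabilities in `[0, 1]`, one per coefficient (for
#'   `estepRegion`, one per region).
#' @export
estepCommon <- function(beta, pi1, prior, t = 1) {
    la <- .logNorm(beta, prior@v1) + log(pi1)
    lb <- .logNorm(beta, prior@v0) + log1p(-pi1)
    stats::plogis(t * (la - lb))
}

#' @rdname estepCommon
#' @param alpha coefficients of the rare variants (for `estepRare`); for
#'   `estepRegion`, the coefficients of the rare variants in one region.
#' @param pi3 current within-region inclusion weight for rare variants.
#' @details `estepRare` conditions on the region being in the model
#'   (region indicator = 1), as the within-region indicator is degenerate at
#'   zero otherwise.
#' @export
estepRare <- function(alpha, pi3, prior, t = 1) {
    lc <- .logNorm(alpha, prior@v3) + log(pi3)
    ld <- .logNorm(alpha, prior@v2) + log1p(-pi3)
    stats::plogis(t * (lc - ld))
}

#' @rdname estepCommon
#' @param pi2 current region inclusion weight.
#' @details `estepRegion` marginalises the within-region indicators: the
#'   region-in-model mass is `pi2 * prod_j [pi3 N(alpha_rj; 0, v3) +
#'   (1 - pi3) N(alpha_rj; 0, v2)]` against the region-out mass
#'   `(1 - pi2) * prod_j N(alpha_rj; 0, v2)`.
#' @export
estepRegion <- function(alpha, pi2, pi3, prior, t = 1) {
    lc <- .logNorm(alpha, prior@v3) + log(pi3)
    ld <- .logNorm(alpha, prior@v2) + log1p(-pi3)
    le <- log(pi2) + sum(.logSumExp2(lc, ld))
    lf <- log1p(-pi2) + sum(.logNorm(alpha, prior@v2))
    stats::plogis(t * (le - lf))
}

#' Diagonal M-step penalty from inclusion probabilities
#'
#' The quadratic penalty of the M-step objective has diagonal
#' `(1 - p_s)/v0 + p_s/v1` for common variants and
#' `(1 - q_rj)/v2 + q_rj/v3` for rare variants, hence is strictly positive
#' definite (every entry is at least `1/max(v1, v3)`).
#'
#' @param pS common-variant inclusion probabilities (length S).
#' @param qRJ rare-variant inclusion probabilities (length L).
#' @param prior a [TrioPrior-class].
#' @return Numeric vector of length S + L: the penalty diagonal.
#' @export
buildPenalty <- function(pS, qRJ, prior) {
    stopifnot(all(pS >= 0 & pS <= 1), all(qRJ >= 0 & qRJ <= 1))
    c((1 - pS) / prior@v0 + pS / prior@v1,
      (1 - qRJ) / prior@v2 + qRJ / prior@v3)
}

#' Closed-form updates of the mixing weights
#'
#' Maximises the pi-components of the Q function.  With the default
#' hyper-parameters (`a_i = 1`, `b1 = S`, `b2 = R`, `b3 = L`) the updates
#' reduce to
#' `pi1 = sum(p_s) / (2S - 1)`, `pi2 = sum(g_r) / (2R - 1)` and
#' `pi3 = sum_r g_r sum_j q_rj / (L + sum_r g_r J_r - 1)`; the generalised
#' Beta(a, b) forms are `(sum + a - 1) / (count + a + b - 2)`.
#'
#' @param pS,qRJ,gR E-step inclusion probabilities (`gR` one per region).
#' @param region region index (one entry per rare variant, aligned with
#'   `qRJ`), taking values in `names(gR)` order.
#' @param prior a completed [TrioPrior-class] (no `NA` in `b`).
#' @param pi current mixing weights, returned unchanged for components
#'   whose counts are zero or whose update is degenerate.
#' @return Numeric(3): updated (pi1, pi2, pi3).
#' @export
updatePis <- function(pS, qRJ, gR, region, prior, pi) {
    a <- prior@a; b <- prior@b
    S <- length(pS)
    R <- length(gR)
    L <- length(qRJ)
    out <- pi
    if (S > 0) {
        den <- S + a[1] + b[1] - 2
        if (den > 0) out[1] <- (sum(pS) + a[1] - 1) / den
    }
    if (R > 0) {
        den <- R + a[2] + b[2] - 2
        if (den > 0) out[2] <- (sum(gR) + a[2] - 1) / den
    }
    if (L > 0) {
        gPer <- gR[match(region, names(gR))]
        den <- sum(gPer) + a[3] + b[3] - 2
        if (den > 0) out[3] <- (sum(gPer * qRJ) + a[3] - 1) / den
    }
    out
}

#' Observed-data log-posterior (up to a constant)
#'
#' The selection indicators integrate out of the posterior in closed form,
#' giving
#' \deqn{l(\theta) = \ell(\omega) + \sum_s \log m_1(\beta_s)
#'   + \sum_r \log m_r(\alpha_r) + \sum_i \log \mathrm{Beta}(\pi_i; a_i, b_i)}
#' with \eqn{m_1} the two-component spike/slab mixture and \eqn{m_r} the
#' region-level mixture over the dual indicators.  Successive differences of
#' this quantity drive the convergence check, and at `t = 1` the EM updates
#' never decrease it.
#'
#' @param x a [TrioContrasts-class] object.
#' @param omega current coefficient vector (common first, then rare).
#' @param pi current mixing weights (pi1, pi2, pi3).
#' @param prior a completed [TrioPrior-class].
#' @return The log-posterior up to an additive constant.
#' @export
observedObjective <- function(x, omega, pi, prior) {
    v <- x@variants
    S <- sum(v$isCommon)
    L <- sum(!v$isCommon)
    ll <- conditionalLogLik(x, omega)
    lp <- 0
    if (S > 0) {
        beta <- omega[seq_len(S)]
        lp <- lp + sum(.logSumExp2(.logNorm(beta, prior@v1) + log(pi[1]),
                                   .logNorm(beta, prior@v0) + log1p(-pi[1])))
        lp <- lp + stats::dbeta(pi[1], prior@a[1], prior@b[1], log = TRUE)
    }
    if (L > 0) {
        alpha <- omega[S + seq_len(L)]
        region <- v$region[!v$isCommon]
        for (r in unique(region)) {
            ar <- alpha[region == r]
            lc <- .logNorm(ar, prior@v3) + log(pi[3])
            ld <- .logNorm(ar, prior@v2) + log1p(-pi[3])
            le <- log(pi[2]) + sum(.logSumExp2(lc, ld))
            lf <- log1p(-pi[2]) + sum(.logNorm(ar, prior@v2))
            lp <- lp + .logSumExp2(le, lf)
        }
        lp <- lp + stats::dbeta(pi[2], prior@a[2], prior@b[2], log = TRUE) +
            stats::dbeta(pi[3], prior@a[3], prior@b[3], log = TRUE)
    }
    ll + lp
}
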