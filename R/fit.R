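#' @include AllClasses.R estep.R
NULL

#' Penalized M-step for the coefficient vector
#'
#' Minimises the strongly convex objective
#' `sum_n log(1 + sum_i exp(-x_in omega)) + 0.5 * omega' diag(penalty) omega`
#' whose unique minimiser is the updated coefficient vector.  Two
#' independent routes are provided: a damped Newton solver (default,
#' deterministic) and a randomized coordinate-descent solver with exact
#' one-dimensional Newton steps (seeded, used as a cross-check).
#'
#' @param x a [TrioContrasts-class] object, or a bare contrast matrix.
#' @param penalty strictly positive penalty diagonal (see [buildPenalty()]).
#' @param init starting coefficient vector (default zero).
#' @param solver `"newton"` or `"cd"`.
#' @param tol relative gradient-norm tolerance.
#' @param maxIter iteration (or sweep) cap; exceeding it is an error.
#' @param seed RNG seed for the coordinate order of the `"cd"` solver.
#' @return Named numeric vector: the minimising coefficients, with
#'   attributes `value` (objective) and `gradNorm`.
#' @export
mstepCoefficients <- function(x, penalty, init = NULL,
                              solver = c("newton", "cd"), tol = 1e-8,
                              maxIter = 200L, seed = 1L) {
    solver <- match.arg(solver)
    X <- if (is(x, "TrioContrasts")) x@contrasts else as.matrix(x)
    storage.mode(X) <- "double"
    p <- ncol(X)
    stopifnot(length(penalty) == p, all(penalty > 0))
    if (is.null(init)) init <- rep(0, p)
    res <- if (solver == "newton")
        clogit_newton(X, penalty, as.numeric(init), tol, as.integer(maxIter))
    else
        clogit_cd(X, penalty, as.numeric(init), tol,
                  as.integer(max(maxIter, 2000L)), as.integer(seed))
    if (!isTRUE(res$converged))
        stop("M-step solver did not reach tolerance ", tol,
             " (final gradient norm ",
             format(if (is.null(res$gradNorm)) NA else res$gradNorm), ")")
    omega <- as.numeric(res$omega)
    names(omega) <- colnames(X)
    attr(omega, "value") <- res$value
    attr(omega, "gradNorm") <- res$gradNorm
    omega
}

.estepAll <- function(omega, S, L, region, regions, pi, prior, t) {
    pS <- if (S > 0) estepCommon(omega[seq_len(S)], pi[1], prior, t)
          else numeric(0)
    if (L > 0) {
        alpha <- omega[S + seq_len(L)]
        qRJ <- estepRare(alpha, pi[3], prior, t)
        gR <- vapply(regions, function(r)
            estepRegion(alpha[region == r], pi[2], pi[3], prior, t),
            numeric(1))
        names(gR) <- as.character(regions)
    } else {
        qRJ <- numeric(0)
        gR <- numeric(0)
    }
    list(pS = pS, qRJ = qRJ, gR = gR)
}

#' Fit the spike-and-slab trio model by deterministic-annealing EM
#'
#' Runs the EM algorithm on the conditional logistic trio likelihood with
#' spike-and-slab priors, treating the selection indicators as missing
#' data.  Every coefficient starts at 0.5, deep inside the slab, so the
#' first E-step places each variant in the model and the first M-step is a
#' lightly penalized fit; variants whose likelihood information cannot hold
#' their coefficients against the spike are then pruned over the EM
#' iterations.  Iterations continue until the change in the observed-data
#' log-posterior drops below `epsilon`.
#'
#' A deterministic-annealing schedule is available through `anneal`: the
#' E-step probabilities are tempered by `t` along the schedule (one EM
#' sweep per temperature, e.g. `seq(0.1, 1, 0.1)`), after which plain EM
#' iterations at t = 1 run to convergence.  It defaults to off: on panels
#' with tens of rare variants per region the tempered sweeps keep the
#' rare-variant penalty high for long enough that even strongly supported
#' rare coefficients are shrunk away before their evidence can accumulate,
#' and the rare-variant side of the model collapses to the degenerate
#' empty mode (see the package vignette).
#'
#' @param x a [TrioContrasts-class] object.
#' @param prior a [TrioPrior-class]; `NA` Beta b-parameters are filled with
#'   the counts S, R, L.
#' @param anneal optional non-decreasing temperature schedule in (0, 1];
#'   each value below 1 gets one tempered EM sweep before the t = 1
#'   iterations.  `numeric(0)` (default) disables annealing.
#' @param epsilon convergence threshold on the objective difference.
#' @param maxIter cap on EM iterations at t = 1.
#' @param initCoef starting value for every coefficient (default 0.5) or a
#'   full-length vector.
#' @param initPi starting mixing weights; default is the prior means
#'   `a / (a + b)`.
#' @param solver,solverTol,seed passed to [mstepCoefficients()].
#' @param penaltyExpectation how the rare-coefficient penalty weights the
#'   slab: `"joint"` (default) uses the joint inclusion expectation
#'   `g_r * q_rj` from the complete-data Q function, so a closed region
#'   gate keeps its members shrunk; `"conditional"` uses `q_rj` alone
#'   (conditional on the region being in the model).
#' @param verbose print per-iteration progress.
#' @return A [TrioFit-class] object; `converged(fit)` is `FALSE` if the
#'   iteration cap was hit.
#' @export
fitTrioEMVS <- function(x, prior = TrioPrior(),
                        anneal = numeric(0), epsilon = 1e-4,
                        maxIter = 500L, initCoef = 0.5, initPi = NULL,
                        solver = "newton", solverTol = 1e-8, seed = 1L,
                        penaltyExpectation = c("joint", "conditional"),
                        verbose = FALSE) {
    penaltyExpectation <- match.arg(penaltyExpectation)
    stopifnot(is(x, "TrioContrasts"), epsilon > 0)
    v <- x@variants
    S <- sum(v$isCommon)
    L <- sum(!v$isCommon)
    p <- S + L
    region <- v$region[!v$isCommon]
    regions <- unique(region)
    R <- length(regions)
    prior <- .completePrior(prior, S, R, L)
    omega <- if (length(initCoef) == 1L) rep(initCoef, p)
             else as.numeric(initCoef)
    stopifnot(length(omega) == p)
    pi <- if (is.null(initPi)) prior@a / (prior@a + prior@b)
          else as.numeric(initPi)

    sched <- anneal[anneal < 1]
    if (length(anneal) && is.unsorted(anneal))
        stop("annealing schedule must be non-decreasing")
    trace <- list()
    k <- 0L
    es <- NULL
    emStep <- function(t) {
        es <<- .estepAll(omega, S, L, region, regions, pi, prior, t)
        qPen <- es$qRJ
        if (penaltyExpectation == "joint" && L > 0)
            qPen <- es$gR[match(region, names(es$gR))] * es$qRJ
        pen <- buildPenalty(es$pS, qPen, prior)
        omega <<- mstepCoefficients(x, pen, init = omega, solver = solver,
                                    tol = solverTol, seed = seed + k)
        pi <<- updatePis(es$pS, es$qRJ, es$gR, region, prior, pi)
        k <<- k + 1L
        obj <- observedObjective(x, omega, pi, prior)
        trace[[k]] <<- data.frame(iteration = k, temperature = t,
                                  objective = obj, pi1 = pi[1],
                                  pi2 = pi[2], pi3 = pi[3])
        if (verbose)
            message(sprintf("iter %3d  t=%.2f  obj=%.6f  pi=(%.3g, %.3g, %.3g)",
                            k, t, obj, pi[1], pi[2], pi[3]))
        obj
    }
    for (t in sched) emStep(t)
    obj <- emStep(1)
    converged <- FALSE
    for (i in seq_len(maxIter - 1L)) {
        objNew <- emStep(1)
        if (abs(objNew - obj) < epsilon) { converged <- TRUE; obj <- objNew; break }
        obj <- objNew
    }
    # final E-step at the converged parameters, at t = 1
    es <- .estepAll(omega, S, L, region, regions, pi, prior, 1)
    names(omega) <- v$id
    if (S > 0) names(es$pS) <- v$id[v$isCommon]
    if (L > 0) names(es$qRJ) <- v$id[!v$isCommon]
    new("TrioFit", coef = omega, pS = es$pS, qRJ = es$qRJ, gR = es$gR,
        pi = pi, prior = prior, variants = v,
        trace = do.call(rbind, trace), converged = converged,
        iterations = k)
}

setMethod("show", "TrioFit", function(object) {
    v <- object@variants
    sel <- selectVariants(object)
    cat("TrioFit:", sum(v$isCommon), "common +", sum(!v$isCommon),
        "rare variants;", object@iterations, "EM iterations",
        if (object@converged) "(converged)\n" else "(NOT converged)\n")
    cat("  pi = (", paste(signif(object@pi, 3), collapse = ", "), ")\n")
    cat("  selected:", sum(sel$selected), "variant(s)\n")
})

#' @rdname TrioFit
#' @param object,fit a `TrioFit` object.
#' @export
setMethod("coef", "TrioFit", function(object) object@coef)

#' @rdname TrioFit
#' @export
setMethod("inclusionProbs", "TrioFit", function(fit)
    list(pS = fit@pS, qRJ = fit@qRJ, gR = fit@gR))

#' Final selection of variants and regions
#'
#' A common variant is selected when its inclusion probability reaches the
#' threshold; a rare variant when the joint probability that both its
#' region and the variant itself are in the model (`g_r * q_rj`) reaches
#' it, so an excluded region suppresses its members.  A region is selected
#' when its own probability reaches the threshold or any member variant is
#' selected.
#'
#' @param fit a [TrioFit-class] object.
#' @param threshold posterior probability cutoff, default 0.5 (the
#'   posterior-mode rule).
#' @return `selectVariants`: data.frame with one row per variant (id,
#'   region, maf, class, coefficient, inclusion probability, selected).
#'   `selectedRegions`: data.frame with one row per region carrying rare
#'   variants (region, gR, selected).
#' @export
setMethod("selectVariants", "TrioFit", function(fit, threshold = 0.5) {
    v <- fit@variants
    prob <- numeric(nrow(v))
    prob[v$isCommon] <- fit@pS
    if (length(fit@qRJ)) {
        region <- v$region[!v$isCommon]
        gPer <- fit@gR[match(as.character(region), names(fit@gR))]
        prob[!v$isCommon] <- gPer * fit@qRJ
    }
    data.frame(id = v$id, region = v$region, maf = v$maf,
               class = ifelse(v$isCommon, "common", "rare"),
               coefficient = unname(fit@coef),
               inclusionProb = prob,
               selected = prob >= threshold)
})

#' @rdname selectVariants
#' @export
setMethod("selectedRegions", "TrioFit", function(fit, threshold = 0.5) {
    sel <- selectVariants(fit, threshold)
    regions <- sort(unique(fit@variants$region))
    gR <- fit@gR[match(as.character(regions), names(fit@gR))]
    gR[is.na(gR)] <- 0
    memberHit <- vapply(regions, function(r)
        any(sel$selected[sel$region == r]), logical(1))
    data.frame(region = regions, gR = unname(gR),
               selected = unname(gR) >= threshold | memberHit)
})
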