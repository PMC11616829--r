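# Direct marginalization oracle for the observed-data log posterior on a
# toy problem: enumerate every indicator configuration.
enumObjective <- function(x, omega, pi, prior) {
    v <- variantInfo(x)
    S <- sum(v$isCommon); L <- sum(!v$isCommon)
    beta <- omega[seq_len(S)]
    alpha <- omega[S + seq_len(L)]
    region <- v$region[!v$isCommon]
    ll <- conditionalLogLik(x, omega)
    margCommon <- sum(vapply(beta, function(b)
        log(pi[1] * dnorm(b, 0, sqrt(prior@v1)) +
            (1 - pi[1]) * dnorm(b, 0, sqrt(prior@v0))), numeric(1)))
    margRare <- 0
    for (r in unique(region)) {
        ar <- alpha[region == r]
        J <- length(ar)
        tot <- 0
        for (eta in 0:1) for (k in seq_len(2^J) - 1L) {
            lam <- as.integer(intToBits(k)[seq_len(J)])
            if (eta == 0 && any(lam == 1)) next
            pr <- if (eta == 1) pi[2] else 1 - pi[2]
            if (eta == 1) pr <- pr * prod(ifelse(lam == 1, pi[3], 1 - pi[3]))
            vv <- ifelse(eta == 1 & lam == 1, prior@v3, prior@v2)
            tot <- tot + pr * prod(dnorm(ar, 0, sqrt(vv)))
        }
        margRare <- margRare + log(tot)
    }
    ll + margCommon + dbeta(pi[1], prior@a[1], prior@b[1], log = TRUE) +
        margRare + dbeta(pi[2], prior@a[2], prior@b[2], log = TRUE) +
        dbeta(pi[3], prior@a[3], prior@b[3], log = TRUE)
}

test_that("the observed objective equals direct indicator marginalization", {
    x <- randomContrasts(15, 1, 4, seed = 71, nRegions = 2)
    prior <- trioEMVS:::.completePrior(TrioPrior(), 1, 2, 4)
    set.seed(72)
    for (rep in 1:5) {
        omega <- rnorm(5, sd = 0.5)
        pi <- runif(3, 0.05, 0.95)
        expect_equal(observedObjective(x, omega, pi, prior),
                     enumObjective(x, omega, pi, prior),
                     tolerance = 1e-10)
    }
})

test_that("EM iterations never decrease the observed objective at t = 1", {
    for (s in 1:20) {
        x <- randomContrasts(25, 2, 4, seed = 400 + s)
        fit <- fitTrioEMVS(x, epsilon = 1e-6)
        obj <- fit@trace$objective[fit@trace$temperature == 1]
        expect_true(all(diff(obj) >= -1e-9))
    }
})

test_that("an uninformative dataset selects nothing and zeroes the coefficients", {
    x <- toyContrasts(matrix(0L, 30, 4), 2, 2)
    fit <- fitTrioEMVS(x)
    expect_true(all(abs(coef(fit)) < 1e-6))
    expect_false(any(selectVariants(fit)$selected))
})

test_that("duplicating every family leaves the selection unchanged", {
    model <- smallModel()
    sim <- simulateTrios(model, 400, seed = 81)
    x <- sim$contrasts
    X2 <- rbind(contrastMatrix(x), contrastMatrix(x))
    x2 <- TrioContrasts(X2, c(familyIDs(x), paste0(familyIDs(x), "b")),
                        variantInfo(x))
    s1 <- selectVariants(fitTrioEMVS(x))
    s2 <- selectVariants(fitTrioEMVS(x2))
    # doubled evidence cannot drop a selected variant, and the causal
    # commons are selected identically
    expect_true(all(s1$id[s1$selected] %in% s2$id[s2$selected]))
    commons <- causalCommonIds(model)
    expect_equal(s1$selected[s1$id %in% commons],
                 s2$selected[s2$id %in% commons])
})

test_that("selection rules follow the posterior-mode threshold", {
    v <- toyVariants(2, 2, nRegions = 1)
    mk <- function(pS, qRJ, gR)
        new("TrioFit", coef = c(b1 = 0.8, b2 = 0, a1 = 0.4, a2 = 0),
            pS = pS, qRJ = qRJ, gR = gR, pi = c(0.1, 0.1, 0.1),
            prior = trioEMVS:::.completePrior(TrioPrior(), 2, 1, 2),
            variants = v, trace = data.frame(), converged = TRUE,
            iterations = 5L)
    fit <- mk(c(0.9, 0.1), c(1, 0.2), c(`1` = 0.4))
    sel <- selectVariants(fit)
    expect_equal(sel$selected, c(TRUE, FALSE, FALSE, FALSE))  # 0.4 * 1 < 0.5
    expect_equal(sum(selectVariants(fit, threshold = 0)$selected), 4L)
    expect_equal(sum(selectVariants(fit, threshold = 1)$selected), 0L)
    # monotone in the threshold
    k <- vapply(c(0, 0.3, 0.6, 1),
                function(th) sum(selectVariants(fit, th)$selected),
                numeric(1))
    expect_true(all(diff(k) <= 0))
    # a region is selected through its own probability or any member
    fit2 <- mk(c(0.9, 0.1), c(1, 0.2), c(`1` = 0.6))
    sr <- selectedRegions(fit2)
    expect_true(sr$selected[sr$region == 1])
})

test_that("selection is invariant to permuting variants", {
    model <- smallModel()
    sim <- simulateTrios(model, 350, seed = 91)
    x <- sim$contrasts
    set.seed(92)
    perm <- sample(ncol(contrastMatrix(x)))
    xp <- TrioContrasts(contrastMatrix(x)[, perm], familyIDs(x),
                        variantInfo(x)[perm, ])
    s1 <- selectVariants(fitTrioEMVS(x))
    s2 <- selectVariants(fitTrioEMVS(xp))
    expect_setequal(s1$id[s1$selected], s2$id[s2$selected])
})

test_that("a single strong common variant is recovered with its sign", {
    pool <- buildPool(seed = 3)
    model <- assignEffects(pool, commonEffects = 0.9, commonRegions = 3L,
                           rareCausalPerRegion = integer(0), seed = 3)
    target <- causalCommonIds(model)
    hits <- 0L
    for (s in 1:20) {
        sim <- simulateTrios(model, 500, seed = 500 + s)
        fit <- fitTrioEMVS(sim$contrasts)
        ip <- inclusionProbs(fit)
        if (ip$pS[target] > 0.5 && coef(fit)[target] > 0) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})

test_that("the iteration cap returns a flagged, unconverged state", {
    x <- randomContrasts(30, 2, 4, seed = 101)
    fit <- fitTrioEMVS(x, maxIter = 2L, epsilon = 1e-12)
    expect_false(fit@converged)
    expect_equal(fit@iterations, 2L)
})
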