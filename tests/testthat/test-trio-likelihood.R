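test_that("pseudo-sibling enumeration yields the three alternative transmissions", {
    # four distinguishable haplotypes over 4 sites
    A <- c(1L, 0L, 0L, 0L); B <- c(0L, 1L, 0L, 0L)
    C <- c(0L, 0L, 1L, 0L); D <- c(0L, 0L, 0L, 1L)
    trio <- enumeratePseudoSiblings(mother = list(h1 = A, h2 = B),
                                    father = list(h1 = C, h2 = D),
                                    child = list(h1 = A, h2 = C))
    expect_equal(trio$case, A + C)
    got <- lapply(seq_len(3), function(i) trio$pseudo[i, ])
    want <- list(B + C, A + D, B + D)
    for (w in want)
        expect_true(any(vapply(got, identical, logical(1), as.integer(w))))
    expect_equal(nrow(trio$pseudo), 3L)
})

test_that("homozygous parents give four identical configurations", {
    h <- c(1L, 1L, 0L)
    trio <- enumeratePseudoSiblings(list(h1 = h, h2 = h), list(h1 = h, h2 = h),
                                    list(h1 = h, h2 = h))
    for (i in 1:3) expect_equal(trio$pseudo[i, ], trio$case)
})

test_that("the configuration multiset ignores which parental haplotype is labeled transmitted", {
    set.seed(42)
    for (rep in 1:5) {
        p <- 6L
        hap <- function() as.integer(runif(p) < 0.4)
        m <- list(h1 = hap(), h2 = hap()); f <- list(h1 = hap(), h2 = hap())
        t1 <- enumeratePseudoSiblings(m, f, list(h1 = m$h1, h2 = f$h2))
        # relabel: swap the mother's haplotype order, child unchanged
        t2 <- enumeratePseudoSiblings(list(h1 = m$h2, h2 = m$h1), f,
                                      list(h1 = m$h1, h2 = f$h2))
        ms <- function(tr) sort(apply(rbind(tr$case, tr$pseudo), 1L,
                                      paste, collapse = ""))
        expect_equal(ms(t1), ms(t2))
    }
})

test_that("Mendelian inconsistency is rejected with a variant-level diagnostic", {
    z <- c(0L, 0L); o <- c(1L, 1L)
    expect_error(
        enumeratePseudoSiblings(list(h1 = z, h2 = z), list(h1 = z, h2 = z),
                                list(h1 = c(1L, 0L), h2 = z)),
        "maternal.*variant index 1")
})

test_that("contrast construction subtracts pseudo-siblings and flags monomorphic sites", {
    fam <- list(case = c(2L, 0L),
                pseudo = rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L)))
    x <- buildContrasts(list(fam), toyVariants(2, 0))
    expect_equal(unname(contrastMatrix(x)[1, ]), c(1, -1))
    expect_true(all(contrastMatrix(x) >= -2 & contrastMatrix(x) <= 2))
    # uninformative family: all-zero rows retained
    quiet <- list(case = c(0L, 1L), pseudo = rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L)))
    x2 <- buildContrasts(list(quiet), toyVariants(2, 0))
    expect_equal(unname(contrastMatrix(x2)), matrix(0, 3, 2))
    expect_equal(variantInfo(x2)$monomorphic, c(TRUE, FALSE))
    # genotype length mismatch names the family
    bad <- list(case = c(1L, 0L, 0L), pseudo = rbind(0L, 0L, 0L))
    expect_error(buildContrasts(list(bad), toyVariants(2, 0),
                                familyID = "famX"), "famX")
})

test_that("random trio sets produce bounded contrasts", {
    x <- randomContrasts(30, 2, 4, seed = 5)
    X <- contrastMatrix(x)
    expect_true(all(X %in% -2:2))
    expect_equal(nrow(X), 90L)
})

test_that("conditional log-likelihood matches closed forms", {
    x <- randomContrasts(25, 2, 4, seed = 9)
    p <- nrow(variantInfo(x))
    # omega = 0: each family is uniform over its 4 configurations
    expect_equal(conditionalLogLik(x, rep(0, p)), -25 * log(4))
    expect_lte(conditionalLogLik(x, rnorm(p)), 0)
    # all four configurations identical: -N log 4 for any omega
    xz <- toyContrasts(matrix(0L, 9, 2), 2, 0)
    expect_equal(conditionalLogLik(xz, c(1.3, -0.2)), -3 * log(4))
    # one family, all three contrasts equal 1, omega = log 3:
    # -log(1 + 3 exp(-log 3)) = -log 2
    x1 <- toyContrasts(matrix(1L, 3, 1), 1, 0)
    expect_equal(conditionalLogLik(x1, log(3)), -log(2))
    expect_error(conditionalLogLik(x1, Inf), "finite")
    expect_error(conditionalLogLik(x1, c(1, 2)), "one entry per variant")
})

test_that("likelihood is invariant to pseudo-sibling order and zero-contrast columns", {
    x <- randomContrasts(20, 1, 3, seed = 11)
    X <- contrastMatrix(x)
    omega <- rnorm(4, sd = 0.4)
    ll <- conditionalLogLik(x, omega)
    # permute the 3 rows within each family
    Xp <- X
    for (n in seq_len(20)) Xp[(3 * n - 2):(3 * n), ] <- X[3 * n - c(0, 2, 1), ]
    xp <- toyContrasts(Xp, 1, 3)
    expect_equal(conditionalLogLik(xp, omega), ll)
    # append an all-zero column: likelihood unchanged for any coefficient
    vi <- variantInfo(x)[c("id", "position", "region", "maf", "isCommon")]
    xa <- TrioContrasts(cbind(X, 0L), familyIDs(x),
                        rbind(vi, data.frame(id = "z", position = 99L,
                                             region = 2L, maf = 0.01,
                                             isCommon = FALSE)))
    expect_equal(conditionalLogLik(xa, c(omega, 5)), ll)
})

test_that("analytic likelihood gradient matches central finite differences", {
    x <- randomContrasts(15, 2, 4, seed = 13)
    X <- contrastMatrix(x)
    storage.mode(X) <- "double"
    p <- ncol(X)
    omega <- rnorm(p, sd = 0.3)
    g <- trioEMVS:::clogit_eval(X, rep(0, p), omega)$gradient
    h <- 1e-5
    for (j in seq_len(p)) {
        e <- rep(0, p); e[j] <- h
        fd <- (conditionalLogLik(x, omega + e) -
               conditionalLogLik(x, omega - e)) / (2 * h)
        # clogit_eval returns the gradient of the negative log-likelihood
        expect_equal(-g[j], fd, tolerance = 1e-6)
    }
})

test_that("variant classification splits on the MAF threshold", {
    expect_equal(classifyVariants(c(0.3, 0.04, 0.05)), c(TRUE, FALSE, TRUE))
    expect_equal(sum(!classifyVariants(rep(0.06, 4))), 0L)
    # replicate matrices are classified on the per-variant median
    m <- rbind(c(0.04, 0.2), c(0.06, 0.2), c(0.055, 0.2))
    expect_equal(classifyVariants(m), c(TRUE, TRUE))
    expect_error(classifyVariants(0.1, threshold = 0), "threshold > 0")
})
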