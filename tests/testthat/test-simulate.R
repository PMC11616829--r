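test_that("weighted MAF averages subpopulation frequencies and folds", {
    expect_equal(weightedMAF(0.3, 1), 0.3)
    expect_equal(weightedMAF(c(0.1, 0.02), c(0.25, 0.75)), 0.04)
    expect_equal(weightedMAF(0.9, 1), 0.1)
    m <- rbind(c(0.1, 0.9), c(0.02, 0.9))
    expect_equal(weightedMAF(m, c(0.25, 0.75)), c(0.04, 0.1))
})

test_that("the pool realizes its configured spectrum", {
    pool <- buildPool(seed = 11)
    v <- pool@variants
    expect_equal(nrow(v), 12L * 10L)
    expect_equal(as.vector(table(v$region)), rep(10L, 12L))
    # subpopulation frequencies reproduce the weighted MAF
    wm <- weightedMAF(pool@freqs, pool@weights)
    expect_equal(wm, v$maf, tolerance = 1e-8)
    # rare sites respect their bins, plus one sentinel at 0.026
    rare <- v$maf[!v$isCommon & !v$sentinel]
    expect_true(all(rare >= 1e-4 & rare < 0.04))
    expect_equal(v$maf[v$sentinel], 0.026)
    expect_equal(v$region[v$sentinel], 1L)
    # positions stay inside their regions
    expect_true(all(v$position > (v$region - 1) * 2700 &
                    v$position <= v$region * 2700))
    expect_error(buildPool(admixWeights = c(0.5, 0.4)), "sum to 1")
})

test_that("effect sizes follow the MAF-magnitude rule with balanced signs", {
    model <- smallModel()
    v <- model@pool@variants
    eff <- model@effects
    rare <- which(eff != 0 & !v$isCommon)
    expect_equal(unname(abs(eff[rare])), 0.4 * abs(log10(v$maf[rare])),
                 tolerance = 1e-12)
    # direct evaluations of the magnitude rule
    expect_equal(0.4 * abs(log10(0.01)), 0.8)
    expect_equal(0.4 * abs(log10(0.026)), 0.634, tolerance = 1e-3)
    # rarer variants act more strongly
    ord <- order(v$maf[rare])
    expect_true(all(diff(abs(eff[rare])[ord]) <= 1e-12))
    # signs split evenly outside the always-positive sentinel
    signs <- sign(eff[setdiff(rare, which(v$sentinel))])
    expect_lte(abs(sum(signs)), 1)
    expect_gt(eff[v$sentinel], 0)
    # the two common causal variants sit in regions 3 and 6
    commons <- which(eff != 0 & v$isCommon)
    expect_equal(sort(v$region[commons]), c(3L, 6L))
    expect_setequal(eff[commons], c(0.9, -0.9))
})

test_that("null-model ascertainment accepts at the closed-form logistic rate", {
    model <- nullModel()
    n <- 1000L
    trios <- sampleCaseTrios(model, n, seed = 31)
    pAcc <- plogis(-2.2)
    nCand <- round(n / trios$acceptanceRate)
    se <- sqrt(pAcc * (1 - pAcc) / nCand)
    expect_lt(abs(trios$acceptanceRate - pAcc), 3 * se)
})

test_that("transmissions are fair coin flips under the null", {
    model <- nullModel()
    trios <- sampleCaseTrios(model, 2500, seed = 37)
    k <- sum(trios$tm) + sum(trios$tf)
    expect_gt(binom.test(k, 5000)$p.value, 0.001)
})

test_that("a risk allele is over-transmitted to affected children", {
    pool <- buildPool(seed = 5)
    model <- assignEffects(pool, commonEffects = 0.9, commonRegions = 3L,
                           rareCausalPerRegion = integer(0), seed = 5)
    cv <- which(model@effects != 0)
    trios <- sampleCaseTrios(model, 2000, seed = 41)
    mT <- ifelse(trios$tm, trios$mh1[, cv], trios$mh2[, cv])
    mU <- ifelse(trios$tm, trios$mh2[, cv], trios$mh1[, cv])
    fT <- ifelse(trios$tf, trios$fh1[, cv], trios$fh2[, cv])
    fU <- ifelse(trios$tf, trios$fh2[, cv], trios$fh1[, cv])
    b <- sum(mT == 1 & mU == 0) + sum(fT == 1 & fU == 0)
    cc <- sum(mT == 0 & mU == 1) + sum(fT == 0 & fU == 1)
    expect_gt(b / (b + cc), 0.55)
})

test_that("the TDT statistic is calibrated under the null", {
    # no causal effects: each common variant's transmission-disequilibrium
    # statistic is asymptotically chi-square(1); variants are independent
    model <- nullModel()
    rejections <- 0L; tests <- 0L
    for (s in 1:4) {
        trios <- sampleCaseTrios(model, 400, seed = 600 + s)
        commons <- which(model@pool@variants$isCommon)
        for (cv in commons) {
            het <- function(hT, hU) cbind(hT[, cv], hU[, cv])
            m <- rbind(het(trios$mh1, trios$mh2)[trios$tm, , drop = FALSE],
                       het(trios$mh2, trios$mh1)[!trios$tm, , drop = FALSE],
                       het(trios$fh1, trios$fh2)[trios$tf, , drop = FALSE],
                       het(trios$fh2, trios$fh1)[!trios$tf, , drop = FALSE])
            b <- sum(m[, 1] == 1 & m[, 2] == 0)
            cc <- sum(m[, 1] == 0 & m[, 2] == 1)
            if (b + cc == 0) next
            stat <- (b - cc)^2 / (b + cc)
            tests <- tests + 1L
            if (stat > qchisq(0.95, 1)) rejections <- rejections + 1L
        }
    }
    expect_gt(binom.test(rejections, tests, p = 0.05)$p.value, 0.001)
})

test_that("simulated datasets are reproducible and Mendelian-consistent", {
    model <- smallModel()
    a <- simulateTrios(model, 40, seed = 51, keepHaplotypes = TRUE)
    b <- simulateTrios(model, 40, seed = 51, keepHaplotypes = TRUE)
    expect_identical(contrastMatrix(a$contrasts), contrastMatrix(b$contrasts))
    expect_identical(a$truth, b$truth)
    c2 <- simulateTrios(model, 40, seed = 52)
    expect_false(identical(contrastMatrix(a$contrasts),
                           contrastMatrix(c2$contrasts)))
    # every contrast row is reachable by some transmission: entries bounded
    expect_true(all(contrastMatrix(a$contrasts) %in% -2:2))
})

test_that("rare sites drop out of small samples", {
    model <- smallModel()
    sim <- simulateTrios(model, 350, seed = 61)
    expect_lt(sum(sim$truth$polymorphic), nrow(sim$truth))
    expect_gt(sum(sim$truth$polymorphic), 0)
    # the analyzed panel excludes sites at or below the MAC cutoff
    expect_true(all(variantInfo(sim$contrasts)$maf * 4 * 350 > 3))
    # truth and analyzed panel agree on the sample MAFs
    v <- variantInfo(sim$contrasts)
    expect_equal(v$maf,
                 sim$truth$sampleMAF[match(v$id, sim$truth$id)])
})

test_that("an empty dataset is valid", {
    model <- smallModel()
    sim <- simulateTrios(model, 0, seed = 1)
    expect_equal(nFamilies(sim$contrasts), 0L)
    expect_equal(nrow(contrastMatrix(sim$contrasts)), 0L)
    expect_equal(nrow(sim$truth), nrow(model@pool@variants))
})
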