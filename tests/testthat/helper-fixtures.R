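# Shared in-code fixtures: no files, everything built at test time.

# Variant annotation for p variants split into commons first, then rares
# grouped into regions of equal size.
toyVariants <- function(nCommon, nRare, nRegions = max(1L, nRare %/% 2L)) {
    p <- nCommon + nRare
    region <- c(rep(1L, nCommon),
                if (nRare) sort(rep_len(seq_len(nRegions), nRare)) else integer(0))
    data.frame(id = sprintf("v%02d", seq_len(p)), position = seq_len(p),
               region = region,
               maf = c(rep(0.3, nCommon), rep(0.01, nRare)),
               isCommon = rep(c(TRUE, FALSE), c(nCommon, nRare)))
}

# TrioContrasts straight from a bare contrast matrix
toyContrasts <- function(X, nCommon, nRare, nRegions = max(1L, nRare %/% 2L)) {
    TrioContrasts(X, sprintf("f%03d", seq_len(nrow(X) / 3L)),
                  toyVariants(nCommon, nRare, nRegions))
}

# Random Mendelian-consistent trio set and its contrast object
randomContrasts <- function(nFam, nCommon, nRare, seed,
                            nRegions = max(1L, nRare %/% 2L),
                            freq = NULL) {
    set.seed(seed)
    p <- nCommon + nRare
    if (is.null(freq)) freq <- c(rep(0.3, nCommon), rep(0.08, nRare))
    fams <- lapply(seq_len(nFam), function(i) {
        hap <- function() as.integer(runif(p) < freq)
        mother <- list(h1 = hap(), h2 = hap())
        father <- list(h1 = hap(), h2 = hap())
        child <- list(h1 = if (runif(1) < 0.5) mother$h1 else mother$h2,
                      h2 = if (runif(1) < 0.5) father$h1 else father$h2)
        enumeratePseudoSiblings(mother, father, child)
    })
    buildContrasts(fams, toyVariants(nCommon, nRare, nRegions))
}

# Small simulation model shared by the heavier statistical tests
smallModel <- function(seed = 7) {
    pool <- buildPool(seed = seed)
    assignEffects(pool, seed = seed)
}

nullModel <- function(seed = 7) {
    pool <- buildPool(seed = seed)
    assignEffects(pool, commonEffects = numeric(0),
                  commonRegions = integer(0),
                  rareCausalPerRegion = integer(0), seed = seed)
}

sentinelId <- function(model) {
    v <- model@pool@variants
    v$id[v$sentinel]
}

causalCommonIds <- function(model) {
    v <- model@pool@variants
    v$id[model@effects != 0 & v$isCommon]
}

# Independent evaluation of the penalized M-step objective (used as an
# oracle against the compiled solvers)
refObjective <- function(X, pen, omega) {
    s <- X %*% omega
    val <- 0
    for (n in seq_len(nrow(X) / 3L)) {
        z <- -s[(3 * n - 2):(3 * n)]
        m <- max(0, z)
        val <- val + m + log(exp(-m) + sum(exp(z - m)))
    }
    val + 0.5 * sum(pen * omega^2)
}

# Independent oracle: enumerate the joint distribution of the dual
# indicators (eta, lambda_1..lambda_J) for one region given fixed alpha and
# mixing weights, and read off the conditional expectations.
enumRegion <- function(alpha, pi2, pi3, v2, v3) {
    J <- length(alpha)
    configs <- expand.grid(c(list(eta = 0:1),
                             rep(list(0:1), J)))
    w <- apply(configs, 1L, function(cf) {
        eta <- cf[1]; lam <- cf[-1]
        pr <- if (eta == 1) pi2 else 1 - pi2
        for (j in seq_len(J)) {
            pr <- pr * if (eta == 1) {
                if (lam[j] == 1) pi3 else 1 - pi3
            } else {
                if (lam[j] == 1) 0 else 1   # point mass at zero
            }
            vj <- if (eta == 1 && lam[j] == 1) v3 else v2
            pr <- pr * dnorm(alpha[j], 0, sqrt(vj))
        }
        pr
    })
    w <- w / sum(w)
    eta <- configs[, 1]
    list(g = sum(w[eta == 1]),
         q = vapply(seq_len(J), function(j)
             sum(w[eta == 1 & configs[, j + 1] == 1]) / sum(w[eta == 1]),
             numeric(1)),
         gq = vapply(seq_len(J), function(j)
             sum(w[eta == 1 & configs[, j + 1] == 1]), numeric(1)))
}

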