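#' @include fit.R
NULL

#' Default candidate grid for the exclusion variances
#'
#' Log-spaced values spanning negligible to appreciable prior standard
#' deviation below the slab variances.
#'
#' @return Increasing numeric vector of candidate spike variances.
#' @export
defaultTuningGrid <- function() c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 3e-2, 1e-1)

#' Regularization path over exclusion-variance candidates
#'
#' Refits the model at each candidate spike variance and records the
#' converged coefficients and selected set, producing the regularization
#' plot data used to choose the exclusion parameters.  In stage `"joint"`
#' the common and rare spikes move together (`v0 = v2 = value`); in stage
#' `"rare"` only `v2` moves while `v0` stays at its value in
#' `prior`.
#'
#' @param x a [TrioContrasts-class] object.
#' @param prior template [TrioPrior-class]; its slab variances are held
#'   fixed along the path.
#' @param grid strictly increasing candidate values, all below
#'   `min(v1, v3)`.
#' @param stage `"joint"` or `"rare"`.
#' @param threshold selection threshold used for the recorded sets.
#' @param warmStart start each fit from the previous grid point's solution
#'   instead of refitting cold.  Defaults to `FALSE`: cold fits make the
#'   path points directly comparable (a warm start can drag one grid
#'   point's mode into the next); warm starts are faster.
#' @param ... further arguments to [fitTrioEMVS()].
#' @return A [TrioRegPath-class] object.  Failed fits are recorded
#'   (`ok = FALSE`) and the path continues.
#' @export
regularizationPath <- function(x, prior = TrioPrior(),
                               grid = defaultTuningGrid(),
                               stage = c("joint", "rare"), threshold = 0.5,
                               warmStart = FALSE, ...) {
    stage <- match.arg(stage)
    stopifnot(!is.unsorted(grid, strictly = TRUE),
              all(grid < min(prior@v1, prior@v3)))
    fits <- vector("list", length(grid))
    selected <- vector("list", length(grid))
    ok <- logical(length(grid))
    dots <- list(...)
    state <- NULL
    for (i in seq_along(grid)) {
        pr <- if (stage == "joint")
            initialize(prior, v0 = grid[i], v2 = grid[i])
        else initialize(prior, v2 = grid[i])
        args <- c(list(x = x, prior = pr), dots)
        if (warmStart && !is.null(state)) {
            args$initCoef <- state$coef
            args$initPi <- state$pi
            args$anneal <- numeric(0)
        }
        fit <- tryCatch(do.call(fitTrioEMVS, args), error = function(e) e)
        if (inherits(fit, "error")) {
            warning("fit failed at grid value ", grid[i], ": ",
                    conditionMessage(fit))
            selected[[i]] <- NA_character_
        } else {
            ok[i] <- TRUE
            fits[[i]] <- fit
            sel <- selectVariants(fit, threshold)
            selected[[i]] <- sel$id[sel$selected]
            if (warmStart)
                state <- list(coef = unname(fit@coef), pi = fit@pi)
        }
    }
    new("TrioRegPath", grid = grid, stage = stage, fits = fits,
        selected = selected, ok = ok)
}

setMethod("show", "TrioRegPath", function(object) {
    cat("TrioRegPath (stage ", object@stage, "): ",
        length(object@grid), " grid values\n", sep = "")
    for (i in seq_along(object@grid))
        cat(sprintf("  %-8g %s\n", object@grid[i],
                    if (!object@ok[i]) "<failed>"
                    else paste(object@selected[[i]], collapse = ", ")))
})

#' Export a regularization path as a plotting table
#'
#' @param path a [TrioRegPath-class] object.
#' @return data.frame (gridValue, id, coefficient, inclusionProb, selected)
#'   suitable for drawing a regularization plot.
#' @export
pathTable <- function(path) {
    out <- lapply(seq_along(path@grid), function(i) {
        if (!path@ok[i]) return(NULL)
        sel <- selectVariants(path@fits[[i]])
        data.frame(gridValue = path@grid[i], id = sel$id,
                   coefficient = sel$coefficient,
                   inclusionProb = sel$inclusionProb,
                   selected = sel$selected)
    })
    do.call(rbind, out)
}

#' Choose an exclusion variance from a stable window
#'
#' Scans the path for runs of consecutive grid values whose selected sets
#' are identical and whose selected coefficients change by less than
#' `relTol` between neighbours ("no shrinkage").  Returns the smallest grid
#' value inside the first run of length at least `minLen`; if none exists,
#' the first value of the longest run is returned with a `stable = FALSE`
#' flag and a warning (ties between equally long runs go to the run at
#' larger grid values, i.e. the more regularized side, since vanishingly
#' small exclusion variances admit saturated solutions that are trivially
#' stable).
#'
#' @param path a [TrioRegPath-class] object.
#' @param minLen minimum run length for a stable window (default 3).
#' @param relTol relative coefficient-change tolerance between adjacent
#'   grid points (default 0.1).
#' @param scope which variants the stability judgement looks at: the whole
#'   selected set, or only its common or rare part.  [tunePriors()] judges
#'   the common-exclusion stage on common variants and the rare-exclusion
#'   stage on rare variants, so each stage's choice reflects the
#'   coefficients it governs.
#' @return list with `value` (chosen grid value), `index`, `runLength` and
#'   `stable`.
#' @export
stableWindow <- function(path, minLen = 3L, relTol = 0.1,
                         scope = c("all", "common", "rare")) {
    scope <- match.arg(scope)
    n <- length(path@grid)
    if (n == 0L) stop("empty regularization path")
    if (n == 1L) {
        if (!path@ok[1]) stop("the only path fit failed")
        return(list(value = path@grid[1], index = 1L, runLength = 1L,
                    stable = minLen <= 1L))
    }
    inScope <- function(i, ids) {
        if (scope == "all" || !length(ids)) return(ids)
        v <- path@fits[[i]]@variants
        common <- ids %in% v$id[v$isCommon]
        ids[if (scope == "common") common else !common]
    }
    same <- logical(n - 1L)  # same[i]: points i and i+1 agree
    for (i in seq_len(n - 1L)) {
        if (!path@ok[i] || !path@ok[i + 1L]) next
        s1 <- inScope(i, path@selected[[i]])
        s2 <- inScope(i + 1L, path@selected[[i + 1L]])
        if (!setequal(s1, s2)) next
        if (length(s1)) {
            c1 <- coef(path@fits[[i]])[s1]
            c2 <- coef(path@fits[[i + 1L]])[s1]
            rel <- abs(c2 - c1) / pmax(abs(c1), 1e-8)
            if (any(rel >= relTol)) next
        }
        same[i] <- TRUE
    }
    # run-lengths of agreeing stretches; ties go to the later run
    best <- list(start = 0L, len = 0L)
    first <- NULL
    i <- 1L
    while (i <= n) {
        j <- i
        while (j < n && same[j]) j <- j + 1L
        len <- j - i + 1L
        if (path@ok[i] && len >= best$len) best <- list(start = i, len = len)
        if (is.null(first) && path@ok[i] && len >= minLen)
            first <- list(start = i, len = len)
        i <- j + 1L
    }
    if (!is.null(first))
        return(list(value = path@grid[first$start], index = first$start,
                    runLength = first$len, stable = TRUE))
    if (best$len == 0L) stop("no successful fit in the path")
    warning("no stable window of length >= ", minLen,
            "; falling back to the longest run")
    list(value = path@grid[best$start], index = best$start,
        runLength = best$len, stable = FALSE)
}

#' Two-stage tuning of the exclusion variances
#'
#' Stage 1 moves the common and rare exclusion variances together
#' (`v0 = v2`) along `grid1` and fixes `v0` where the selected set of
#' common variants is stable.  Stage 2 holds `v0` fixed, re-tunes `v2`
#' along `grid2`, and judges stability on the selected rare variants.
#' When the dataset has no rare variants, stage 2 is skipped and
#' `v2 = v0`.
#'
#' @param x a [TrioContrasts-class] object.
#' @param prior template [TrioPrior-class] (slabs held fixed).
#' @param grid1,grid2 candidate grids for the two stages.  The stage-1
#'   grid stops at 0.01 by default: beyond that the common "exclusion"
#'   scale (prior SD 0.1 on a log odds ratio) is no longer small relative
#'   to the slab, and a window there reflects overshrinkage of the
#'   individually well-informed common variants rather than stability.
#' @param minLen,relTol stable-window parameters (see [stableWindow()]).
#' @param ... further arguments to [fitTrioEMVS()].
#' @return list with `prior` (the completed [TrioPrior-class]), `v0`, `v2`,
#'   the two paths (`path1`, `path2`; the latter `NULL` when skipped) and
#'   the window diagnostics.
#' @export
tunePriors <- function(x, prior = TrioPrior(),
                       grid1 = defaultTuningGrid()[1:5],
                       grid2 = defaultTuningGrid(), minLen = 3L,
                       relTol = 0.1, ...) {
    path1 <- regularizationPath(x, prior, grid1, stage = "joint", ...)
    w1 <- stableWindow(path1, minLen, relTol, scope = "common")
    prior1 <- initialize(prior, v0 = w1$value, v2 = w1$value)
    if (sum(!x@variants$isCommon) == 0L)
        return(list(prior = prior1, v0 = w1$value, v2 = w1$value,
                    path1 = path1, path2 = NULL, window1 = w1,
                    window2 = NULL))
    path2 <- regularizationPath(x, prior1, grid2, stage = "rare", ...)
    w2 <- stableWindow(path2, minLen, relTol, scope = "rare")
    list(prior = initialize(prior1, v2 = w2$value), v0 = w1$value,
         v2 = w2$value, path1 = path1, path2 = path2, window1 = w1,
         window2 = w2)
}
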