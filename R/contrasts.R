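#' Construct a TrioContrasts object
#'
#' Assembles the per-family contrast rows (case genotype minus each
#' pseudo-sibling genotype) into the container used by [fitTrioEMVS()].
#' Columns are reordered so that common variants come first, followed by
#' rare variants grouped by region (ascending region id, then position).
#'
#' @param contrasts numeric matrix with three rows per family and one column
#'   per variant; entries must be integers in -2..2.
#' @param familyID character vector of family identifiers (one per trio).
#' @param variants data.frame with columns `id`, `position`, `region`,
#'   `maf`, `isCommon` describing the matrix columns.
#' @return A [TrioContrasts-class] object.
#' @export
TrioContrasts <- function(contrasts, familyID, variants) {
    contrasts <- as.matrix(contrasts)
    storage.mode(contrasts) <- "integer"
    chk <- .checkVariantTable(variants)
    if (!isTRUE(chk)) stop(chk)
    if (ncol(contrasts) != nrow(variants))
        stop("one contrast column per variant required")
    ord <- order(!variants$isCommon,
                 ifelse(variants$isCommon, 0L, variants$region),
                 variants$position)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    contrasts <- contrasts[, ord, drop = FALSE]
    colnames(contrasts) <- variants$id
    new("TrioContrasts", contrasts = contrasts,
        familyID = as.character(familyID), variants = variants)
}

#' @rdname TrioContrasts
#' @param x a `TrioContrasts` object.
#' @export
setMethod("contrastMatrix", "TrioContrasts", function(x) x@contrasts)

#' @rdname TrioContrasts
#' @export
setMethod("variantInfo", "TrioContrasts", function(x) x@variants)

#' @rdname TrioContrasts
#' @export
setMethod("familyIDs", "TrioContrasts", function(x) x@familyID)

#' @rdname TrioContrasts
#' @export
setMethod("nFamilies", "TrioContrasts", function(x) length(x@familyID))

setMethod("show", "TrioContrasts", function(object) {
    v <- object@variants
    cat("TrioContrasts:", length(object@familyID), "families,",
        nrow(v), "variants (", sum(v$isCommon), "common,",
        sum(!v$isCommon), "rare in", length(unique(v$region[!v$isCommon])),
        "regions )\n")
})

#' Enumerate the pseudo-siblings of a phased trio
#'
#' Given the phased haplotype pairs of mother, father and affected child,
#' returns the child's additive genotype together with the three alternative
#' transmissions (the pseudo-siblings): untransmitted-maternal with
#' transmitted-paternal, transmitted-maternal with untransmitted-paternal,
#' and both untransmitted.  Each haplotype is a 0/1 allele vector; genotypes
#' are sums of two haplotypes.
#'
#' @param mother,father,child lists with components `h1` and `h2` (0/1
#'   vectors of equal length).  For the child, `h1` is the maternally and
#'   `h2` the paternally inherited haplotype.
#' @return list with `case` (integer genotype vector) and `pseudo` (3 x p
#'   integer matrix, one pseudo-sibling per row).
#' @export
enumeratePseudoSiblings <- function(mother, father, child) {
    p <- length(child$h1)
    stopifnot(length(child$h2) == p, length(mother$h1) == p,
              length(mother$h2) == p, length(father$h1) == p,
              length(father$h2) == p)
    mIdx <- .matchHaplotype(child$h1, mother, "maternal")
    fIdx <- .matchHaplotype(child$h2, father, "paternal")
    mT <- if (mIdx == 1L) mother$h1 else mother$h2
    mU <- if (mIdx == 1L) mother$h2 else mother$h1
    fT <- if (fIdx == 1L) father$h1 else father$h2
    fU <- if (fIdx == 1L) father$h2 else father$h1
    case <- as.integer(mT + fT)
    pseudo <- rbind(as.integer(mU + fT),
                    as.integer(mT + fU),
                    as.integer(mU + fU))
    list(case = case, pseudo = pseudo)
}

.matchHaplotype <- function(hap, parent, side) {
    if (all(hap == parent$h1)) return(1L)
    if (all(hap == parent$h2)) return(2L)
    bad <- which(hap != parent$h1 & hap != parent$h2)
    stop("Mendelian inconsistency on the ", side, " side at variant index",
         if (length(bad) > 1) "es " else " ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
}

#' Build the contrast matrix for a set of trios
#'
#' Stacks, for every family, the three difference vectors between the case
#' genotype and each pseudo-sibling genotype.  Variants that carry no minor
#' allele anywhere (all genotypes zero, hence all contrasts zero) are
#' flagged as monomorphic in the returned annotation.
#'
#' @param families list of trios as returned by
#'   [enumeratePseudoSiblings()], each with `case` and `pseudo`.
#' @param variants variant annotation data.frame (see [TrioContrasts()]).
#' @param familyID optional family identifiers; defaults to `fam1..famN`.
#' @return A [TrioContrasts-class] object; the annotation gains a
#'   `monomorphic` column.
#' @export
buildContrasts <- function(families, variants, familyID = NULL) {
    if (is.null(familyID)) familyID <- paste0("fam", seq_along(families))
    p <- nrow(variants)
    rows <- vector("list", length(families))
    anyAllele <- rep(FALSE, p)
    for (k in seq_along(families)) {
        f <- families[[k]]
        if (length(f$case) != p || ncol(f$pseudo) != p)
            stop("genotype length mismatch in family ", familyID[k])
        rows[[k]] <- matrix(rep(f$case, each = 3L) - f$pseudo, nrow = 3L)
        anyAllele <- anyAllele | f$case > 0L | colSums(f$pseudo) > 0L
    }
    X <- do.call(rbind, rows)
    variants$monomorphic <- !anyAllele
    TrioContrasts(X, familyID, variants)
}

#' Conditional logistic log-likelihood of trio contrasts
#'
#' Evaluates the 1:3 matched-set conditional likelihood
#' \deqn{\sum_n \log \frac{e^{g_{0n}\omega}}{\sum_{i=0}^{3} e^{g_{in}\omega}}
#'   = -\sum_n \log\big(1 + \sum_{i=1}^{3} e^{-x_{in}\omega}\big)}
#' where \eqn{x_{in}} are the case-minus-pseudo-sibling contrasts.  Computed
#' with a log-sum-exp guard so the value is finite for any finite
#' coefficient vector.
#'
#' @param x a [TrioContrasts-class] object.
#' @param omega coefficient vector of length equal to the variant count.
#' @return The log-likelihood (always at most 0; equal to `-N log 4` at
#'   `omega = 0`).
#' @export
conditionalLogLik <- function(x, omega) {
    X <- x@contrasts
    if (length(omega) != ncol(X))
        stop("omega must have one entry per variant")
    if (!all(is.finite(omega)))
        stop("omega entries must be finite")
    -clogit_value(X, rep(0, ncol(X)), as.numeric(omega))
}

#' Classify variants as common or rare by minor allele frequency
#'
#' A variant is rare when its MAF is strictly below the threshold, common
#' otherwise.  When a matrix of per-replicate MAFs is supplied the
#' per-variant median across replicates is classified, which stabilises the
#' split across replicate datasets.
#'
#' @param maf numeric vector of per-variant MAFs, or a matrix with one row
#'   per replicate and one column per variant.
#' @param threshold MAF threshold in (0, 1); default 0.05.
#' @return Logical vector: `TRUE` for common variants.
#' @export
classifyVariants <- function(maf, threshold = 0.05) {
    stopifnot(threshold > 0, threshold < 1)
    if (is.matrix(maf))
        maf <- apply(maf, 2L, stats::median)
    maf >= threshold
}
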