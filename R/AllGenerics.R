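#' @rdname TrioContrasts
#' @export
setGeneric("contrastMatrix", function(x) standardGeneric("contrastMatrix"))

#' @rdname TrioContrasts
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname TrioContrasts
#' @export
setGeneric("familyIDs", function(x) standardGeneric("familyIDs"))

#' @rdname TrioContrasts
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname selectVariants
#' @export
setGeneric("selectVariants",
    function(fit, threshold = 0.5) standardGeneric("selectVariants"))

#' @rdname selectVariants
#' @export
setGeneric("selectedRegions",
    function(fit, threshold = 0.5) standardGeneric("selectedRegions"))

#' @rdname TrioFit
#' @export
setGeneric("inclusionProbs", function(fit) standardGeneric("inclusionProbs"))
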