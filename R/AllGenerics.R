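#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @export
setGeneric("spectraLabels", function(x) standardGeneric("spectraLabels"))

#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @export
setGeneric("injectedOutlier", function(x) standardGeneric("injectedOutlier"))

#' @export
setGeneric("lowerBound", function(x) standardGeneric("lowerBound"))

#' @export
setGeneric("upperBound", function(x) standardGeneric("upperBound"))

#' @export
setGeneric("propVariance", function(x) standardGeneric("propVariance"))

#' @export
setGeneric("selectComponents",
           function(x, rule = c("fixed", "cumulative"), m = 4L,
                    threshold = 0.95)
             standardGeneric("selectComponents"))

#' @export
setGeneric("projectSpectra",
           function(object, x, m = NULL) standardGeneric("projectSpectra"))
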