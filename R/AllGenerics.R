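#' Accessors for intensity and beta assays
#'
#' \code{methylated} and \code{unmethylated} return the two intensity
#' matrices of a \linkS4class{MethylIntensitySet}; \code{betas} returns the
#' beta matrix of a \linkS4class{BetaSet}.
#'
#' @param object a MethylIntensitySet or BetaSet.
#' @return A numeric matrix (probes x samples).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("methylated", function(object) standardGeneric("methylated"))

#' @rdname accessors
#' @export
setGeneric("unmethylated", function(object) standardGeneric("unmethylated"))

#' @rdname accessors
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))

#' @rdname accessors
setMethod("methylated", "MethylIntensitySet", function(object)
    assay(object, "methylated"))

#' @rdname accessors
setMethod("unmethylated", "MethylIntensitySet", function(object)
    assay(object, "unmethylated"))

#' @rdname accessors
setMethod("betas", "BetaSet", function(object) assay(object, "beta"))

#' Apply a preprocessing method
#'
#' @param object data to preprocess (a \linkS4class{MethylIntensitySet}).
#' @param method method name from \code{\link{normMethods}}.
#' @param ... passed to methods.
#' @export
setGeneric("applyMethod", function(object, method, ...)
    standardGeneric("applyMethod"))
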