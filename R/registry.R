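## The preprocessing method registry.  Each method is a design point on two
## axes: background adjustment between assay types (none / peak-equalized /
## peak-equalized with Sentrix-position smoothing) and between-array
## quantile normalization mode.  Dye-bias removal is a consequence of the
## "MU together" QN modes, which normalize methylated against unmethylated
## intensities.

.QN_MODES <- c("none", "MU_separate_types_together",
               "MU_separate_types_separate", "MU_together_types_together",
               "MU_together_types_separate", "beta_qn")

.METHOD_TABLE <- data.frame(
    name = c("raw", "betaqn", "naten", "nanet", "nanes", "danes",
             "danet", "danen", "daten1", "daten2", "nasen", "dasen"),
    background = c("none", "none", "none", "none", "none", "equalize",
                   "equalize", "equalize", "equalize", "equalize_smoothed",
                   "none", "equalize"),
    qn = c("none", "beta_qn", "MU_separate_types_together",
           "MU_together_types_together", "MU_together_types_separate",
           "MU_together_types_separate", "MU_together_types_together",
           "none", "MU_separate_types_together",
           "MU_separate_types_together", "MU_separate_types_separate",
           "MU_separate_types_separate"),
    stringsAsFactors = FALSE)

#' Names of the available preprocessing methods
#'
#' The twelve in-package methods: \code{raw} (betas from raw intensities),
#' \code{betaqn} (quantile normalization of betas), the \code{na..}
#' family (no background adjustment) and the \code{da..} family (Type I/II
#' background equalization), crossed with the QN modes: \code{..ten}
#' (methylated and unmethylated normalized separately, assay types
#' together), \code{..sen} (separately by assay type too — four strata),
#' \code{..net} (M and U normalized against each other, types together),
#' \code{..nes} (M against U, types separate).  \code{daten1} uses
#' per-sample background offsets, \code{daten2} Sentrix-position-smoothed
#' offsets; otherwise they share their axes.
#'
#' @return Character vector of method names.
#' @export
normMethods <- function() .METHOD_TABLE$name

#' Look up a preprocessing method specification
#'
#' @param name one of \code{\link{normMethods}()}.
#' @param alpha beta offset in fluorescence units (default 100).
#' @return A list with components \code{name}, \code{background}
#'   (none/equalize/equalize_smoothed), \code{qn} (QN mode) and
#'   \code{alpha}.
#' @export
methodSpec <- function(name, alpha = 100) {
    i <- match(name, .METHOD_TABLE$name)
    if (is.na(i))
        stop("unknown method '", name, "'; valid methods are: ",
             paste(.METHOD_TABLE$name, collapse = ", "))
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
    list(name = name, background = .METHOD_TABLE$background[i],
         qn = .METHOD_TABLE$qn[i], alpha = alpha)
}

#' @describeIn applyMethod Preprocess a MethylIntensitySet with a named
#'   method and return a \linkS4class{BetaSet}.
#'
#' @param alpha beta offset (default 100), applied when betas are computed
#'   from the (possibly normalized) intensities.
#' @param offsets optional precomputed background offsets (from
#'   \code{\link{estimateBackgroundOffsets}}); estimated on the fly when
#'   needed and not supplied.
#'
#' @details The pipeline is: (1) if the method calls for background
#' adjustment, estimate Type I/II offsets (Sentrix-smoothed for
#' \code{daten2}) and add them to Type I intensities; (2) apply the
#' between-array QN mode — M and U matrices separately or joined
#' column-wise, rows as a single stratum or stratified by assay type;
#' \code{betaqn} instead computes raw betas and quantile normalizes those;
#' (3) compute betas with offset \code{alpha}.
#' @export
setMethod("applyMethod", "MethylIntensitySet",
          function(object, method, alpha = 100, offsets = NULL, ...) {
    spec <- methodSpec(method, alpha = alpha)
    if (spec$qn != "none" && ncol(object) < 2L)
        stop("method '", method, "' requires >= 2 samples")
    x <- object
    if (spec$background != "none") {
        if (is.null(offsets))
            offsets <- estimateBackgroundOffsets(
                x, smoothByPosition = spec$background == "equalize_smoothed")
        x <- equalizeBackground(x, offsets)
    }
    if (spec$qn == "beta_qn") {
        b <- quantileNormalize(.beta_values(methylated(x), unmethylated(x),
                                            spec$alpha))
        b[b < 0] <- 0
        b[b > 1] <- 1
        return(BetaSet(b, rowData = rowData(object),
                       colData = colData(object), method = method))
    }
    if (spec$qn != "none") {
        groups <- if (grepl("types_separate$", spec$qn))
            rowData(x)$AssayType else NULL
        m <- methylated(x)
        u <- unmethylated(x)
        if (grepl("^MU_together", spec$qn)) {
            qn <- quantileNormalizeGrouped(m, rowGroups = groups, join = u)
            m <- qn$x
            u <- qn$join
        } else {
            m <- quantileNormalizeGrouped(m, rowGroups = groups)
            u <- quantileNormalizeGrouped(u, rowGroups = groups)
        }
        m[m < 0] <- 0
        u[u < 0] <- 0
        b <- .beta_values(m, u, spec$alpha)
    } else {
        b <- .beta_values(methylated(x), unmethylated(x), spec$alpha)
    }
    BetaSet(b, rowData = rowData(object), colData = colData(object),
            method = method)
})

#' Run several preprocessing methods
#'
#' @param object a \linkS4class{MethylIntensitySet}.
#' @param methods character vector of method names (default: all twelve).
#' @param alpha beta offset.
#' @return Named list of \linkS4class{BetaSet} objects.  Background offsets
#'   (per-sample and, when chip positions are available, smoothed) are
#'   estimated once and shared across the methods that need them.
#' @export
applyMethods <- function(object, methods = normMethods(), alpha = 100) {
    bad <- setdiff(methods, normMethods())
    if (length(bad))
        stop("unknown method(s): ", paste(bad, collapse = ", "),
             "; valid methods are: ", paste(normMethods(), collapse = ", "))
    specs <- lapply(methods, methodSpec)
    off_raw <- off_smooth <- NULL
    if (any(vapply(specs, `[[`, "", "background") == "equalize"))
        off_raw <- estimateBackgroundOffsets(object)
    if (any(vapply(specs, `[[`, "", "background") == "equalize_smoothed"))
        off_smooth <- estimateBackgroundOffsets(object, smoothByPosition = TRUE)
    out <- lapply(specs, function(sp) {
        off <- switch(sp$background, equalize = off_raw,
                      equalize_smoothed = off_smooth, NULL)
        applyMethod(object, sp$name, alpha = alpha, offsets = off)
    })
    names(out) <- methods
    out
}
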