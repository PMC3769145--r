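#' Compute beta values from intensities
#'
#' The methylation fraction index \eqn{\beta = M / (M + U + \alpha)}, where
#' M and U are methylated and unmethylated signal intensities and
#' \eqn{\alpha \ge 0} is an offset (conventionally 100) stabilising
#' \eqn{\beta} at low total intensity.  With \eqn{\alpha > 0} and
#' \eqn{M, U \ge 0} every value lies in [0, 1]; M = U = 0 gives 0.
#'
#' @param object a \linkS4class{MethylIntensitySet}, or a numeric matrix of
#'   methylated intensities (then \code{unmeth} is required).
#' @param alpha non-negative offset, default 100 fluorescence units.
#' @param unmeth unmethylated matrix when \code{object} is a matrix.
#' @return A \linkS4class{BetaSet} (or plain matrix for matrix input).
#' @examples
#' computeBeta(matrix(900), alpha = 100, unmeth = matrix(0))   # 0.9
#' @export
computeBeta <- function(object, alpha = 100, unmeth = NULL) {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
    if (is(object, "MethylIntensitySet")) {
        b <- .beta_values(methylated(object), unmethylated(object), alpha)
        return(BetaSet(b, rowData = rowData(object), colData = colData(object),
                       method = "raw"))
    }
    if (is.null(unmeth))
        stop("matrix input requires 'unmeth'")
    .beta_values(as.matrix(object), as.matrix(unmeth), alpha)
}

.beta_values <- function(m, u, alpha) {
    denom <- m + u + alpha
    if (alpha == 0 && any(denom == 0)) {
        idx <- which(denom == 0, arr.ind = TRUE)[1, ]
        stop("undefined beta (M = U = 0 with alpha = 0) at probe '",
             rownames(m)[idx[1]] %||% idx[1], "', sample '",
             colnames(m)[idx[2]] %||% idx[2], "'")
    }
    b <- m / denom
    b[denom == 0] <- 0  # unreachable when alpha > 0
    b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert beta values to M-values
#'
#' The logit-like transform \eqn{M = \log_2(\beta / (1 - \beta))};
#' unbounded, zero at \eqn{\beta = 0.5}.
#'
#' @param beta numeric vector/matrix with values strictly inside (0, 1).
#' @return M-values of the same shape.
#' @export
beta2m <- function(beta) {
    if (any(beta <= 0 | beta >= 1))
        stop("beta2m requires values strictly inside (0, 1)")
    log2(beta / (1 - beta))
}

#' Convert M-values to beta values
#'
#' Inverse of \code{\link{beta2m}}: \eqn{\beta = 2^M / (2^M + 1)}.
#'
#' @param m numeric vector/matrix of M-values.
#' @return beta values in (0, 1).
#' @export
m2beta <- function(m) 2^m / (2^m + 1)

#' M-values directly from intensities
#'
#' \eqn{M_{val} = \log_2((M + \alpha) / (U + \alpha))} with
#' \eqn{\alpha > 0} guarding the ratio at zero intensity.
#'
#' @param meth,unmeth non-negative intensities (vectors or matrices).
#' @param alpha positive offset, default 100.
#' @return M-values of the common shape.
#' @export
intensityToM <- function(meth, unmeth, alpha = 100) {
    stopifnot(alpha > 0)
    log2((meth + alpha) / (unmeth + alpha))
}
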