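#' Quantile normalization of a features-by-samples matrix
#'
#' Forces every column onto the common target distribution formed by the
#' row means of the column-sorted matrix: each value is replaced by the
#' mean of the values of the same rank across arrays.  Within-column rank
#' order is preserved and all columns end up with identical sorted values.
#' Ties within a column receive the mean of the target values at the tied
#' ranks.
#'
#' @param x numeric matrix, features in rows, >= 2 sample columns, all
#'   entries finite.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2L)
        stop("quantile normalization needs >= 2 columns, got ", ncol(x))
    if (any(!is.finite(x)))
        stop("quantile normalization requires finite values")
    target <- rowMeans(apply(x, 2L, sort.int, method = "quick"))
    out <- x
    for (j in seq_len(ncol(x))) {
        col <- x[, j]
        v <- numeric(length(col))
        v[order(col)] <- target
        # tied input values share the mean of the targets at their ranks
        if (anyDuplicated(col))
            v <- stats::ave(v, match(col, col), FUN = mean)
        out[, j] <- v
    }
    out
}

#' Grouped / joined quantile normalization
#'
#' The workhorse behind the between-array normalization modes: quantile
#' normalization applied independently within row groups (e.g. Infinium
#' Type I vs Type II probes), optionally with a second matrix of identical
#' shape joined column-wise first (methylated and unmethylated intensities
#' normalized against each other, which removes dye-bias variation) and
#' split back afterwards.
#'
#' @param x numeric matrix (features x samples).
#' @param rowGroups vector of length \code{nrow(x)} labelling each row's
#'   group, or NULL for a single group.
#' @param join optional matrix of identical shape and dimnames whose
#'   columns are concatenated with \code{x} before normalization.
#' @return If \code{join} is NULL, a matrix like \code{x}; otherwise a list
#'   with elements \code{x} and \code{join}, both normalized.
#' @export
quantileNormalizeGrouped <- function(x, rowGroups = NULL, join = NULL) {
    x <- as.matrix(x)
    if (!is.null(join)) {
        join <- as.matrix(join)
        if (!identical(dim(x), dim(join)))
            stop("'join' must match the shape of 'x'")
        if (!is.null(rownames(x)) && !is.null(rownames(join)) &&
            !identical(rownames(x), rownames(join)))
            stop("'join' must have the same row labels as 'x'")
    }
    if (is.null(rowGroups)) rowGroups <- rep(1L, nrow(x))
    if (length(rowGroups) != nrow(x))
        stop("rowGroups must label every row")
    outx <- x
    outj <- join
    for (g in unique(rowGroups)) {
        idx <- which(rowGroups == g)
        if (length(idx) < 2L) {
            warning("row group '", g, "' has a single row; left unchanged")
            next
        }
        if (is.null(join)) {
            outx[idx, ] <- quantileNormalize(x[idx, , drop = FALSE])
        } else {
            both <- cbind(x[idx, , drop = FALSE], join[idx, , drop = FALSE])
            qn <- quantileNormalize(both)
            n <- ncol(x)
            outx[idx, ] <- qn[, seq_len(n), drop = FALSE]
            outj[idx, ] <- qn[, n + seq_len(n), drop = FALSE]
        }
    }
    if (is.null(join)) outx else list(x = outx, join = outj)
}
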