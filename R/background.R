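## Type I vs Type II background equalization.
##
## Raw methylated and unmethylated intensities both show a characteristic
## peak close to zero whose position differs between the two Infinium assay
## chemistries (the Type II background sits higher, which compresses Type II
## beta values toward 0.5).  We locate that peak per sample and channel with
## a kernel density estimate and shift the Type I intensities by the
## difference, equalizing the background without trying to remove it.

.CHANNELS <- c("methylated", "unmethylated")

#' Estimate per-sample Type I/II background offsets
#'
#' For each sample and channel (methylated, unmethylated), a Gaussian kernel
#' density (Silverman bandwidth) of the Type I and of the Type II
#' intensities is evaluated on a fixed grid of \code{gridSize} points
#' spanning [0, max intensity]; the background peak is the highest density
#' mode among grid points below the channel's median intensity, and the
#' offset is peak(Type II) - peak(Type I).  With
#' \code{smoothByPosition = TRUE} the per-sample offsets are replaced by
#' fitted values of a per-channel least-squares model offset ~ chip row
#' (vertical Sentrix position), which yields smooth offsets when the
#' background shows a positional gradient.
#'
#' @param object a \linkS4class{MethylIntensitySet} with at least one probe
#'   of each assay type.
#' @param smoothByPosition replace raw offsets by linear-model fits on chip
#'   row; requires \code{ChipRow} for every sample.
#' @param pooledChannels estimate a single offset per sample from the two
#'   channels pooled, replicated to both channels.
#' @param gridSize number of density grid points (default 512).
#' @param useChipCol also include chip column in the smoothing model.
#' @return A \code{data.frame} with columns \code{sample}, \code{channel},
#'   \code{offset}, plus attributes \code{smoothed} (logical) and
#'   \code{gridStep} (named per-channel grid resolution, fluorescence
#'   units).
#' @export
estimateBackgroundOffsets <- function(object, smoothByPosition = FALSE,
                                      pooledChannels = FALSE,
                                      gridSize = 512L, useChipCol = FALSE) {
    stopifnot(is(object, "MethylIntensitySet"))
    type <- rowData(object)$AssayType
    if (!any(type == "I") || !any(type == "II"))
        stop("offset estimation needs probes of both assay types")
    samples <- colnames(object)
    mats <- list(methylated = methylated(object),
                 unmethylated = unmethylated(object))
    res <- expand.grid(sample = samples, channel = .CHANNELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    res$offset <- NA_real_
    steps <- numeric(nrow(res))
    for (k in seq_len(nrow(res))) {
        j <- match(res$sample[k], samples)
        v <- if (pooledChannels)
            c(mats$methylated[, j], mats$unmethylated[, j])
        else mats[[res$channel[k]]][, j]
        tI <- if (pooledChannels) rep(type, 2L) else type
        pk <- .background_peaks(v[tI == "I"], v[tI == "II"], v, gridSize)
        res$offset[k] <- pk$peakII - pk$peakI
        steps[k] <- pk$step
    }
    if (smoothByPosition)
        res$offset <- .smooth_offsets(res, colData(object), useChipCol)
    attr(res, "smoothed") <- smoothByPosition
    attr(res, "gridStep") <- stats::setNames(
        vapply(.CHANNELS, function(ch) max(steps[res$channel == ch]), 0),
        .CHANNELS)
    res
}

## locate the low-intensity density mode of each assay type on a common grid
.background_peaks <- function(vI, vII, all_values, gridSize) {
    hi <- max(all_values)
    if (hi <= 0) return(list(peakI = 0, peakII = 0, step = 0))
    med <- stats::median(all_values)
    peak1 <- .low_mode(vI, hi, med, gridSize)
    peak2 <- .low_mode(vII, hi, med, gridSize)
    list(peakI = peak1, peakII = peak2, step = hi / (gridSize - 1L))
}

.low_mode <- function(v, hi, med, gridSize) {
    d <- stats::density(v, n = gridSize, from = 0, to = hi)
    low <- d$x < med
    if (!any(low)) {
        warning("no density grid point below the median intensity; ",
                "falling back to the global mode")
        return(d$x[which.max(d$y)])
    }
    d$x[low][which.max(d$y[low])]
}

.smooth_offsets <- function(res, cd, useChipCol) {
    row <- cd$ChipRow[match(res$sample, rownames(cd))]
    if (anyNA(row))
        stop("smoothByPosition requires ChipRow for every sample")
    col <- cd$ChipCol[match(res$sample, rownames(cd))]
    out <- res$offset
    for (ch in unique(res$channel)) {
        i <- res$channel == ch
        df <- data.frame(offset = res$offset[i], row = row[i])
        fml <- offset ~ row
        if (useChipCol) {
            df$col <- col[i]
            fml <- offset ~ row + col
        }
        out[i] <- stats::fitted(stats::lm(fml, data = df))
    }
    out
}

#' Add background offsets to Type I intensities
#'
#' Applies a set of offsets from \code{\link{estimateBackgroundOffsets}}:
#' for every sample and channel, the signed offset is added to the Type I
#' probe intensities of that channel (Type II rows are untouched), and any
#' resulting negative intensity is clipped to 0.
#'
#' @param object a \linkS4class{MethylIntensitySet}.
#' @param offsets data.frame from \code{\link{estimateBackgroundOffsets}}
#'   covering every (sample, channel) pair.
#' @return A new \linkS4class{MethylIntensitySet}.
#' @export
equalizeBackground <- function(object, offsets) {
    stopifnot(is(object, "MethylIntensitySet"))
    typeI <- rowData(object)$AssayType == "I"
    mats <- list(methylated = methylated(object),
                 unmethylated = unmethylated(object))
    for (ch in .CHANNELS) {
        sel <- offsets$channel == ch
        off <- offsets$offset[sel][match(colnames(object), offsets$sample[sel])]
        if (anyNA(off))
            stop("offsets missing for channel '", ch, "' for sample(s): ",
                 paste(colnames(object)[is.na(off)], collapse = ", "))
        mats[[ch]][typeI, ] <- sweep(mats[[ch]][typeI, , drop = FALSE], 2L,
                                     off, `+`)
        mats[[ch]][mats[[ch]] < 0] <- 0
    }
    MethylIntensitySet(mats$methylated, mats$unmethylated,
                       probeData = rowData(object),
                       sampleData = colData(object))
}
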