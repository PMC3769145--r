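#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

.VALID_SEX <- c("male", "female", "unknown")
.VALID_ASSAY_TYPE <- c("I", "II")
.VALID_CHANNEL <- c("Red", "Grn", "Both")

#' MethylIntensitySet: paired methylated/unmethylated intensities
#'
#' Container for raw (or background-equalised / quantile-normalised) signal
#' intensities from an Infinium HumanMethylation450 experiment.  Extends
#' \linkS4class{SummarizedExperiment} with two assays, \code{"methylated"}
#' and \code{"unmethylated"}, holding non-negative fluorescence intensities
#' (probes in rows, samples in columns).  \code{rowData} carries the probe
#' manifest (assay type, chromosome, colour channel, SNP-control and
#' imprinted-DMR flags); \code{colData} carries the sample sheet (sex and
#' BeadChip position).
#'
#' Validity requires: both assays present with identical dimensions; all
#' intensities finite and non-negative; rowData columns \code{AssayType}
#' (\code{"I"}/\code{"II"}), \code{Chromosome}, \code{Channel}
#' (\code{"Red"}/\code{"Grn"} for Type I, \code{"Both"} for Type II),
#' logical \code{IsSNP} and \code{IsIDMR} (mutually exclusive); colData
#' columns \code{Sex} (\code{"male"}/\code{"female"}/\code{"unknown"}),
#' \code{ChipID}, and \code{ChipRow}/\code{ChipCol} either both present or
#' both \code{NA} per sample.
#'
#' @seealso \code{\link{readIntensities}}, \code{\link{applyMethod}},
#'   \code{\link{simulateDataset}}
#' @exportClass MethylIntensitySet
setClass("MethylIntensitySet", contains = "SummarizedExperiment")

.validate_probe_annotation <- function(rd, nprobe) {
    need <- c("AssayType", "Chromosome", "Channel", "IsSNP", "IsIDMR")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        return(paste("rowData missing column(s):", paste(miss, collapse = ", ")))
    at <- as.character(rd$AssayType)
    if (!all(at %in% .VALID_ASSAY_TYPE))
        return("AssayType values must be 'I' or 'II'")
    ch <- as.character(rd$Channel)
    if (!all(ch %in% .VALID_CHANNEL))
        return("Channel values must be 'Red', 'Grn' or 'Both'")
    if (any(at == "II" & ch != "Both"))
        return("Type II probes must have Channel 'Both'")
    if (any(at == "I" & !(ch %in% c("Red", "Grn"))))
        return("Type I probes must have Channel 'Red' or 'Grn'")
    if (!is.logical(rd$IsSNP) || !is.logical(rd$IsIDMR))
        return("IsSNP and IsIDMR must be logical")
    if (any(rd$IsSNP & rd$IsIDMR))
        return("IsSNP and IsIDMR are mutually exclusive")
    NULL
}

.validate_sample_annotation <- function(cd) {
    need <- c("Sex", "ChipID", "ChipRow", "ChipCol")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData missing column(s):", paste(miss, collapse = ", ")))
    if (!all(as.character(cd$Sex) %in% .VALID_SEX))
        return("Sex values must be 'male', 'female' or 'unknown'")
    row_na <- is.na(cd$ChipRow)
    col_na <- is.na(cd$ChipCol)
    if (any(row_na != col_na))
        return("ChipRow and ChipCol must be both present or both missing per sample")
    ok <- !row_na
    if (any(ok) && (any(cd$ChipRow[ok] < 1) || any(cd$ChipCol[ok] < 1)))
        return("ChipRow and ChipCol must be >= 1")
    NULL
}

setValidity("MethylIntensitySet", function(object) {
    an <- assayNames(object)
    if (!all(c("methylated", "unmethylated") %in% an))
        return("assays must include 'methylated' and 'unmethylated'")
    m <- assay(object, "methylated")
    u <- assay(object, "unmethylated")
    if (!identical(dim(m), dim(u)))
        return("methylated and unmethylated assays differ in dimension")
    if (any(!is.finite(m)) || any(!is.finite(u)))
        return("intensities must all be finite")
    if (any(m < 0) || any(u < 0))
        return("intensities must be non-negative")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("probe ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("sample ids (colnames) must be present and unique")
    err <- .validate_probe_annotation(rowData(object), nrow(object))
    if (!is.null(err)) return(err)
    err <- .validate_sample_annotation(colData(object))
    if (!is.null(err)) return(err)
    TRUE
})

#' Construct a MethylIntensitySet
#'
#' @param methylated,unmethylated numeric matrices (probes x samples) of
#'   non-negative intensities with matching dimnames.
#' @param probeData data.frame or DataFrame of probe annotation with columns
#'   \code{AssayType}, \code{Chromosome}, \code{Channel}, \code{IsSNP},
#'   \code{IsIDMR}; one row per probe, in row order of the matrices.
#' @param sampleData data.frame or DataFrame of sample annotation with
#'   columns \code{Sex}, \code{ChipID}, \code{ChipRow}, \code{ChipCol}.
#' @return A validated \linkS4class{MethylIntensitySet}.
#' @examples
#' m <- matrix(c(100, 900, 400, 800), 2, dimnames = list(c("p1","p2"), c("s1","s2")))
#' u <- matrix(c(900, 100, 600, 150), 2, dimnames = dimnames(m))
#' pd <- data.frame(AssayType = c("I","II"), Chromosome = c("1","2"),
#'                  Channel = c("Red","Both"), IsSNP = FALSE, IsIDMR = FALSE)
#' sd <- data.frame(Sex = c("male","female"), ChipID = "chip1",
#'                  ChipRow = 1:2, ChipCol = 1L)
#' MethylIntensitySet(m, u, pd, sd)
#' @export
MethylIntensitySet <- function(methylated, unmethylated, probeData, sampleData) {
    methylated <- as.matrix(methylated)
    unmethylated <- as.matrix(unmethylated)
    probeData <- .as_probe_df(probeData)
    sampleData <- .as_sample_df(sampleData)
    se <- SummarizedExperiment(
        assays = list(methylated = methylated, unmethylated = unmethylated),
        rowData = probeData, colData = sampleData)
    new("MethylIntensitySet", se)
}

.as_probe_df <- function(pd) {
    pd <- as(pd, "DataFrame")
    for (col in c("AssayType", "Chromosome", "Channel"))
        if (col %in% colnames(pd)) pd[[col]] <- as.character(pd[[col]])
    for (col in c("IsSNP", "IsIDMR"))
        if (col %in% colnames(pd)) pd[[col]] <- as.logical(pd[[col]])
    if ("Chromosome" %in% colnames(pd))
        pd$Chromosome <- sub("^chr", "", pd$Chromosome, ignore.case = TRUE)
    pd
}

.as_sample_df <- function(cd) {
    cd <- as(cd, "DataFrame")
    for (col in c("Sex", "ChipID"))
        if (col %in% colnames(cd)) cd[[col]] <- as.character(cd[[col]])
    for (col in c("ChipRow", "ChipCol"))
        if (col %in% colnames(cd)) cd[[col]] <- suppressWarnings(as.integer(cd[[col]]))
    cd
}

#' BetaSet: a matrix of methylation beta values
#'
#' Probes x samples methylation fractions in [0, 1], as produced by
#' \code{\link{computeBeta}} or \code{\link{applyMethod}}.  Extends
#' \linkS4class{SummarizedExperiment} with a single assay \code{"beta"};
#' probe and sample annotation are carried over from the source
#' \linkS4class{MethylIntensitySet}.  The preprocessing method that produced
#' the values is recorded in \code{metadata(x)$method}.
#'
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    if (!"beta" %in% assayNames(object))
        return("assay 'beta' required")
    b <- assay(object, "beta")
    if (any(!is.finite(b)))
        return("beta values must be finite")
    if (any(b < 0) || any(b > 1))
        return("beta values must lie in [0, 1]")
    TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of values in [0, 1] (probes x samples).
#' @param rowData,colData optional probe/sample annotation.
#' @param method character scalar recorded in \code{metadata()$method}.
#' @return A validated \linkS4class{BetaSet}.
#' @export
BetaSet <- function(beta, rowData = NULL, colData = NULL, method = "unknown") {
    beta <- as.matrix(beta)
    args <- list(assays = list(beta = beta))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment, args)
    out <- new("BetaSet", se)
    metadata(out)$method <- method
    out
}

setMethod("show", "MethylIntensitySet", function(object) {
    cat("MethylIntensitySet with", nrow(object), "probes and",
        ncol(object), "samples\n")
    rd <- rowData(object)
    cat(sprintf("  Type I: %d  Type II: %d  SNP controls: %d  iDMR: %d  X: %d\n",
                sum(rd$AssayType == "I"), sum(rd$AssayType == "II"),
                sum(rd$IsSNP), sum(rd$IsIDMR),
                sum(toupper(rd$Chromosome) == "X")))
    sx <- table(factor(colData(object)$Sex, levels = .VALID_SEX))
    cat(sprintf("  samples: %d male, %d female, %d unknown\n",
                sx[["male"]], sx[["female"]], sx[["unknown"]]))
    invisible(NULL)
})

setMethod("show", "BetaSet", function(object) {
    cat("BetaSet with", nrow(object), "probes and", ncol(object),
        "samples (method:", metadata(object)$method, ")\n")
    b <- assay(object, "beta")
    cat(sprintf("  beta range: [%.4f, %.4f]\n", min(b), max(b)))
    invisible(NULL)
})
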