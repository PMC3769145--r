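## Text-file interfaces: GenomeStudio-style intensity exports (TSV, probes x
## samples), manifest and sample-sheet tables (TSV or CSV), beta TSVs.
## Dialect: UTF-8, '.' decimal separator, probe-id column header "ProbeID".

.sep_for <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_raw_table <- function(path, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE, encoding = "UTF-8")
    if (ncol(df) < 1) stop("empty table: ", path)
    df
}

## parse an intensity table to a numeric matrix with probe-id rownames,
## failing loudly on duplicate labels and on non-numeric or negative cells
.parse_intensity_table <- function(path, what) {
    df <- .read_raw_table(path)
    if (tolower(colnames(df)[1]) != "probeid")
        stop(what, " table ", path, ": first column must be 'ProbeID', found '",
             colnames(df)[1], "'")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop(what, " table ", path, ": duplicate probe id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    samples <- colnames(df)[-1]
    if (anyDuplicated(samples))
        stop(what, " table ", path, ": duplicate sample id(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    if (length(samples) == 0)
        stop(what, " table ", path, ": no sample columns")
    mat <- matrix(NA_real_, nrow(df), length(samples),
                  dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(what, " table ", path, ": non-numeric value '",
                 df[[j + 1L]][bad[1]], "' at probe '", ids[bad[1]],
                 "', sample '", samples[j], "'")
        neg <- which(v < 0)
        if (length(neg))
            stop(what, " table ", path, ": negative intensity ", v[neg[1]],
                 " at probe '", ids[neg[1]], "', sample '", samples[j], "'")
        mat[, j] <- v
    }
    mat
}

#' Read a probe manifest table
#'
#' Expects columns \code{ProbeID}, \code{AssayType} (I/II),
#' \code{Chromosome}, \code{Channel} (Red/Grn/Both), \code{IsSNP},
#' \code{IsIDMR}.  TSV or CSV (by file extension).
#'
#' @param path file path.
#' @return A \code{DataFrame} with \code{ProbeID} as rownames.
#' @export
readManifest <- function(path) {
    df <- .read_raw_table(path, sep = .sep_for(path))
    need <- c("ProbeID", "AssayType", "Chromosome", "Channel", "IsSNP", "IsIDMR")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("manifest ", path, " missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$ProbeID))
        stop("manifest ", path, ": duplicate probe id(s): ",
             paste(unique(df$ProbeID[duplicated(df$ProbeID)]), collapse = ", "))
    bad <- setdiff(unique(df$AssayType), c("I", "II"))
    if (length(bad))
        stop("manifest ", path, ": AssayType must be 'I' or 'II', found: ",
             paste(bad, collapse = ", "))
    df$IsSNP <- .parse_logical(df$IsSNP, "IsSNP", path)
    df$IsIDMR <- .parse_logical(df$IsIDMR, "IsIDMR", path)
    rd <- .as_probe_df(df[setdiff(colnames(df), "ProbeID")])
    rownames(rd) <- df$ProbeID
    rd
}

.parse_logical <- function(x, col, path) {
    v <- rep(NA, length(x))
    v[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    v[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    if (any(is.na(v)))
        stop("manifest ", path, ": column ", col,
             " has non-logical value '", x[which(is.na(v))[1]], "'")
    v
}

#' Read a sample sheet
#'
#' Expects columns \code{SampleID}, \code{Sex} (male/female/unknown),
#' \code{ChipID}, \code{ChipRow}, \code{ChipCol} (the latter two may be
#' empty/NA, but only jointly per sample).
#'
#' @param path file path.
#' @return A \code{DataFrame} with \code{SampleID} as rownames.
#' @export
readSampleSheet <- function(path) {
    df <- .read_raw_table(path, sep = .sep_for(path))
    need <- c("SampleID", "Sex", "ChipID", "ChipRow", "ChipCol")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("sample sheet ", path, " missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$SampleID))
        stop("sample sheet ", path, ": duplicate sample id(s): ",
             paste(unique(df$SampleID[duplicated(df$SampleID)]), collapse = ", "))
    df$ChipRow[df$ChipRow == ""] <- NA
    df$ChipCol[df$ChipCol == ""] <- NA
    cd <- .as_sample_df(df[setdiff(colnames(df), "SampleID")])
    rownames(cd) <- df$SampleID
    cd
}

#' Read paired intensity tables into a MethylIntensitySet
#'
#' Reads the methylated and unmethylated intensity exports (TSV, probes x
#' samples, first column \code{ProbeID}), a probe manifest and a sample
#' sheet, aligns everything by label (not file order), validates, and
#' returns a \linkS4class{MethylIntensitySet}.  Probe and sample order
#' follow the methylated table.
#'
#' @param methPath,unmethPath paths to the two intensity TSVs.
#' @param manifestPath path to the probe manifest (see
#'   \code{\link{readManifest}}).
#' @param sampleSheetPath path to the sample sheet (see
#'   \code{\link{readSampleSheet}}).
#' @return A validated \linkS4class{MethylIntensitySet}.
#' @export
readIntensities <- function(methPath, unmethPath, manifestPath,
                            sampleSheetPath) {
    m <- .parse_intensity_table(methPath, "methylated")
    u <- .parse_intensity_table(unmethPath, "unmethylated")
    if (!setequal(rownames(m), rownames(u)))
        stop("methylated and unmethylated tables disagree on probe ids; e.g. ",
             paste(utils::head(c(setdiff(rownames(m), rownames(u)),
                                 setdiff(rownames(u), rownames(m))), 3),
                   collapse = ", "))
    if (!setequal(colnames(m), colnames(u)))
        stop("methylated and unmethylated tables disagree on sample ids")
    u <- u[rownames(m), colnames(m), drop = FALSE]
    manifest <- readManifest(manifestPath)
    missing_probes <- setdiff(rownames(m), rownames(manifest))
    if (length(missing_probes))
        stop("manifest does not cover probe id(s): ",
             paste(utils::head(missing_probes, 3), collapse = ", "))
    sheet <- readSampleSheet(sampleSheetPath)
    missing_samples <- setdiff(colnames(m), rownames(sheet))
    if (length(missing_samples))
        stop("sample sheet does not cover sample id(s): ",
             paste(utils::head(missing_samples, 3), collapse = ", "))
    MethylIntensitySet(m, u,
                       probeData = manifest[rownames(m), , drop = FALSE],
                       sampleData = sheet[colnames(m), , drop = FALSE])
}

#' Write beta values to a TSV file
#'
#' Writes a probes x samples beta table with probe ids in a leading
#' \code{ProbeID} column, to 6 decimal places.
#'
#' @param betas a \linkS4class{BetaSet} or numeric matrix.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeBetas <- function(betas, path) {
    b <- if (is(betas, "BetaSet")) betas(betas) else as.matrix(betas)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("ProbeID", colnames(b)), collapse = "\t"), con)
    if (nrow(b)) {
        body <- apply(format(round(b, 6), trim = TRUE, scientific = FALSE),
                      1, paste, collapse = "\t")
        writeLines(paste(rownames(b), body, sep = "\t"), con)
    }
    invisible(path)
}

#' Read a beta TSV written by \code{writeBetas}
#'
#' @param path file path.
#' @param method method label to record in the result.
#' @return A \linkS4class{BetaSet}.
#' @export
readBetas <- function(path, method = "unknown") {
    df <- .read_raw_table(path)
    if (tolower(colnames(df)[1]) != "probeid")
        stop("beta table ", path, ": first column must be 'ProbeID'")
    ids <- df[[1]]
    mat <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                  dimnames = list(ids, colnames(df)[-1]))
    for (j in seq_len(ncol(df) - 1L)) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        if (nrow(df) && anyNA(v))
            stop("beta table ", path, ": non-numeric value in column ",
                 colnames(df)[j + 1L])
        mat[, j] <- v
    }
    BetaSet(mat, method = method)
}
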