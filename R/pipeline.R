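#' Run the full method-evaluation pipeline over one or more datasets
#'
#' For each dataset: preprocess with every requested method, compute the
#' three quality metrics per assay type, and finally rank methods across
#' datasets by the mean-rank procedure of \code{\link{rankMethods}}.
#'
#' @param datasets a \linkS4class{MethylIntensitySet}, a list of them, or a
#'   character vector of fixture directories (as written by
#'   \code{\link{writeFixture}}).
#' @param methods method names (default all twelve).
#' @param alpha beta offset.
#' @param datasetIds labels for the datasets; defaults to list names,
#'   directory basenames, or \code{dataset1..N}.
#' @return List with \code{metrics} (per dataset x method x type
#'   data.frame) and \code{ranks} (the final rank table).
#' @export
evaluatePipeline <- function(datasets, methods = normMethods(), alpha = 100,
                             datasetIds = NULL) {
    if (is(datasets, "MethylIntensitySet")) datasets <- list(datasets)
    if (is.character(datasets)) {
        dirs <- datasets
        datasets <- lapply(dirs, function(d)
            readIntensities(file.path(d, "methylated.tsv"),
                            file.path(d, "unmethylated.tsv"),
                            file.path(d, "manifest.tsv"),
                            file.path(d, "samplesheet.tsv")))
        if (is.null(datasetIds)) datasetIds <- basename(dirs)
    }
    if (is.null(datasetIds))
        datasetIds <- names(datasets) %||% paste0("dataset", seq_along(datasets))
    if (is.null(names(datasets)) || any(names(datasets) == ""))
        names(datasets) <- datasetIds
    reports <- do.call(rbind, lapply(seq_along(datasets), function(i) {
        bs <- applyMethods(datasets[[i]], methods = methods, alpha = alpha)
        evaluateMetrics(bs, datasetId = datasetIds[i])
    }))
    list(metrics = reports, ranks = rankMethods(reports))
}
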