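## Cross-dataset ranking of preprocessing methods.  Per dataset and assay
## type the three metrics (DMRSE, GCOSE collapsed from its three genotype
## groups, Seabird) are ranked across methods (ascending: lower = more
## sensitive), the three metric ranks are averaged per method, those mean
## ranks are averaged across datasets, and the per-type averages are ranked
## again to give the final score; the two type scores are averaged.  Ties
## receive mean ranks throughout, so fractional scores like 1.5 are normal.

#' Rank preprocessing methods from metric reports
#'
#' @param reports data.frame as produced by \code{\link{evaluateMetrics}}
#'   (possibly rbind-ed over datasets): columns \code{dataset},
#'   \code{method}, \code{assay_type}, \code{dmrse}, \code{gcose},
#'   \code{seabird}.  Every (dataset, method, assay type) cell must be
#'   present; a metric that is NA for every row (e.g. Seabird on
#'   single-sex data) is dropped from the ranking with a message, but a
#'   partially missing metric is an error.
#' @return A data.frame with columns \code{method}, \code{rank_typeI},
#'   \code{rank_typeII} and \code{average} (= their mean), sorted by
#'   \code{average}.
#' @export
rankMethods <- function(reports) {
    need <- c("dataset", "method", "assay_type", "dmrse", "gcose", "seabird")
    miss <- setdiff(need, colnames(reports))
    if (length(miss))
        stop("reports missing column(s): ", paste(miss, collapse = ", "))
    methods <- unique(reports$method)
    if (length(methods) < 2L)
        stop("ranking needs >= 2 methods")
    datasets <- unique(reports$dataset)
    types <- c("I", "II")
    full <- expand.grid(dataset = datasets, method = methods,
                        assay_type = types, stringsAsFactors = FALSE)
    key <- function(d) paste(d$dataset, d$method, d$assay_type)
    absent <- setdiff(key(full), key(reports))
    if (length(absent))
        stop("reports missing cell(s): ", paste(absent, collapse = "; "))

    metrics <- c("dmrse", "gcose", "seabird")
    dropped <- metrics[vapply(metrics, function(m) all(is.na(reports[[m]])),
                              NA)]
    if (length(dropped)) {
        message("metric(s) unavailable for all datasets, ranking without: ",
                paste(dropped, collapse = ", "))
        metrics <- setdiff(metrics, dropped)
    }
    for (m in metrics)
        if (anyNA(reports[[m]]))
            stop("metric '", m, "' is missing for some cells but not all; ",
                 "cannot rank")
    if (!length(metrics))
        stop("no usable metrics to rank")

    type_score <- sapply(types, function(ty) {
        per_dataset <- sapply(datasets, function(ds) {
            sub <- reports[reports$assay_type == ty & reports$dataset == ds, ]
            sub <- sub[match(methods, sub$method), ]
            metric_ranks <- vapply(metrics, function(m)
                rank(sub[[m]], ties.method = "average"),
                numeric(length(methods)))
            rowMeans(matrix(metric_ranks, nrow = length(methods)))
        })
        mean_rank <- rowMeans(matrix(per_dataset, nrow = length(methods)))
        rank(mean_rank, ties.method = "average")
    })
    out <- data.frame(method = methods,
                      rank_typeI = type_score[, "I"],
                      rank_typeII = type_score[, "II"])
    out$average <- (out$rank_typeI + out$rank_typeII) / 2
    out <- out[order(out$average, out$method), ]
    rownames(out) <- NULL
    out
}

#' Per-dataset mean metric ranks
#'
#' The intermediate per-method mean of the three metric ranks for a single
#' dataset and assay type (the quantity averaged across datasets by
#' \code{\link{rankMethods}}); useful for inspecting how stable a method's
#' standing is across replicates.
#'
#' @param reports metric report data.frame restricted to one dataset.
#' @param assay_type "I" or "II".
#' @param metrics which metric columns to rank.
#' @return Named numeric vector of mean ranks per method.
#' @export
meanMetricRanks <- function(reports, assay_type,
                            metrics = c("dmrse", "gcose", "seabird")) {
    sub <- reports[reports$assay_type == assay_type, ]
    if (anyDuplicated(sub$method))
        stop("meanMetricRanks expects a single dataset")
    rk <- vapply(metrics, function(m) rank(sub[[m]], ties.method = "average"),
                 numeric(nrow(sub)))
    stats::setNames(rowMeans(matrix(rk, nrow = nrow(sub))), sub$method)
}
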