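## Data-quality metrics built on probes with known expected behaviour:
## imprinted DMR probes (expected beta 0.5), SNP genotyping control probes
## (expected trimodal beta), and X-chromosome probes (expected male/female
## differences under X inactivation).  All three shrink as technical
## variance shrinks, so lower is better.

.beta_matrix <- function(betas) {
    if (is(betas, "BetaSet")) betas(betas) else as.matrix(betas)
}

#' DMRSE: imprinted-DMR standard error
#'
#' Probes in imprinted differentially methylated regions are uniparentally
#' methylated, so their expected beta is 0.5 in most tissues.  The metric
#' is the standard deviation of the full set of iDMR beta values (pooled
#' over probes and samples, default) divided by the square root of the
#' number of samples — a standard-error-like score of residual technical
#' scatter around the known level.
#'
#' @param betas a \linkS4class{BetaSet} or beta matrix.
#' @param idmr logical/integer row subset of iDMR probes; defaults to the
#'   \code{IsIDMR} column of the object's rowData.
#' @param mode \code{"pooled"} (default: one sd over all iDMR entries),
#'   \code{"row"} (per-probe sd across samples, then mean) or \code{"col"}
#'   (per-sample sd across probes, then mean); all divided by sqrt(n
#'   samples).
#' @return Non-negative scalar.
#' @examples
#' b <- matrix(c(0.4, 0.4, 0.6, 0.6), 2)   # 2 probes x 2 samples
#' dmrse(b, idmr = c(TRUE, TRUE))          # 0.0816497
#' @export
dmrse <- function(betas, idmr = NULL, mode = c("pooled", "row", "col")) {
    mode <- match.arg(mode)
    b <- .beta_matrix(betas)
    if (is.null(idmr)) {
        if (!is(betas, "BetaSet"))
            stop("'idmr' is required for matrix input")
        idmr <- rowData(betas)$IsIDMR
    }
    sub <- b[idmr, , drop = FALSE]
    if (nrow(sub) == 0L)
        stop("no iDMR probes in manifest")
    if (nrow(sub) < 2L || ncol(sub) < 2L)
        stop("dmrse needs >= 2 iDMR probes and >= 2 samples")
    n <- ncol(sub)
    s <- switch(mode,
                pooled = stats::sd(as.vector(sub)),
                row = mean(apply(sub, 1L, stats::sd)),
                col = mean(apply(sub, 2L, stats::sd)))
    s / sqrt(n)
}

## Deterministic 3-means on one SNP probe's betas: Lloyd iterations from
## fixed centers (0.2, 0.5, 0.8); degenerate probes (< 3 distinct values)
## are clustered with reduced k and their clusters mapped to genotype
## groups by nearest canonical center.
.snp_clusters <- function(v) {
    centers <- c(0.2, 0.5, 0.8)
    ndist <- length(unique(v))
    k <- min(3L, ndist)
    if (k == 1L)
        return(list(ss = sum((v - mean(v))^2), n = length(v),
                    group = which.min(abs(mean(v) - centers))))
    init <- if (k == 3L) centers else sort(unique(v))[seq_len(k)]
    km <- suppressWarnings(stats::kmeans(v, centers = matrix(init),
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
    ord <- order(km$centers[, 1L])
    group <- if (k == 3L) seq_len(3L)[order(ord)] else {
        g <- vapply(km$centers[, 1L],
                    function(cc) which.min(abs(cc - centers)), 0L)
        if (anyDuplicated(g)) g <- rank(km$centers[, 1L], ties.method = "first")
        as.integer(g)
    }
    list(ss = km$withinss, n = km$size, group = group)
}

#' GCOSE: genotype combined standard error
#'
#' The 65 SNP genotyping control probes on the array produce trimodal beta
#' values (two homozygote clusters and a heterozygote cluster).  Each SNP
#' probe is partitioned into three clusters by k-means; within-cluster sums
#' of squares and cluster sizes are summed over SNPs per genotype group
#' (BB, AB, AA ordered by ascending cluster center), each summed SS is
#' divided by the summed size, and the three mean squares are divided by
#' the square root of the total sample count.  GCOSE is the mean of the
#' three group scores; zero-width clusters give 0.
#'
#' @param betas a \linkS4class{BetaSet} or beta matrix.
#' @param snp row subset of SNP control probes; defaults to rowData
#'   \code{IsSNP}.
#' @return A list with \code{by_group} (named BB/AB/AA scores) and
#'   \code{gcose} (their mean).
#' @export
gcose <- function(betas, snp = NULL) {
    b <- .beta_matrix(betas)
    if (is.null(snp)) {
        if (!is(betas, "BetaSet"))
            stop("'snp' is required for matrix input")
        snp <- rowData(betas)$IsSNP
    }
    sub <- b[snp, , drop = FALSE]
    if (nrow(sub) == 0L)
        stop("no SNP control probes in manifest")
    n_total <- ncol(sub)
    if (n_total < 3L)
        stop("gcose needs >= 3 samples")
    ss_sum <- n_sum <- numeric(3L)
    for (i in seq_len(nrow(sub))) {
        cl <- .snp_clusters(sub[i, ])
        for (k in seq_along(cl$group)) {
            g <- cl$group[k]
            ss_sum[g] <- ss_sum[g] + cl$ss[k]
            n_sum[g] <- n_sum[g] + cl$n[k]
        }
    }
    ms <- ifelse(n_sum > 0, ss_sum / n_sum, 0)
    by_group <- stats::setNames(ms / sqrt(n_total), c("BB", "AB", "AA"))
    list(by_group = by_group, gcose = mean(by_group))
}

#' Per-probe p-values for sex differences
#'
#' A two-sided t-test of every probe's betas between male and female
#' samples; Welch's unequal-variance form by default.  Probes with zero
#' variance in both groups get p = 1 when the group means are equal and
#' p = 0 otherwise (the difference is then seen without noise).
#'
#' @param betas a \linkS4class{BetaSet} or beta matrix.
#' @param sex per-sample labels ("male"/"female"; other labels dropped);
#'   defaults to the colData \code{Sex} column.
#' @param var.equal use the pooled-variance (Student) form instead of
#'   Welch.
#' @return Named numeric vector of p-values, one per probe.
#' @export
sexDifferencePvalues <- function(betas, sex = NULL, var.equal = FALSE) {
    b <- .beta_matrix(betas)
    if (is.null(sex)) {
        if (!is(betas, "BetaSet"))
            stop("'sex' is required for matrix input")
        sex <- colData(betas)$Sex
    }
    male <- sex == "male"
    female <- sex == "female"
    if (sum(male) < 2L || sum(female) < 2L)
        stop("sex-difference test needs >= 2 males and >= 2 females ",
             "(single-sex data make the test redundant)")
    .welch_rows(b[, male, drop = FALSE], b[, female, drop = FALSE],
                var.equal = var.equal)
}

## vectorised row-wise two-sample t-test
.welch_rows <- function(x, y, var.equal = FALSE) {
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1L)
    vy <- rowSums((y - my)^2) / (ny - 1L)
    if (var.equal) {
        sp <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
        se2 <- sp * (1 / nx + 1 / ny)
        df <- rep(nx + ny - 2L, length(mx))
    } else {
        se2 <- vx / nx + vy / ny
        df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
    }
    tstat <- (mx - my) / sqrt(se2)
    p <- 2 * stats::pt(-abs(tstat), df)
    zero <- se2 == 0
    p[zero & mx == my] <- 1
    p[zero & mx != my] <- 0
    stats::setNames(p, rownames(x))
}

## Mann-Whitney AUC of score predicting a binary label, ties by average rank
.rank_auc <- function(score, positive) {
    n_pos <- sum(positive)
    n_neg <- sum(!positive)
    if (n_pos == 0L || n_neg == 0L)
        stop("AUC needs both positive and negative probes")
    r <- rank(score, ties.method = "average")
    (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Seabird: 1 - AUC for predicting X-chromosome location
#'
#' X-inactivation hypermethylates one X in females, so sex-difference
#' p-values should single out X-chromosome probes.  The metric runs an ROC
#' analysis with score -p (smaller p ranks higher) against the indicator
#' "probe is on chromosome X" and returns 1 - AUC: 0 for a perfect
#' predictor, 0.5 for chance.
#'
#' @param betas a \linkS4class{BetaSet} or beta matrix.
#' @param sex,chromosomes per-sample sex labels and per-probe chromosome
#'   labels; default to colData \code{Sex} / rowData \code{Chromosome}.
#' @param excludeY drop Y-chromosome probes from the negatives (default
#'   FALSE: everything not on X counts as a negative).
#' @param pvalues optional precomputed p-values (skips the t-tests).
#' @return Scalar in [0, 1].
#' @export
seabird <- function(betas, sex = NULL, chromosomes = NULL, excludeY = FALSE,
                    pvalues = NULL) {
    if (is.null(chromosomes)) {
        if (!is(betas, "BetaSet"))
            stop("'chromosomes' is required for matrix input")
        chromosomes <- rowData(betas)$Chromosome
    }
    if (is.null(pvalues))
        pvalues <- sexDifferencePvalues(betas, sex)
    chromosomes <- toupper(as.character(chromosomes))
    keep <- if (excludeY) chromosomes != "Y" else rep(TRUE, length(chromosomes))
    is_x <- chromosomes[keep] == "X"
    if (!any(is_x) || all(is_x))
        stop("seabird needs both X and non-X probes")
    1 - .rank_auc(-pvalues[keep], is_x)
}

#' Evaluate all metrics for a set of preprocessed datasets
#'
#' Computes DMRSE, GCOSE (with its three genotype-group components) and
#' Seabird for each method's beta matrix, separately for Type I and Type II
#' probes (Seabird's ROC is restricted to probes of the given type).  A
#' metric that cannot be computed (e.g. Seabird on single-sex data) is
#' recorded as NA with a warning rather than failing the run.
#'
#' @param betasByMethod named list of \linkS4class{BetaSet} objects (as from
#'   \code{\link{applyMethods}}).
#' @param datasetId label stored in the report's \code{dataset} column.
#' @return A data.frame with one row per method x assay type and columns
#'   \code{dataset}, \code{method}, \code{assay_type}, \code{dmrse},
#'   \code{gcose_BB}, \code{gcose_AB}, \code{gcose_AA}, \code{gcose},
#'   \code{seabird}, \code{n_samples}.
#' @export
evaluateMetrics <- function(betasByMethod, datasetId = "dataset1") {
    stopifnot(is.list(betasByMethod), length(betasByMethod) >= 1L,
              !is.null(names(betasByMethod)))
    rows <- list()
    for (method in names(betasByMethod)) {
        bs <- betasByMethod[[method]]
        stopifnot(is(bs, "BetaSet"))
        rd <- rowData(bs)
        for (type in c("I", "II")) {
            sel <- rd$AssayType == type
            sub <- bs[sel, ]
            rec <- list(dataset = datasetId, method = method,
                        assay_type = type,
                        dmrse = .try_metric(function() dmrse(sub),
                                            method, type, "dmrse"),
                        gcose_BB = NA_real_, gcose_AB = NA_real_,
                        gcose_AA = NA_real_, gcose = NA_real_,
                        seabird = .try_metric(function() seabird(sub),
                                              method, type, "seabird"),
                        n_samples = ncol(sub))
            gc <- .try_metric(function() gcose(sub), method, type, "gcose")
            if (is.list(gc)) {
                rec$gcose_BB <- gc$by_group[["BB"]]
                rec$gcose_AB <- gc$by_group[["AB"]]
                rec$gcose_AA <- gc$by_group[["AA"]]
                rec$gcose <- gc$gcose
            }
            rows[[length(rows) + 1L]] <- as.data.frame(rec)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.try_metric <- function(f, method, type, metric) {
    tryCatch(f(), error = function(e) {
        warning(metric, " unavailable for method '", method, "', Type ",
                type, ": ", conditionMessage(e), call. = FALSE)
        NA_real_
    })
}
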