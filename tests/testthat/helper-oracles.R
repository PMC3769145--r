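## Independent reference implementations used to cross-check the package,
## written deliberately naively (explicit loops, no shared code paths).

suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

## brute-force quantile normalization: sort each column, average rank-wise,
## hand values back by walking each column's order; tied input values get
## the mean of the targets at their rank positions
qn_oracle <- function(x) {
    n <- nrow(x)
    sorted <- matrix(NA_real_, n, ncol(x))
    for (j in seq_len(ncol(x))) sorted[, j] <- sort(x[, j])
    target <- numeric(n)
    for (i in seq_len(n)) target[i] <- mean(sorted[i, ])
    out <- x
    for (j in seq_len(ncol(x))) {
        ord <- order(x[, j])
        vals <- numeric(n)
        vals[ord] <- target
        i <- 1L
        while (i <= n) {
            run <- which(x[, j] == x[ord[i], j])
            vals[run] <- mean(target[i:(i + length(run) - 1L)])
            i <- i + length(run)
        }
        out[, j] <- vals
    }
    out
}

## all-pairs AUC: every (positive, negative) pair scores 1 if the positive's
## score is higher, 0.5 on a tie
auc_bruteforce <- function(score, positive) {
    pos <- score[positive]
    neg <- score[!positive]
    tot <- 0
    for (p in pos)
        for (q in neg)
            tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
    tot / (length(pos) * length(neg))
}

## small deterministic MethylIntensitySet: 6 probes (3 Type I / 3 Type II,
## one iDMR, one SNP, one X probe), 4 samples
make_toy_mset <- function() {
    probes <- paste0("p", 1:6)
    samples <- paste0("s", 1:4)
    set.seed(42)
    m <- matrix(round(runif(24, 100, 5000), 1), 6,
                dimnames = list(probes, samples))
    u <- matrix(round(runif(24, 100, 5000), 1), 6,
                dimnames = list(probes, samples))
    pd <- data.frame(
        AssayType = c("I", "I", "I", "II", "II", "II"),
        Chromosome = c("1", "2", "X", "3", "4", "5"),
        Channel = c("Red", "Grn", "Red", "Both", "Both", "Both"),
        IsSNP = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
        IsIDMR = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
        row.names = probes)
    sd_ <- data.frame(
        Sex = c("male", "female", "male", "female"),
        ChipID = "chipA",
        ChipRow = 1:4, ChipCol = 1L,
        row.names = samples)
    MethylIntensitySet(m, u, pd, sd_)
}

## write a MethylIntensitySet as the four input files readIntensities wants
write_toy_files <- function(ds, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(mat, path) {
        df <- data.frame(ProbeID = rownames(mat), mat, check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wr(methylated(ds), file.path(dir, "meth.tsv"))
    wr(unmethylated(ds), file.path(dir, "unmeth.tsv"))
    rd <- as.data.frame(rowData(ds))
    write.table(cbind(ProbeID = rownames(ds), rd),
                file.path(dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(colData(ds))
    write.table(cbind(SampleID = colnames(ds), cd),
                file.path(dir, "samplesheet.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

## small simulated dataset shared by several tests
small_sim <- function(seed = 1, ...) {
    simulateDataset(simConfig(n_samples = 12L, n_autosomal = 1500L,
                              n_idmr = 60L, n_snp = 20L, n_x = 120L,
                              seed = seed, ...))
}
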