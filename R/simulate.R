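## Synthetic 450K-like data generator.  Emulates the structural features the
## preprocessing methods and quality metrics exploit: bimodal autosomal
## methylation, iDMR probes at 50% methylation, trimodal SNP control probes
## under Hardy-Weinberg genotypes, sex-dependent X-chromosome methylation,
## Type II background inflation, per-sample dye bias on the Type II
## unmethylated channel, lognormal sample-level intensity scaling, and an
## optional chip-row background gradient.

#' Simulation configuration
#'
#' Builds a validated parameter set for \code{\link{simulateDataset}}.
#' Defaults describe a modest but realistic array: 20 samples and ~21k
#' probes (20,000 autosomal CpGs, 237 iDMR probes, 65 SNP controls, 800
#' X-chromosome probes — a reduced-scale stand-in for the array's 11,232 X
#' features), 72% of probes Type II.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_autosomal,n_idmr,n_snp,n_x probe counts per category.
#' @param frac_type2 fraction of probes on the Type II design, in (0, 1).
#' @param intensity_mean mean total fluorescence per probe (arbitrary
#'   units).
#' @param background_type1,background_type2 additive background level per
#'   assay type; Type II higher than Type I reproduces the characteristic
#'   compression of Type II betas toward 0.5.
#' @param background_sd lognormal spread (sdlog) of per-cell background.
#' @param background_sample_sd lognormal sd of a per-sample background
#'   multiplier (arrays differ in overall background level — staining and
#'   wash efficiency — which shifts each sample's whole intensity
#'   distribution; this is the between-sample systematic error that
#'   between-array normalization exists to remove).
#' @param dye_bias_type2 mean multiplier on the Type II unmethylated
#'   (red-channel) signal.
#' @param dye_bias_sd per-sample lognormal sd of the dye-bias multiplier
#'   (dye bias varies between scans, which is what the "M against U" QN
#'   modes remove).
#' @param sample_scale_sd lognormal sd of per-sample intensity scaling.
#' @param meth_shift_sd sd of a per-sample shift applied to methylation
#'   fractions on the logit scale before intensities are formed.  Emulates
#'   between-sample differences in bisulfite-conversion and single-base
#'   extension efficiency, which move a sample's whole methylated/
#'   unmethylated balance and are a major systematic between-sample error
#'   on real arrays.
#' @param chip_row_gradient background units added to the Type II
#'   background per chip row (vertical Sentrix position), making the
#'   Type I/II background offset vary smoothly with array position; 0
#'   disables the gradient.
#' @param noise_sd lognormal sd of per-cell multiplicative intensity noise.
#' @param theta_concentration Beta-distribution concentration of per-sample
#'   methylation fractions around each probe's true level (larger =
#'   tighter; \code{Inf} switches per-sample scatter off).
#' @param allele_freqs per-SNP alternate-allele frequencies; default drawn
#'   uniformly in (0.2, 0.8).
#' @param sex_ratio fraction of female samples, in (0, 1).
#' @param seed integer seed; every random component derives a fixed
#'   sub-seed from it.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simConfig <- function(n_samples = 20L, n_autosomal = 20000L, n_idmr = 237L,
                      n_snp = 65L, n_x = 800L, frac_type2 = 0.72,
                      intensity_mean = 4000, background_type1 = 400,
                      background_type2 = 1000, background_sd = 0.2,
                      background_sample_sd = 0.3,
                      dye_bias_type2 = 1.15, dye_bias_sd = 0.15,
                      sample_scale_sd = 0.15, meth_shift_sd = 0.15,
                      chip_row_gradient = 0,
                      noise_sd = 0.1, theta_concentration = 100,
                      allele_freqs = NULL, sex_ratio = 0.5, seed = 1L) {
    cfg <- list(n_samples = as.integer(n_samples),
                n_autosomal = as.integer(n_autosomal),
                n_idmr = as.integer(n_idmr), n_snp = as.integer(n_snp),
                n_x = as.integer(n_x), frac_type2 = frac_type2,
                intensity_mean = intensity_mean,
                background_type1 = background_type1,
                background_type2 = background_type2,
                background_sd = background_sd,
                background_sample_sd = background_sample_sd,
                dye_bias_type2 = dye_bias_type2, dye_bias_sd = dye_bias_sd,
                sample_scale_sd = sample_scale_sd,
                meth_shift_sd = meth_shift_sd,
                chip_row_gradient = chip_row_gradient, noise_sd = noise_sd,
                theta_concentration = theta_concentration,
                allele_freqs = allele_freqs, sex_ratio = sex_ratio,
                seed = as.integer(seed))
    with(cfg, {
        stopifnot(n_samples >= 4L, n_autosomal >= 1L, n_idmr >= 0L,
                  n_snp >= 0L, n_x >= 0L,
                  frac_type2 > 0, frac_type2 < 1,
                  intensity_mean > 0, background_type1 >= 0,
                  background_type2 >= 0, background_sd >= 0,
                  background_sample_sd >= 0,
                  dye_bias_type2 > 0, dye_bias_sd >= 0,
                  sample_scale_sd >= 0, meth_shift_sd >= 0, noise_sd >= 0,
                  theta_concentration > 0,
                  sex_ratio > 0, sex_ratio < 1)
    })
    if (!is.null(cfg$allele_freqs)) {
        stopifnot(length(cfg$allele_freqs) == cfg$n_snp,
                  all(cfg$allele_freqs > 0), all(cfg$allele_freqs < 1))
    }
    class(cfg) <- "SimulationConfig"
    cfg
}

## fixed sub-seed per random component, all below 2^31
.sub_seed <- function(seed, k) (abs(seed) %% 1000003L) * 1000L + k

#' Simulate a synthetic methylation array dataset
#'
#' Draws per-probe true methylation fractions (bimodal autosomal mixture
#' with a small intermediate component; iDMR probes at 0.5; SNP probes at
#' 0/0.5/1 by Hardy-Weinberg genotype; X probes averaging the active and
#' largely methylated inactive X in females, with a 20% XCI-escape fraction
#' showing no sex difference), adds per-sample Beta-distributed scatter,
#' per-sample methylation-balance shifts, and converts to
#' intensities: M = theta * T * e_M + b_M, U = (1 - theta) * T * d * e_U +
#' b_U, where T is the per-sample-scaled total intensity, e_M and e_U are
#' independent lognormal per-cell channel noises, b the assay-type
#' background (with per-sample level, optional chip-row gradient and
#' lognormal per-cell spread) and d the per-sample Type II dye-bias
#' multiplier.  Fully reproducible from
#' \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A list with elements \code{dataset} (a
#'   \linkS4class{MethylIntensitySet}) and \code{truth} (true methylation
#'   matrix, genotypes, sexes, per-sample scales and dye factors, the
#'   background levels, and the config).
#' @export
simulateDataset <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    cf <- config
    n <- cf$n_samples
    p <- cf$n_autosomal + cf$n_idmr + cf$n_snp + cf$n_x

    ## --- probe annotation -------------------------------------------------
    set.seed(.sub_seed(cf$seed, 1L))
    category <- rep(c("autosomal", "idmr", "snp", "x"),
                    c(cf$n_autosomal, cf$n_idmr, cf$n_snp, cf$n_x))
    probe_id <- ifelse(category == "snp",
                       sprintf("rs%07d", seq_len(p)),
                       sprintf("cg%07d", seq_len(p)))
    assay_type <- ifelse(stats::runif(p) < cf$frac_type2, "II", "I")
    channel <- ifelse(assay_type == "II", "Both",
                      sample(c("Red", "Grn"), p, replace = TRUE))
    chromosome <- ifelse(category == "x", "X",
                         as.character(sample.int(22L, p, replace = TRUE)))

    ## --- sample annotation ------------------------------------------------
    set.seed(.sub_seed(cf$seed, 2L))
    sample_id <- sprintf("S%03d", seq_len(n))
    n_female <- max(2L, min(n - 2L, round(cf$sex_ratio * n)))
    sex <- rep("male", n)
    sex[sample.int(n, n_female)] <- "female"
    slot_on_chip <- (seq_len(n) - 1L) %% 12L
    sample_data <- data.frame(
        Sex = sex,
        ChipID = sprintf("chip%d", (seq_len(n) - 1L) %/% 12L + 1L),
        ChipRow = as.integer(slot_on_chip %% 6L + 1L),
        ChipCol = as.integer(slot_on_chip %/% 6L + 1L),
        row.names = sample_id)

    ## --- true methylation fractions ---------------------------------------
    set.seed(.sub_seed(cf$seed, 3L))
    theta0 <- numeric(p)
    auto <- category == "autosomal"
    comp <- sample(c("low", "mid", "high"), sum(auto), replace = TRUE,
                   prob = c(0.45, 0.10, 0.45))
    theta0[auto][comp == "low"] <- stats::rbeta(sum(comp == "low"), 1.5, 60)
    theta0[auto][comp == "mid"] <- stats::rbeta(sum(comp == "mid"), 5, 5)
    theta0[auto][comp == "high"] <- stats::rbeta(sum(comp == "high"), 60, 1.5)
    theta0[category == "idmr"] <- 0.5
    ## X probes: males carry one active X whose methylation varies by locus
    ## (bimodal, like autosomes); in females the inactive X is largely
    ## methylated at XCI-influenced loci, so the female level is the
    ## active/inactive average, while XCI-escape loci show no sex
    ## difference.  Sex differences therefore range from large (active X
    ## unmethylated) to nil (escape or already-methylated loci).
    x_idx <- which(category == "x")
    nx <- length(x_idx)
    xcomp <- sample(c("low", "mid", "high"), nx, replace = TRUE,
                    prob = c(0.45, 0.10, 0.45))
    male_x <- numeric(nx)
    male_x[xcomp == "low"] <- stats::rbeta(sum(xcomp == "low"), 1.5, 60)
    male_x[xcomp == "mid"] <- stats::rbeta(sum(xcomp == "mid"), 5, 5)
    male_x[xcomp == "high"] <- stats::rbeta(sum(xcomp == "high"), 60, 1.5)
    escapes <- stats::runif(nx) < 0.2
    inactive_x <- stats::runif(nx, 0.65, 0.95)
    female_x <- ifelse(escapes, male_x, (male_x + inactive_x) / 2)

    set.seed(.sub_seed(cf$seed, 4L))
    freqs <- cf$allele_freqs
    if (is.null(freqs)) freqs <- stats::runif(cf$n_snp, 0.2, 0.8)
    genotypes <- matrix(stats::rbinom(cf$n_snp * n, 2L, rep(freqs, n)),
                        nrow = cf$n_snp,
                        dimnames = list(probe_id[category == "snp"],
                                        sample_id))

    theta <- matrix(theta0, nrow = p, ncol = n,
                    dimnames = list(probe_id, sample_id))
    theta[category == "snp", ] <- genotypes / 2
    female <- sex == "female"
    theta[x_idx, female] <- female_x
    theta[x_idx, !female] <- male_x

    ## per-sample scatter around the true level, Beta-distributed so values
    ## stay inside [0, 1]
    set.seed(.sub_seed(cf$seed, 5L))
    kappa <- cf$theta_concentration
    tc <- pmin(pmax(theta, 0.005), 0.995)
    theta_obs <- if (is.finite(kappa))
        matrix(stats::rbeta(p * n, tc * kappa, (1 - tc) * kappa),
               nrow = p, dimnames = dimnames(theta))
    else theta
    ## per-sample methylation-balance shift (conversion/extension efficiency)
    meth_shift_j <- stats::rnorm(n, 0, cf$meth_shift_sd)
    if (cf$meth_shift_sd > 0)
        theta_obs <- stats::plogis(stats::qlogis(pmin(pmax(theta_obs, 1e-6),
                                                      1 - 1e-6)) +
                                   matrix(rep(meth_shift_j, each = p),
                                          nrow = p))

    ## --- intensities -------------------------------------------------------
    set.seed(.sub_seed(cf$seed, 6L))
    scale_j <- exp(stats::rnorm(n, 0, cf$sample_scale_sd))
    bg_scale_j <- exp(stats::rnorm(n, 0, cf$background_sample_sd))
    dye_j <- cf$dye_bias_type2 * exp(stats::rnorm(n, 0, cf$dye_bias_sd))
    total <- cf$intensity_mean * matrix(rep(scale_j, each = p), nrow = p)
    noise_m <- exp(matrix(stats::rnorm(p * n, 0, cf$noise_sd), nrow = p))
    noise_u <- exp(matrix(stats::rnorm(p * n, 0, cf$noise_sd), nrow = p))
    bg_level <- ifelse(assay_type == "II", cf$background_type2,
                       cf$background_type1)
    grad <- cf$chip_row_gradient *
        matrix(rep(sample_data$ChipRow - 1L, each = p), nrow = p)
    grad[assay_type != "II", ] <- 0
    bg_level <- (matrix(bg_level, nrow = p, ncol = n) + grad) *
        matrix(rep(bg_scale_j, each = p), nrow = p)
    bM <- bg_level * exp(matrix(stats::rnorm(p * n, 0, cf$background_sd),
                                nrow = p))
    bU <- bg_level * exp(matrix(stats::rnorm(p * n, 0, cf$background_sd),
                                nrow = p))
    dye <- matrix(1, nrow = p, ncol = n)
    dye[assay_type == "II", ] <- matrix(rep(dye_j, each = sum(assay_type == "II")),
                                        nrow = sum(assay_type == "II"))
    m <- theta_obs * total * noise_m + bM
    u <- (1 - theta_obs) * total * dye * noise_u + bU
    m[m < 0] <- 0
    u[u < 0] <- 0
    dimnames(m) <- dimnames(u) <- list(probe_id, sample_id)

    probe_data <- data.frame(
        AssayType = assay_type, Chromosome = chromosome, Channel = channel,
        IsSNP = category == "snp", IsIDMR = category == "idmr",
        row.names = probe_id)
    dataset <- MethylIntensitySet(m, u, probeData = probe_data,
                                  sampleData = sample_data)
    truth <- list(theta = theta, theta_observed = theta_obs,
                  genotypes = genotypes, sex = sex,
                  sample_scale = stats::setNames(scale_j, sample_id),
                  meth_shift = stats::setNames(meth_shift_j, sample_id),
                  background_scale = stats::setNames(bg_scale_j, sample_id),
                  dye_factor = stats::setNames(dye_j, sample_id),
                  background_type1 = cf$background_type1,
                  background_type2 = cf$background_type2,
                  chip_row_gradient = cf$chip_row_gradient,
                  allele_freqs = freqs, config = cf)
    list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset as a text fixture
#'
#' Emits the file set \code{\link{readIntensities}} consumes —
#' \code{methylated.tsv}, \code{unmethylated.tsv}, \code{manifest.tsv},
#' \code{samplesheet.tsv} — plus ground-truth tables
#' (\code{truth_samples.csv}, \code{truth_theta.tsv}).
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
writeFixture <- function(sim, dir) {
    stopifnot(is.list(sim), !is.null(sim$dataset))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ds <- sim$dataset
    .write_intensity_tsv(methylated(ds), file.path(dir, "methylated.tsv"))
    .write_intensity_tsv(unmethylated(ds), file.path(dir, "unmethylated.tsv"))
    rd <- as.data.frame(rowData(ds))
    utils::write.table(
        cbind(ProbeID = rownames(ds), rd),
        file.path(dir, "manifest.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(colData(ds))
    utils::write.table(
        cbind(SampleID = colnames(ds), cd),
        file.path(dir, "samplesheet.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$truth)) {
        tr <- sim$truth
        utils::write.csv(
            data.frame(SampleID = colnames(ds), Sex = tr$sex,
                       SampleScale = tr$sample_scale,
                       DyeFactor = tr$dye_factor),
            file.path(dir, "truth_samples.csv"), row.names = FALSE)
        .write_intensity_tsv(round(tr$theta, 6),
                             file.path(dir, "truth_theta.tsv"))
    }
    invisible(dir)
}

.write_intensity_tsv <- function(mat, path) {
    df <- data.frame(ProbeID = rownames(mat),
                     format(round(mat, 6), trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
    colnames(df) <- c("ProbeID", colnames(mat))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
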