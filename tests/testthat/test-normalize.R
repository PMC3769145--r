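test_that("beta and M-value arithmetic matches the closed forms", {
    expect_equal(computeBeta(matrix(900), unmeth = matrix(0)), matrix(0.9))
    expect_equal(computeBeta(matrix(0), unmeth = matrix(0)), matrix(0))
    expect_equal(computeBeta(matrix(450), unmeth = matrix(450)),
                 matrix(0.45))
    expect_error(computeBeta(matrix(0), alpha = 0, unmeth = matrix(0)),
                 "undefined beta")

    expect_equal(beta2m(0.5), 0)
    expect_equal(beta2m(0.8), 2)
    expect_equal(beta2m(0.2), -2)
    expect_error(beta2m(1), "strictly inside")
    b <- runif(20, 0.01, 0.99)
    expect_equal(m2beta(beta2m(b)), b)

    expect_equal(intensityToM(300, 300), 0)
    expect_equal(intensityToM(700, 100), 2)
    expect_equal(intensityToM(0, 0), 0)
})

test_that("quantile normalization matches the closed forms and the oracle", {
    x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
    got <- quantileNormalize(x)
    expect_equal(unname(got), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

    same <- cbind(c(3, 1, 2), c(3, 1, 2))
    expect_equal(quantileNormalize(same), same)

    expect_error(quantileNormalize(matrix(1:3)), ">= 2 columns")
    expect_error(quantileNormalize(cbind(c(1, NA), c(2, 3))), "finite")

    set.seed(101)
    for (i in 1:25) {
        m <- matrix(rnorm(50 * 5), 50, 5)
        expect_lt(max(abs(quantileNormalize(m) - qn_oracle(m))), 1e-12)
    }
    ## with ties
    for (i in 1:10) {
        m <- matrix(sample(1:8, 60, replace = TRUE), 20, 3)
        expect_lt(max(abs(quantileNormalize(m) - qn_oracle(m))), 1e-12)
    }
})

test_that("quantile normalization agrees with limma on tie-free data", {
    skip_if_not_installed("limma")
    set.seed(77)
    m <- matrix(rexp(200 * 6), 200, 6)
    expect_equal(unname(quantileNormalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("grouped QN respects groups and the M/U join", {
    set.seed(5)
    x <- matrix(rnorm(40), 20, 2)
    groups <- rep(c("I", "II"), each = 10)
    got <- quantileNormalizeGrouped(x, groups)
    expect_equal(got[1:10, ], quantileNormalize(x[1:10, ]))
    expect_equal(got[11:20, ], quantileNormalize(x[11:20, ]))

    ## degenerate grouping = plain QN
    expect_equal(quantileNormalizeGrouped(x, rep(1, 20)),
                 quantileNormalize(x))

    ## joined M/U: columns concatenated before QN, split after
    m <- matrix(c(1, 3, 5, 7), 2)
    u <- matrix(c(2, 4, 6, 8), 2)
    res <- quantileNormalizeGrouped(m, join = u)
    ref <- qn_oracle(cbind(m, u))
    expect_equal(res$x, ref[, 1:2])
    expect_equal(res$join, ref[, 3:4])

    expect_warning(quantileNormalizeGrouped(x, c("solo", rep("g", 19))),
                   "single row")
    expect_error(quantileNormalizeGrouped(x, groups, join = x[1:10, ]),
                 "shape")
})

test_that("background offsets recover constructed Type I/II peaks", {
    set.seed(11)
    n <- 6
    probes <- paste0("p", 1:400)
    type <- rep(c("I", "II"), each = 200)
    ## background-only probes clustered at 100 (I) and 400 (II) plus a
    ## high-intensity signal mass in both types
    mk <- function() {
        m <- rbind(matrix(rnorm(150 * n, 100, 10), 150),
                   matrix(rnorm(50 * n, 4000, 300), 50),
                   matrix(rnorm(150 * n, 400, 10), 150),
                   matrix(rnorm(50 * n, 4000, 300), 50))
        m[m < 0] <- 0
        dimnames(m) <- list(probes, paste0("s", 1:n))
        m
    }
    pd <- data.frame(AssayType = type, Chromosome = "1",
                     Channel = ifelse(type == "I", "Red", "Both"),
                     IsSNP = FALSE, IsIDMR = FALSE, row.names = probes)
    cd <- data.frame(Sex = "unknown", ChipID = "c",
                     ChipRow = rep(1:3, 2), ChipCol = rep(1:2, each = 3),
                     row.names = paste0("s", 1:n))
    ds <- MethylIntensitySet(mk(), mk(), pd, cd)
    off <- estimateBackgroundOffsets(ds)
    step <- max(attr(off, "gridStep"))
    expect_true(all(abs(off$offset - 300) <= step + 10))

    ## identically distributed types -> offset about 0
    pd2 <- pd
    pd2$AssayType <- rep(c("I", "II"), 200)
    pd2$Channel <- ifelse(pd2$AssayType == "I", "Red", "Both")
    ds2 <- MethylIntensitySet(mk(), mk(), pd2, cd)
    off2 <- estimateBackgroundOffsets(ds2)
    expect_true(all(abs(off2$offset) <= max(attr(off2, "gridStep")) * 2))

    ## smoothing needs chip positions
    cd_na <- cd; cd_na$ChipRow <- NA_integer_; cd_na$ChipCol <- NA_integer_
    ds3 <- MethylIntensitySet(mk(), mk(), pd, cd_na)
    expect_error(estimateBackgroundOffsets(ds3, smoothByPosition = TRUE),
                 "ChipRow")
})

test_that("equalizeBackground shifts Type I only and clips at zero", {
    ds <- make_toy_mset()
    off <- expand.grid(sample = colnames(ds),
                       channel = c("methylated", "unmethylated"),
                       stringsAsFactors = FALSE)
    off$offset <- 300
    eq <- equalizeBackground(ds, off)
    typeI <- rowData(ds)$AssayType == "I"
    expect_equal(methylated(eq)[typeI, ], methylated(ds)[typeI, ] + 300)
    expect_equal(methylated(eq)[!typeI, ], methylated(ds)[!typeI, ])

    off$offset <- 0
    expect_equal(methylated(equalizeBackground(ds, off)), methylated(ds))

    ## negative offsets clip at zero
    off$offset <- -1e6
    eq2 <- equalizeBackground(ds, off)
    expect_true(all(methylated(eq2)[typeI, ] == 0))

    expect_error(equalizeBackground(ds, off[off$sample != "s2", ]),
                 "missing")
})

test_that("equalization drives re-estimated offsets to zero", {
    sim <- small_sim(seed = 2)
    off <- estimateBackgroundOffsets(sim$dataset)
    expect_gt(mean(off$offset), 0)  # Type II background inflation
    eq <- equalizeBackground(sim$dataset, off)
    off2 <- estimateBackgroundOffsets(eq)
    expect_true(all(abs(off2$offset) <= max(attr(off2, "gridStep")) * 1.5))
})

test_that("applyMethod dispatches the registry correctly", {
    ds <- make_toy_mset()
    expect_error(applyMethod(ds, "nosuch"), "raw.*dasen")
    expect_equal(sort(normMethods()),
                 sort(c("raw", "betaqn", "naten", "nanet", "nanes", "danes",
                        "danet", "danen", "daten1", "daten2", "nasen",
                        "dasen")))

    ## raw is exactly computeBeta
    expect_equal(betas(applyMethod(ds, "raw")), betas(computeBeta(ds)))

    ## every method stays in [0, 1]
    sim <- small_sim(seed = 3)
    for (m in normMethods()) {
        b <- betas(applyMethod(sim$dataset, m))
        expect_true(all(b >= 0 & b <= 1), info = m)
    }
})

test_that("naten equals betas of hand-quantile-normalized M and U", {
    ds <- make_toy_mset()
    mq <- qn_oracle(methylated(ds))
    uq <- qn_oracle(unmethylated(ds))
    expect_equal(betas(applyMethod(ds, "naten")), mq / (mq + uq + 100),
                 tolerance = 1e-12)
})

test_that("dasen reduces to raw when nothing needs normalizing", {
    ## two samples with identical per-channel distributions within each
    ## stratum and no Type I/II background difference
    probes <- paste0("p", 1:40)
    type <- rep(c("I", "II"), each = 20)
    base_m <- c(seq(50, 800, length.out = 15), seq(2000, 6000, length.out = 5))
    base_u <- rev(c(seq(60, 820, length.out = 15),
                    seq(2100, 6100, length.out = 5)))
    m <- cbind(s1 = c(base_m, base_m), s2 = c(sample(base_m), sample(base_m)))
    u <- cbind(s1 = c(base_u, base_u), s2 = c(sample(base_u), sample(base_u)))
    rownames(m) <- rownames(u) <- probes
    pd <- data.frame(AssayType = type, Chromosome = "1",
                     Channel = ifelse(type == "I", "Red", "Both"),
                     IsSNP = FALSE, IsIDMR = FALSE, row.names = probes)
    cd <- data.frame(Sex = "unknown", ChipID = "c", ChipRow = 1:2,
                     ChipCol = 1L, row.names = c("s1", "s2"))
    ds <- MethylIntensitySet(m, u, pd, cd)
    ## identical value multisets in both strata: offsets are exactly zero
    off <- estimateBackgroundOffsets(ds)
    expect_equal(off$offset, rep(0, 4))
    got <- betas(applyMethod(ds, "dasen"))
    raw <- betas(applyMethod(ds, "raw"))
    expect_equal(got, raw, tolerance = 1e-10)
})

test_that("QN-bearing methods equalise array-wide distributions", {
    sim <- small_sim(seed = 6)
    b <- betas(applyMethod(sim$dataset, "betaqn"))
    srt <- apply(b, 2, sort)
    expect_true(all(abs(srt - srt[, 1]) < 1e-12))
    ## betaqn preserves within-sample rank order of beta
    raw <- betas(applyMethod(sim$dataset, "raw"))
    for (j in 1:3)
        expect_equal(order(b[, j]), order(raw[, j]))
})
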