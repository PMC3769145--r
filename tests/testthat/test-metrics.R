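test_that("dmrse matches its closed forms and 1/sqrt(n) scaling", {
    const <- matrix(0.5, 5, 4)
    expect_equal(dmrse(const, idmr = rep(TRUE, 5)), 0)

    b <- matrix(c(0.4, 0.4, 0.6, 0.6), 2)  # 2 probes x 2 samples
    expect_equal(dmrse(b, idmr = c(TRUE, TRUE)), sd(c(0.4, 0.4, 0.6, 0.6)) / sqrt(2))
    expect_equal(dmrse(b, idmr = c(TRUE, TRUE)), 0.0816497, tolerance = 1e-6)

    ## duplicating every sample column leaves the pooled sd unchanged and
    ## scales the metric by 1/sqrt(2)
    set.seed(3)
    m <- matrix(runif(30, 0.4, 0.6), 5, 6)
    ## exact up to the n-1 vs 2n-1 sample-variance denominators
    expect_equal(dmrse(cbind(m, m), idmr = rep(TRUE, 5)),
                 dmrse(m, idmr = rep(TRUE, 5)) / sqrt(2), tolerance = 0.02)

    expect_error(dmrse(m, idmr = rep(FALSE, 5)), "no iDMR")

    ## alternative modes exist and differ in general
    expect_gt(dmrse(m, rep(TRUE, 5), mode = "row"), 0)
    expect_gt(dmrse(m, rep(TRUE, 5), mode = "col"), 0)
})

test_that("gcose matches the worked trimodal examples", {
    ## perfect trimodal clusters: zero width, zero score
    perfect <- matrix(rep(c(0, 0.5, 1), each = 2), 4, 6, byrow = TRUE)
    g <- gcose(perfect, snp = rep(TRUE, 4))
    expect_equal(unname(g$by_group), c(0, 0, 0))
    expect_equal(g$gcose, 0)

    ## 1 SNP, 6 samples: per-cluster SS 0.005, n 2 -> MS 0.0025,
    ## score 0.0025/sqrt(6), GCOSE the mean of three equal scores
    one <- matrix(c(0.05, 0.15, 0.45, 0.55, 0.85, 0.95), 1)
    g1 <- gcose(one, snp = TRUE)
    expect_equal(unname(g1$by_group), rep(0.0025 / sqrt(6), 3))
    expect_lt(abs(g1$gcose - 0.0010206), 1e-6)
    expect_equal(g1$gcose, 0.0025 / sqrt(6))

    ## invariant to sample order
    perm <- one[, c(4, 2, 6, 1, 3, 5), drop = FALSE]
    expect_equal(gcose(perm, snp = TRUE)$gcose, g1$gcose)

    expect_error(gcose(one, snp = FALSE), "no SNP")
})

test_that("gcose grows monotonically with cluster noise", {
    set.seed(8)
    base <- matrix(rep(c(rep(0.02, 6), rep(0.5, 6), rep(0.98, 6)), 10),
                   10, 18, byrow = TRUE)
    noise <- matrix(rnorm(180), 10, 18)
    vals <- sapply(c(0.005, 0.02, 0.05), function(s) {
        b <- pmin(pmax(base + s * noise, 0), 1)
        gcose(b, snp = rep(TRUE, 10))$gcose
    })
    expect_true(all(diff(vals) > 0))
})

test_that("degenerate SNP probes contribute only the clusters they form", {
    ## one constant probe plus one well-behaved probe
    b <- rbind(rep(0.5, 6), c(0.02, 0.05, 0.5, 0.52, 0.95, 0.98))
    g <- gcose(b, snp = c(TRUE, TRUE))
    expect_true(all(is.finite(g$by_group)))
    expect_equal(g$gcose, mean(g$by_group))
})

test_that("sex-difference p-values match the t.test oracle", {
    set.seed(21)
    b <- matrix(runif(80), 10, 8)
    sex <- rep(c("male", "female"), each = 4)
    p <- sexDifferencePvalues(b, sex)
    for (i in 1:10) {
        ref <- t.test(b[i, 1:4], b[i, 5:8])$p.value
        expect_equal(unname(p[i]), ref, tolerance = 1e-8)
    }
    ## pooled-variance option
    p2 <- sexDifferencePvalues(b, sex, var.equal = TRUE)
    ref2 <- t.test(b[3, 1:4], b[3, 5:8], var.equal = TRUE)$p.value
    expect_equal(unname(p2[3]), ref2, tolerance = 1e-8)

    ## degenerate probes
    b[1, ] <- 0.5
    b[2, ] <- rep(c(0.2, 0.8), each = 4)
    p <- sexDifferencePvalues(b, sex)
    expect_equal(unname(p[1]), 1)
    expect_equal(unname(p[2]), 0)

    ## complete separation with decent n -> tiny p
    big <- rbind(rep(c(0.1, 0.9), each = 10))
    expect_lt(sexDifferencePvalues(big, rep(c("male", "female"), each = 10))[1],
              1e-6)

    expect_error(sexDifferencePvalues(b, rep("male", 8)), "redundant")
})

test_that("seabird matches brute-force AUC and its symmetries", {
    ## perfect predictor: every X probe more significant than every other
    p <- c(1e-5, 1e-4, 0.2, 0.4, 0.9)
    chrom <- c("X", "X", "1", "2", "3")
    expect_equal(seabird(NULL, chromosomes = chrom, pvalues = p), 0)

    ## the 4-probe toy: X probes at the two smallest p-values
    p4 <- c(0.0011, 0.2, 0.012, 0.9)
    c4 <- c("X", "1", "X", "2")
    expect_equal(seabird(NULL, chromosomes = c4, pvalues = p4),
                 1 - auc_bruteforce(-p4, c4 == "X"))
    expect_equal(seabird(NULL, chromosomes = c4, pvalues = p4), 0)

    ## random fixtures against the all-pairs oracle, including ties
    set.seed(13)
    for (i in 1:20) {
        np <- sample(20:60, 1)
        pv <- round(runif(np), 2)
        ch <- sample(c("X", "1", "7"), np, replace = TRUE,
                     prob = c(0.3, 0.35, 0.35))
        if (!any(ch == "X") || all(ch == "X")) next
        expect_equal(seabird(NULL, chromosomes = ch, pvalues = pv),
                     1 - auc_bruteforce(-pv, ch == "X"), tolerance = 1e-12)
    }

    ## antisymmetry: negating the score flips AUC
    pv <- runif(30)
    ch <- rep(c("X", "2"), 15)
    a <- 1 - seabird(NULL, chromosomes = ch, pvalues = pv)
    a_flip <- 1 - seabird(NULL, chromosomes = ch, pvalues = -pv + 1e-9 +
                              max(pv))
    expect_equal(a_flip, 1 - a, tolerance = 1e-12)

    expect_error(seabird(NULL, chromosomes = rep("X", 4),
                         pvalues = runif(4)), "both X and non-X")
})

test_that("Y probes can be excluded from the Seabird negatives", {
    ## the Y probe outranks both X probes, so it drags the AUC down only
    ## while it is counted among the negatives
    p <- c(0.002, 0.003, 0.5, 0.001)
    ch <- c("X", "X", "1", "Y")
    with_y <- seabird(NULL, chromosomes = ch, pvalues = p)
    no_y <- seabird(NULL, chromosomes = ch, pvalues = p, excludeY = TRUE)
    expect_equal(no_y, 0)
    expect_equal(with_y, 0.5)
})

test_that("evaluateMetrics composes the per-type reports", {
    sim <- small_sim(seed = 5)
    bs <- applyMethods(sim$dataset, methods = c("raw", "dasen"))
    rep <- evaluateMetrics(bs, datasetId = "d1")
    expect_equal(nrow(rep), 4L)  # 2 methods x 2 types
    expect_setequal(rep$assay_type, c("I", "II"))
    expect_equal(rep$gcose, rowMeans(rep[, c("gcose_BB", "gcose_AB",
                                             "gcose_AA")]))

    ## reports match direct single calls on the subsets
    rd <- rowData(sim$dataset)
    typeI <- rd$AssayType == "I"
    raw <- bs$raw[typeI, ]
    row <- rep[rep$method == "raw" & rep$assay_type == "I", ]
    expect_equal(row$dmrse, dmrse(raw))
    expect_equal(row$gcose, gcose(raw)$gcose)
    expect_equal(row$seabird, seabird(raw))
})

test_that("metrics are invariant to probe and sample reordering", {
    sim <- small_sim(seed = 9)
    b <- applyMethod(sim$dataset, "raw")
    ip <- sample(nrow(b)); is_ <- sample(ncol(b))
    b2 <- b[ip, is_]
    expect_equal(dmrse(b2), dmrse(b))
    expect_equal(gcose(b2)$gcose, gcose(b)$gcose)
    expect_equal(seabird(b2), seabird(b))
})

test_that("single-sex data records Seabird as missing, not a crash", {
    sim <- small_sim(seed = 10)
    ds <- sim$dataset
    cd <- as.data.frame(colData(ds))
    cd$Sex <- "male"
    ds2 <- MethylIntensitySet(methylated(ds), unmethylated(ds),
                              rowData(ds), cd)
    bs <- applyMethods(ds2, methods = "raw")
    warns <- capture_warnings(rep <- evaluateMetrics(bs, "d"))
    expect_length(warns, 2)  # one per assay type
    expect_match(warns, "seabird", all = TRUE)
    expect_true(all(is.na(rep$seabird)))
    expect_true(all(is.finite(rep$dmrse)))
})
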