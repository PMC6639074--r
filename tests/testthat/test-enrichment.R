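makeIntensity <- function(m, design, logScale = FALSE)
    IntensityMatrix(m, design, logScale = logScale)

test_that("log transform maps zeros to missing and refuses double application", {
    design <- makeDesign(2, 3)
    m <- matrix(c(1024, 0, 2, 8, 0, 1), 1, 6,
                dimnames = list("P1", sampleIds(design)))
    im <- makeIntensity(m, design)
    lg <- logTransform(im)
    v <- SummarizedExperiment::assay(lg)[1, ]
    expect_equal(unname(v[1]), 10)
    expect_true(is.na(v[2]))
    expect_equal(unname(v[6]), 0)  # intensity 1 -> log2 = 0, still "detected"
    expect_true(lg@logScale)
    expect_error(logTransform(lg), "already")
})

test_that("minimum-valid filter reproduces the enumerated survivor set", {
    design <- makeDesign(3, 3)
    ## validity patterns per bait: (3,0,0) (2,1,0) (1,1,1) (0,0,0) (2,2,2)
    pat <- list(c(3, 0, 0), c(2, 1, 0), c(1, 1, 1), c(0, 0, 0), c(2, 2, 2))
    m <- matrix(NA_real_, 5, 9,
                dimnames = list(paste0("P", 1:5), sampleIds(design)))
    for (i in seq_along(pat))
        for (b in 1:3) {
            k <- pat[[i]][b]
            if (k > 0) m[i, (b - 1) * 3 + seq_len(k)] <- 20 + i
        }
    lg <- makeIntensity(m, design, logScale = TRUE)
    out <- filterMinValid(lg, minValid = 2)
    expect_setequal(rownames(out), c("P1", "P2", "P5"))
    ## idempotent
    expect_identical(rownames(filterMinValid(out, 2)), rownames(out))
    ## exhaustive check of all 3-bait validity patterns against the rule
    pats <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
    m2 <- matrix(NA_real_, nrow(pats), 9,
                 dimnames = list(sprintf("Q%02d", seq_len(nrow(pats))),
                                 sampleIds(design)))
    for (i in seq_len(nrow(pats)))
        for (b in 1:3) {
            k <- pats[i, b]
            if (k > 0) m2[i, (b - 1) * 3 + seq_len(k)] <- 25
        }
    keep <- filterMinValid(makeIntensity(m2, design, logScale = TRUE), 2)
    expectKeep <- apply(pats, 1L, function(r) any(r >= 2))
    expect_setequal(rownames(keep), rownames(m2)[expectKeep])
    ## min_valid beyond every bait's replicate count
    expect_error(filterMinValid(lg, 4), "replicate")
})

test_that("downshift imputation has the stated moments and determinism", {
    design <- makeDesign(2, 3)
    ## large column: many missing entries, observed mean 25 sd 2
    nPrey <- 20000
    withr::local_seed(5)
    obs <- rnorm(nPrey, 25, 2)
    m <- matrix(rep(obs, 6), nPrey, 6,
                dimnames = list(paste0("P", seq_len(nPrey)),
                                sampleIds(design)))
    m[seq_len(nPrey / 2), 1] <- NA  # half the first column missing
    lg <- makeIntensity(m, design, logScale = TRUE)
    imp <- imputeDownshift(lg, seed = 99)
    x <- SummarizedExperiment::assay(imp)
    expect_false(anyNA(x))
    ## observed entries bit-identical
    expect_identical(x[!is.na(m)], m[!is.na(m)])
    obsCol <- m[-seq_len(nPrey / 2), 1]
    filled <- x[seq_len(nPrey / 2), 1]
    expect_equal(mean(filled), mean(obsCol) - 1.8 * sd(obsCol),
                 tolerance = 0.02)
    expect_equal(sd(filled), 0.3 * sd(obsCol), tolerance = 0.02)
    ## same seed -> identical matrices; complete column untouched
    imp2 <- imputeDownshift(lg, seed = 99)
    expect_identical(x, SummarizedExperiment::assay(imp2))
    expect_identical(x[, 2], m[, 2])
    ## a column with < 2 observed values is an error naming it
    bad <- matrix(25, 3, 6, dimnames = list(c("a", "b", "c"),
                                            sampleIds(design)))
    bad[, 3] <- NA; bad[1, 3] <- 21
    expect_error(imputeDownshift(makeIntensity(bad, design, logScale = TRUE)),
                 "BAIT1_r3")
})

test_that("contrast construction pools GDP backgrounds as specified", {
    pd <- makePairedDesign(17, 3)
    cts <- buildContrasts(pd)
    expect_length(cts, 34L)
    gtp <- Filter(function(ct) grepl("pooledGDP", ct@label), cts)
    gdp <- Filter(function(ct) grepl("otherGDP", ct@label), cts)
    expect_length(gtp, 17L)
    for (ct in gtp) {
        expect_length(ct@testSamples, 3L)
        expect_length(ct@backgroundSamples, 51L)
    }
    for (ct in gdp) expect_length(ct@backgroundSamples, 48L)
    ## GTP background includes the same GTPase's GDP replicates
    ct1 <- gtp[[1]]
    ownGdp <- sub("_GTP$", "_GDP", ct1@testBait)
    expect_true(all(replicateSamples(pd, ownGdp) %in% ct1@backgroundSamples))

    pd3 <- makePairedDesign(3, 3)
    cts3 <- buildContrasts(pd3)
    expect_equal(sort(unique(vapply(cts3, function(ct)
        length(ct@backgroundSamples), integer(1)))), c(6L, 9L))

    ## fewer than two GDP baits: no pooled background possible
    expect_error(buildContrasts(makeDesign(3, 3, states = c("GTP", "GTP", "GDP"))),
                 "GDP")
    ## control baits receive no contrast
    pdc <- makeDesign(4, 3, states = c("GTP", "GDP", "GDP", "NONE"),
                      baitNames = c("A", "B", "C", "CTRL"))
    expect_false("CTRL" %in% vapply(buildContrasts(pdc),
                                    function(ct) ct@testBait, character(1)))
})

test_that("two-sample t test matches hand evaluation and stats::t.test", {
    r <- twoSampleTest(c(10, 11, 12), c(8, 9, 10))
    expect_equal(r$log2fc, 2)
    expect_equal(r$t_stat, 2.449, tolerance = 1e-3)
    expect_equal(r$p_value, 0.0705, tolerance = 1e-3)
    expect_equal(r$df, 4)
    ## cross-check against the standard implementation at s0 = 0
    withr::with_seed(3, {
        for (i in 1:10) {
            a <- rnorm(4, 25); b <- rnorm(6, 24)
            mine <- twoSampleTest(a, b)
            ref <- t.test(a, b, var.equal = TRUE)
            expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
            expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
        }
    })
    ## identical groups and degenerate zero-variance guard
    expect_equal(twoSampleTest(c(1, 2, 3), c(1, 2, 3))$t_stat, 0)
    expect_equal(twoSampleTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
    expect_equal(twoSampleTest(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
    d <- twoSampleTest(c(6, 6, 6), c(5, 5, 5))
    expect_equal(d$p_value, .Machine$double.xmin)
    ## s0 shrinks the statistic
    expect_lt(abs(twoSampleTest(c(10, 11, 12), c(8, 9, 10), s0 = 1)$t_stat),
              abs(r$t_stat))
    expect_error(twoSampleTest(1, c(1, 2)), "2 values")
})

test_that("permutation FDR equals brute-force enumeration on 3 vs 3", {
    design <- makeDesign(2, 3)
    withr::local_seed(21)
    m <- matrix(rnorm(12 * 6, 24, 1), 12, 6,
                dimnames = list(paste0("P", 1:12), sampleIds(design)))
    m[1, 1:3] <- m[1, 1:3] + 5  # one strong hit
    ct <- new("ContrastSpec", testBait = "BAIT1",
              testSamples = sampleIds(design)[1:3],
              backgroundSamples = sampleIds(design)[4:6],
              label = "BAIT1_vs_BAIT2")
    got <- permutationFDR(m, ct, nPerm = 250)
    want <- bruteFdr(m, 3)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    ## determinism under a seed on the sampling path
    big <- makeDesign(2, 6)
    mb <- matrix(rnorm(30 * 12, 24, 1), 30, 12,
                 dimnames = list(paste0("Q", 1:30), sampleIds(big)))
    ctb <- new("ContrastSpec", testBait = "BAIT1",
               testSamples = sampleIds(big)[1:6],
               backgroundSamples = sampleIds(big)[7:12], label = "b")
    f1 <- permutationFDR(mb, ctb, nPerm = 100, seed = 4)
    f2 <- permutationFDR(mb, ctb, nPerm = 100, seed = 4)
    expect_identical(f1, f2)
    ## FDR is monotone non-increasing in |t|
    tt <- abs(proxComp:::.rowTests(mb, 1:6, 7:12, 0)$t_stat)
    ord <- order(tt, decreasing = TRUE)
    expect_true(all(diff(f1[ord]) >= -1e-12))
    ## forcing the sampling path on a small instance warns
    expect_warning(permutationFDR(m, ct, nPerm = 50, seed = 1,
                                  method = "sample"), "replacement")
})

test_that("permutation FDR separates a real effect from exchangeable noise", {
    design <- makeDesign(4, 3)
    withr::local_seed(31)
    m <- matrix(rnorm(100 * 12, 24, 1), 100, 12,
                dimnames = list(paste0("P", 1:100), sampleIds(design)))
    m[1, 1:3] <- m[1, 1:3] + 8
    ct <- new("ContrastSpec", testBait = "BAIT1",
              testSamples = sampleIds(design)[1:3],
              backgroundSamples = sampleIds(design)[4:12], label = "c")
    fdr <- permutationFDR(m, ct, nPerm = 250, seed = 8)
    expect_lt(fdr["P1"], 0.05)
    ## null preys keep high FDR overall
    expect_gte(median(fdr[-1]), 0.5)
})

test_that("runEnrichment composes the branch and respects planted effects", {
    pd <- makePairedDesign(2, 3)
    withr::local_seed(41)
    base <- matrix(2^rnorm(60 * 12, 25, 0.5), 60, 12,
                   dimnames = list(paste0("P", 1:60), sampleIds(pd)))
    ## plant an 8-fold (3 log2 unit) effector on the first GTP bait
    tgt <- replicateSamples(pd, "G01_GTP")
    base["P1", tgt] <- base["P1", tgt] * 8
    im <- IntensityMatrix(base, pd)
    en <- runEnrichment(im, seed = 17, fdrMethod = "BH")
    hit <- en[en$bait_id == "G01_GTP" & en$prey_id == "P1", ]
    expect_equal(hit$log2fc, 3, tolerance = 0.5)
    expect_lt(hit$p_value, 1e-4)
    expect_equal(hit$n_test, 3L)
    expect_equal(hit$n_background, 6L)
    ## complete output: every contrast x surviving prey, finite log2fc
    expect_equal(nrow(en), 4L * 60L)
    expect_true(all(is.finite(en$log2fc)))
    expect_true(all(en$p_value > 0 & en$p_value <= 1))
    expect_true(all(en$fdr >= 0 & en$fdr <= 1))
    ## determinism of the full branch
    en2 <- runEnrichment(im, seed = 17, fdrMethod = "BH")
    expect_identical(en, en2)
    ## empty post-filter matrix gives an empty table
    sparse <- matrix(0, 3, 12, dimnames = list(c("a", "b", "c"),
                                               sampleIds(pd)))
    sparse[cbind(1:3, 1:3)] <- 100  # one valid value per prey at most
    expect_equal(nrow(runEnrichment(IntensityMatrix(sparse, pd))), 0L)
})

test_that("log2fc is invariant to replicate order within groups", {
    pd <- makePairedDesign(2, 3)
    withr::local_seed(51)
    m <- matrix(rnorm(20 * 12, 24, 1), 20, 12,
                dimnames = list(paste0("P", 1:20), sampleIds(pd)))
    ct <- buildContrasts(pd)[[1]]
    t1 <- proxComp:::.rowTests(m, match(ct@testSamples, colnames(m)),
                               match(ct@backgroundSamples, colnames(m)), 0)
    t2 <- proxComp:::.rowTests(m, match(rev(ct@testSamples), colnames(m)),
                               match(sample(ct@backgroundSamples),
                                     colnames(m)), 0)
    expect_equal(t1$log2fc, t2$log2fc, tolerance = 1e-12)
    expect_equal(t1$t_stat, t2$t_stat, tolerance = 1e-12)
})
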