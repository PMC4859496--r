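test_that("PAVA: textbook case, monotone passthrough, and max-min oracle", {
    expect_equal(pava(c(1, 3, 2)), c(1, 2.5, 2.5))
    expect_equal(pava(1:5), as.numeric(1:5))
    expect_equal(pava(numeric(0)), numeric(0))
    set.seed(420)
    for (i in 1:25) {
        v <- rnorm(8); w <- runif(8, 0.2, 3)
        expect_equal(pava(v, w), isotonicMaxMin(v, w), tolerance = 1e-10)
    }
    # unit weights also agree with stats::isoreg
    for (i in 1:10) {
        v <- rnorm(12)
        expect_equal(pava(v), isoreg(v)$yf, tolerance = 1e-10)
    }
})

test_that("monomorphic twin preserves depths exactly and zero error gives zero reads", {
    set.seed(421)
    d <- rep(c(1L, 0L), 25)
    tt <- matrix(rpois(200, 8), 4)
    rr <- matrix(0L, 4, 50); rr[1, 1] <- 2L
    grm <- tinyGrm(tt, rr, d)
    aeb <- matrix(1e-12, 4, 2)  # effectively error-free
    mono <- simulateMonomorphic(grm, aeb)
    expect_identical(totalReads(mono), totalReads(grm))
    expect_true(all(altReads(mono) == 0))
    aeb2 <- matrix(0.01, 4, 2)
    mono2 <- simulateMonomorphic(grm, aeb2)
    expect_identical(totalReads(mono2), totalReads(grm))
})

test_that("deconvolution: edge cases and CDF validity", {
    # no monomorphic screen-ins: F_p is the observed CDF, phi 0
    fp <- estimateFp(c(0.001, 0.01, 0.03), numeric(0))
    expect_equal(fp@phiHat, 0)
    expect_identical(fp@mPHat, 3L)
    expect_equal(fp@cdf, c(1, 2, 3) / 3)
    # monomorphic count >= observed: no evidence of polymorphism
    fp2 <- estimateFp(c(0.001), c(0.001, 0.002))
    expect_identical(fp2@mPHat, 0L)
    # CDF validity on random inputs
    set.seed(422)
    for (i in 1:20) {
        obs <- rbeta(sample(3:40, 1), 1, 50)
        mono <- rbeta(sample(0:20, 1), 1, 200)
        fp <- estimateFp(obs, mono)
        expect_true(all(diff(fp@cdf) >= -1e-12))
        expect_true(all(fp@cdf >= 0 & fp@cdf <= 1))
        expect_identical(fp@mPHat,
                         as.integer(max(length(obs) - length(mono), 0)))
    }
})

test_that("inverse-CDF draws reproduce the deconvolved distribution", {
    set.seed(423)
    obs <- c(rbeta(60, 2, 100), rbeta(30, 1, 800))
    mono <- rbeta(30, 1, 800)
    fp <- estimateFp(obs, mono)
    draws <- sampleFromFp(fp, 4000)
    expect_true(all(draws %in% fp@support))
    # empirical CDF of draws tracks the isotonic estimate on its support
    at <- quantile(fp@support, c(0.25, 0.5, 0.9), type = 1)
    for (x in at) {
        target <- max(fp@cdf[fp@support <= x])
        expect_lt(abs(mean(draws <= x) - target), 0.04)
    }
})

test_that("bootstrap replicates preserve depths and inject the requested variant count", {
    set.seed(424)
    d <- rep(c(1L, 0L), 100)
    tt <- matrix(rpois(40 * 200, 10), 40)
    grm <- tinyGrm(tt, matrix(0L, 40, 200), d)
    aeb <- matrix(2e-4, 40, 2)
    fp <- estimateFp(rep(c(0.005, 0.02), 5), rep(0.001, 4))
    rep1 <- makeBootstrapReplicate(grm, aeb, fp)
    expect_identical(totalReads(rep1), tt)
    # every injected locus screens in by construction; at least mPHat do
    kept <- ReadBurden:::.screenMatrices(totalReads(rep1),
                                         altReads(rep1), d)
    expect_gte(length(kept), fp@mPHat)
    # mPHat = 0: pure monomorphic replicate at tiny errors
    fp0 <- estimateFp(c(0.001), c(0.001, 0.002))
    rep0 <- makeBootstrapReplicate(grm, matrix(1e-12, 40, 2), fp0)
    expect_true(all(altReads(rep0) == 0))
})

test_that("sequential p-value formulas are exact on constructed exceedance traces", {
    # 5 exceedances reached at replicate 100 -> p = 5/100
    mk <- function(zs) { i <- 0; function(k) { zs[k] } }
    zs <- rep(0, 100); zs[c(10, 30, 50, 70, 100)] <- 9
    out <- sequentialPvalue(2, mk(zs), lMin = 5L, kMax = 1000L)
    expect_equal(out$pValue, 0.05)
    expect_identical(out$kObs, 100L)
    expect_true(out$stoppedEarly)
    # K_max reached with 2 exceedances -> (2 + 1) / (999 + 1)
    zs2 <- rep(0, 999); zs2[c(5, 6)] <- 9
    out2 <- sequentialPvalue(2, mk(zs2), lMin = 5L, kMax = 999L)
    expect_equal(out2$pValue, 3 / 1000)
    expect_false(out2$stoppedEarly)
    # exceedance is two-sided on |Z|
    zs3 <- rep(-9, 5)
    out3 <- sequentialPvalue(1.5, mk(zs3), lMin = 5L, kMax = 10L)
    expect_equal(out3$pValue, 1)
})

test_that("p-value is nonincreasing in |Z| for a fixed replicate stream", {
    set.seed(425)
    stream <- rnorm(3000)
    pFor <- function(z) sequentialPvalue(z, function(k) stream[k],
                                         lMin = 5L, kMax = 3000L)$pValue
    ps <- vapply(c(0.1, 0.5, 1, 1.5, 2, 2.5, 3), pFor, 0)
    expect_true(all(diff(ps) <= 1e-12))
})

test_that("sequential stopping on a null gene terminates quickly with the analytic law", {
    set.seed(426)
    ks <- replicate(2000, {
        zObs <- rnorm(1)
        sequentialPvalue(zObs, function(k) rnorm(1), lMin = 5L,
                         kMax = 400L)$kObs
    })
    expect_lte(median(ks), 10)
    # analytic marginal: P(K <= k) = (k - 4) / (k + 1)
    expect_lt(abs(mean(ks <= 9) - 0.5), 0.035)
    expect_lt(abs(mean(ks <= 14) - 10 / 15), 0.035)
})

test_that("full bootstrap on a small null gene returns a sane outcome", {
    set.seed(427)
    cfg <- simConfig(lociPerGene = 150, nSnv = 4, depthCase = 12,
                     depthCtrl = 6, nCases = 120, nControls = 120)
    st <- simulateCaseControlStudy(cfg)
    grm <- st$grm
    d <- phenotype(grm)
    tt <- totalReads(grm); rr <- altReads(grm)
    kept <- ReadBurden:::.screenMatrices(tt, rr, d)
    fits <- ReadBurden:::.fitLoci(tt, rr, d, kept)
    er <- geneErrorRates(grm, fits, kept)
    res <- ReadBurden:::.burdenCore(tt, rr, d, fits, kept)
    mafs <- vapply(kept, function(j) fits[[j]]$pi0, 0)
    bo <- bootstrapPvalue(grm, res@z, er$aeb, obsMafs = mafs,
                          lMin = 5L, kMax = 120L)
    expect_gt(bo@pValue, 0)
    expect_lte(bo@pValue, 1)
    expect_lte(bo@kObs, 120L)
    expect_identical(nrow(bo@log), as.integer(bo@kObs))
})
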