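test_that("method-of-moments beta fit: closed form and degenerate input", {
    x <- c(0.1, 0.3, 0.2, 0.2, 0.1, 0.3, 0.2, 0.2, 0.1, 0.3)
    m <- mean(x); v <- var(x)
    pr <- fitBetaMoM(x)
    ab <- m * (1 - m) / v - 1
    expect_equal(pr@a, m * ab)
    expect_equal(pr@b, (1 - m) * ab)
    # mean 0.2 and variance 0.01 give Beta(3, 12)
    mm <- 0.2; vv <- 0.01
    abx <- mm * (1 - mm) / vv - 1
    expect_equal(c(mm * abx, (1 - mm) * abx), c(3, 12))
    expect_true(fitBetaMoM(rep(0.01, 20))@degenerate)
})

test_that("MoM recovers beta hyperparameters from samples at error-rate scale", {
    set.seed(409)
    aHat <- replicate(20, fitBetaMoM(rbeta(2730, 2, 9998))@a)
    expect_lt(abs(mean(aHat) - 2) / 2, 0.3)
})

test_that("EB estimate is conjugate shrinkage with the right limits", {
    pr <- fitBetaMoM(rbeta(100, 3, 1000))
    expect_equal(ebEstimate(0, 0, pr), pr@a / (pr@a + pr@b))
    expect_equal(ebEstimate(0.02 * 1e7, 1e7, pr), 0.02, tolerance = 1e-3)
    # shrinkage: EB never further from the prior mean than the MLE
    set.seed(410)
    e <- rbinom(50, 5000, 0.003); t <- rep(5000, 50)
    pm <- pr@a / (pr@a + pr@b)
    eb <- ebEstimate(e, t, pr)
    expect_true(all(abs(eb - pm) <= abs(e / t - pm) + 1e-12))
})

test_that("adjusted EB preserves ranks and matches prior quantiles exactly", {
    set.seed(411)
    pr <- methods::new("ErrorPrior", a = 2, b = 9998, group = "case",
                       degenerate = FALSE)
    eb <- rbeta(40, 5, 2000)
    aeb <- adjustedEB(eb, pr)
    expect_equal(cor(eb, aeb, method = "spearman"), 1)
    expect_equal(sort(aeb), qbeta((seq_len(40) - 0.5) / 40, 2, 9998))
})

test_that("adjusted EB recovers the true error-rate distribution better than the MLE", {
    set.seed(412)
    wins <- 0
    for (rep in 1:8) {
        M <- 800
        epsTrue <- rbeta(M, 2, 9998)           # mean 0.02%
        trials <- rep(6000, M)                  # ~ n * depth error trials
        errs <- rbinom(M, trials, epsTrue)
        mle <- errs / trials
        pr <- fitBetaMoM(mle, trials = trials)
        eb <- ebEstimate(errs, trials, pr)
        aeb <- adjustedEB(eb, pr)
        ksA <- suppressWarnings(ks.test(aeb, epsTrue)$statistic)
        ksM <- suppressWarnings(ks.test(mle, epsTrue)$statistic)
        if (ksA < ksM) wins <- wins + 1
    }
    expect_gte(wins, 7)
})

test_that("gene-level error estimates: separate groups, all in [0, 0.5], mean preserved", {
    set.seed(413)
    cfg <- simConfig(lociPerGene = 300, nSnv = 5, depthCase = 30,
                     depthCtrl = 6)
    st <- simulateCaseControlStudy(cfg)
    grm <- st$grm
    d <- phenotype(grm)
    kept <- ReadBurden:::.screenMatrices(totalReads(grm), altReads(grm), d)
    fits <- ReadBurden:::.fitLoci(totalReads(grm), altReads(grm), d, kept)
    er <- geneErrorRates(grm, fits, kept)
    expect_true(all(er$aeb >= 0 & er$aeb <= 0.5))
    expect_true(all(er$eb >= 0 & er$eb <= 0.5 + 1e-12))
    for (grp in 1:2) {
        pr <- if (grp == 1) er$priorCase else er$priorCtrl
        if (pr@degenerate) next
        pm <- pr@a / (pr@a + pr@b)
        sdp <- sqrt(pr@a * pr@b / ((pr@a + pr@b)^2 * (pr@a + pr@b + 1)))
        expect_lt(abs(mean(er$aeb[, grp]) - pm), 2 * sdp / sqrt(300) + 1e-6)
    }
})
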