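mkFit <- function(dosages, pi0 = 0.01) {
    n <- length(dosages)
    methods::new("NullFit", pi0 = pi0, epsCase = 0.001, epsCtrl = 0.001,
        loglik = 0, dosages = dosages,
        postG = cbind(1 - dosages / 2, dosages / 2, 0),
        converged = TRUE, niter = 1L, boundary = FALSE,
        epsFlags = c(FALSE, FALSE))
}

test_that("score statistic is the centered dosage sum", {
    d <- c(1, 1, 0, 0)
    expect_equal(scoreStatistic(mkFit(c(1, 1, 0, 0)), d), 1)
    expect_equal(scoreStatistic(mkFit(rep(0.3, 4)), d), 0)
    expect_equal(scoreStatistic(mkFit(rep(0, 4)), d), 0)
})

test_that("allele-frequency weights: closed form, monotone, modes", {
    expect_equal(madsenBrowningWeight(0.5), 2)
    expect_equal(madsenBrowningWeight(0.01), 1 / sqrt(0.01 * 0.99))
    expect_equal(madsenBrowningWeight(0.3, "none"), 1)
    expect_equal(madsenBrowningWeight(0.1, "mb2"), 1 / (0.1 * 0.9))
    pis <- seq(0.01, 0.49, by = 0.02)
    expect_true(all(diff(madsenBrowningWeight(pis)) < 0))
    expect_error(madsenBrowningWeight(0))
})

test_that("in the deep error-free limit the read-based Z matches the hand-computed score test", {
    set.seed(416)
    n <- 400; d <- rep(c(1L, 0L), n / 2)
    L <- 6
    G <- sapply(runif(L, 0.005, 0.04), function(p) rbinom(n, 2, p))
    tt <- matrix(800L, L, n)
    rr <- t(G) * 400L   # exact het/hom read counts at eps ~ 0
    fits <- ReadBurden:::.fitLoci(tt, rr, d, seq_len(L))
    res <- ReadBurden:::.burdenCore(tt, rr, d, fits, seq_len(L))
    expect_equal(res@z, handBurdenZ(G, d), tolerance = 1e-3)
})

test_that("swapping case/control labels negates W and preserves V and |Z|", {
    set.seed(417)
    cfg <- simConfig(lociPerGene = 80, nSnv = 6, depthCase = 20,
                     depthCtrl = 6, nCases = 60, nControls = 60)
    st <- ReadBurden:::.simStudyRaw(cfg, generateBasePopulation(cfg), "all")
    kept <- ReadBurden:::.screenMatrices(st$tt, st$rr, st$d)
    fits <- ReadBurden:::.fitLoci(st$tt, st$rr, st$d, kept)
    a <- ReadBurden:::.burdenCore(st$tt, st$rr, st$d, fits, kept)
    dSw <- 1L - st$d
    fitsSw <- ReadBurden:::.fitLoci(st$tt, st$rr, dSw, kept)
    b <- ReadBurden:::.burdenCore(st$tt, st$rr, dSw, fitsSw, kept)
    expect_equal(a@w, -b@w, tolerance = 1e-6)
    expect_equal(a@v, b@v, tolerance = 1e-6)
})

test_that("an all-zero-dosage locus changes nothing and zero variance is flagged", {
    d <- rep(c(1L, 0L), 20)
    n <- length(d)
    tt <- matrix(10L, 2, n); rr <- matrix(0L, 2, n)
    rr[1, c(1, 3)] <- 5L
    fits <- ReadBurden:::.fitLoci(tt, rr, d, 1:2)
    fits[[2]] <- list(pi0 = 0, epsCase = 1e-8, epsCtrl = 1e-8, loglik = 0,
                      dosages = rep(0, n), postG = cbind(rep(1, n), 0, 0),
                      converged = TRUE, niter = 0L, boundary = TRUE,
                      epsFlags = c(FALSE, FALSE))
    one <- ReadBurden:::.burdenCore(tt, rr, d, fits, 1L)
    both <- ReadBurden:::.burdenCore(tt, rr, d, fits, 1:2)
    expect_equal(one@w, both@w)
    expect_equal(one@v, both@v)
    expect_equal(one@z, both@z)
    # degenerate: every dosage zero
    degFits <- list(fits[[2]])
    deg <- ReadBurden:::.burdenCore(tt, rr, d, degFits, 1L)
    expect_true(deg@degenerate)
})

test_that("single-locus unweighted Z-squared equals the per-locus score test", {
    set.seed(418)
    d <- rep(c(1L, 0L), 50)
    loc <- randomLocus(n = 100, depth = 30, eps = 0.01, pi = 0.1)
    tt <- matrix(loc$t, 1); rr <- matrix(loc$r, 1)
    fits <- ReadBurden:::.fitLoci(tt, rr, d, 1L)
    res <- ReadBurden:::.burdenCore(tt, rr, d, fits, 1L,
                                    weighting = "none", mafCap = 0.5)
    f <- fits[[1]]
    s <- sum((d - 0.5) * f$dosages)
    u <- (d - 0.5) * (f$dosages - 2 * f$pi0)
    expect_equal(res@z^2, s^2 / sum(u^2), tolerance = 1e-9)
})

test_that("efficient and centered variances agree at interior fits", {
    set.seed(419)
    cfg <- simConfig(lociPerGene = 60, nSnv = 8, depthCase = 10,
                     depthCtrl = 10, nCases = 150, nControls = 150)
    st <- ReadBurden:::.simStudyRaw(cfg, generateBasePopulation(cfg), "all")
    kept <- ReadBurden:::.screenMatrices(st$tt, st$rr, st$d)
    fits <- ReadBurden:::.fitLoci(st$tt, st$rr, st$d, kept)
    a <- ReadBurden:::.burdenCore(st$tt, st$rr, st$d, fits, kept,
                                  variance = "efficient")
    b <- ReadBurden:::.burdenCore(st$tt, st$rr, st$d, fits, kept,
                                  variance = "centered")
    expect_equal(a@z, b@z, tolerance = 0.02)
})
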