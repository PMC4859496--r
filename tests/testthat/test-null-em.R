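test_that("boundary null fit: no minor reads anywhere gives pi0 = 0 and zero dosages", {
    t <- rep(10L, 8); r <- rep(0L, 8); d <- rep(c(1, 0), 4)
    f <- fitNull(t, r, d)
    expect_true(f@boundary)
    expect_identical(f@pi0, 0)
    expect_true(all(f@dosages == 0))
})

test_that("EM recovers the allele frequency from deep reads and matches a grid search", {
    # 10 samples at depth 200: one het among nine reference homozygotes
    t <- rep(200L, 10)
    r <- c(rep(0L, 9), 100L)
    d <- rep(c(1, 0), 5)
    f <- fitNull(t, r, d)
    expect_lt(abs(f@pi0 - 0.05), 0.005)
    g <- gridFitNull(t, r, d, seq(0, 0.3, by = 1e-3),
                     seq(1e-6, 0.2, length.out = 201))
    expect_lt(abs(f@pi0 - g$pi), 1.5e-3)
    expect_gte(f@loglik, g$loglik - 1e-3)
})

test_that("EM log-likelihood trace is nondecreasing", {
    set.seed(402)
    for (i in 1:10) {
        loc <- randomLocus(n = 40, depth = 10, eps = 0.02, pi = 0.05)
        d <- rep(c(1L, 0L), 20)
        raw <- ReadBurden:::.cpp_fit_null(loc$t, loc$r, d, 1e-8, 500L,
                                          1e-8, 0.5)
        expect_true(all(diff(raw$llTrace) >= -1e-9))
    }
})

test_that("EM agrees with brute-force grid search on random small instances", {
    set.seed(403)
    piGrid <- seq(0, 0.6, by = 1e-3)
    epsGrid <- seq(1e-6, 0.5, length.out = 251)
    for (i in 1:25) {
        loc <- randomLocus(n = 16, depth = 25,
                           eps = runif(1, 0.005, 0.1),
                           pi = runif(1, 0.05, 0.4))
        d <- rep(c(1L, 0L), 8)
        if (sum(loc$t[d == 1]) == 0 || sum(loc$t[d == 0]) == 0) next
        f <- fitNull(loc$t, loc$r, d, screen = FALSE)
        g <- gridFitNull(loc$t, loc$r, d, piGrid, epsGrid)
        expect_gte(f@loglik, g$loglik - 1e-3)
        expect_lt(abs(f@pi0 - g$pi), 2e-3)
    }
})

test_that("interior EM fixed points satisfy the score equations", {
    set.seed(404)
    found <- 0
    for (i in 1:20) {
        loc <- randomLocus(n = 60, depth = 15, eps = 0.03, pi = 0.15)
        d <- rep(c(1L, 0L), 30)
        f <- fitNull(loc$t, loc$r, d, screen = FALSE)
        int <- f@pi0 > 1e-3 && f@pi0 < 0.99 &&
            f@epsCase > 1e-4 && f@epsCase < 0.49 &&
            f@epsCtrl > 1e-4 && f@epsCtrl < 0.49
        if (!int) next
        found <- found + 1
        h <- 1e-6
        ll <- function(p, e1, e0)
            ReadBurden:::.cpp_null_loglik(loc$t, loc$r, d, p, e1, e0)
        gr <- c(
            (ll(f@pi0 + h, f@epsCase, f@epsCtrl) -
             ll(f@pi0 - h, f@epsCase, f@epsCtrl)) / (2 * h),
            (ll(f@pi0, f@epsCase + h, f@epsCtrl) -
             ll(f@pi0, f@epsCase - h, f@epsCtrl)) / (2 * h),
            (ll(f@pi0, f@epsCase, f@epsCtrl + h) -
             ll(f@pi0, f@epsCase, f@epsCtrl - h)) / (2 * h))
        expect_lt(sqrt(sum(gr^2)), 1e-2)
    }
    expect_gte(found, 5)
})

test_that("with deep error-free reads the MLE equals the sample allele frequency", {
    set.seed(405)
    g <- rbinom(50, 2, 0.2)
    t <- rep(500L, 50)
    r <- as.integer(t * c(0, 0.5, 1)[g + 1])
    d <- rep(c(1L, 0L), 25)
    f <- fitNull(t, r, d, screen = FALSE)
    expect_equal(f@pi0, sum(g) / 100, tolerance = 1e-6)
})

test_that("profile likelihood at pi = 0 is maximized by the minor-read fraction", {
    t <- c(10L, 10L, 8L); r <- c(1L, 0L, 1L)
    pl <- groupProfileLoglik(t, r, 0)
    expect_equal(pl$eps, 2 / 28)
    # no reads at all: constant profile, flagged
    expect_true(groupProfileLoglik(c(0L, 0L), c(0L, 0L), 0.1)$flag)
})

test_that("profile likelihood is concave in pi and maximized at 0 without minor reads", {
    set.seed(406)
    loc <- randomLocus(n = 25, depth = 10, eps = 0.02, pi = 0.1)
    grid <- seq(0, 0.5, length.out = 41)
    pl <- vapply(grid, function(p) groupProfileLoglik(loc$t, loc$r, p)$value, 0)
    expect_true(all(diff(diff(pl)) <= 1e-6))
    t0 <- rep(10L, 20); r0 <- rep(0L, 20)
    pl0 <- vapply(c(0, 0.05, 0.2), function(p)
        groupProfileLoglik(t0, r0, p)$value, 0)
    expect_true(which.max(pl0) == 1)
})

test_that("a group with zero depth inherits the other group's error rate, flagged", {
    t <- c(0L, 0L, 20L, 20L); r <- c(0L, 0L, 2L, 1L)
    d <- c(1L, 1L, 0L, 0L)
    f <- fitNull(t, r, d, screen = FALSE)
    expect_true(f@epsFlags[1])
    expect_false(f@epsFlags[2])
    expect_equal(f@epsCase, f@epsCtrl)
})
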