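# Independent reference implementations used to validate the package's
# estimators.  Everything here is computed from first principles with plain
# base-R arithmetic, deliberately avoiding the package's EM / derivative /
# PAVA code paths.

# single-group log-likelihood matrix over a (pi, eps) grid:
# rows = pi values, cols = eps values
gridLoglikGroup <- function(t, r, piGrid, epsGrid) {
    n <- length(t)
    out <- matrix(0, length(piGrid), length(epsGrid))
    for (ei in seq_along(epsGrid)) {
        e <- epsGrid[ei]
        L <- cbind(dbinom(r, t, e), dbinom(r, t, 0.5), dbinom(r, t, 1 - e))
        P <- rbind((1 - piGrid)^2, 2 * piGrid * (1 - piGrid), piGrid^2)
        A <- L %*% P                       # n x length(piGrid)
        out[, ei] <- colSums(log(pmax(A, 1e-300)))
    }
    out
}

# joint restricted MLE by brute force: the null likelihood factorizes over
# groups given pi, so eps1 and eps0 maximize independently per pi
gridFitNull <- function(t, r, d, piGrid, epsGrid) {
    ll1 <- gridLoglikGroup(t[d == 1], r[d == 1], piGrid, epsGrid)
    ll0 <- gridLoglikGroup(t[d == 0], r[d == 0], piGrid, epsGrid)
    prof <- apply(ll1, 1, max) + apply(ll0, 1, max)
    k <- which.max(prof)
    list(pi = piGrid[k],
         eps1 = epsGrid[which.max(ll1[k, ])],
         eps0 = epsGrid[which.max(ll0[k, ])],
         loglik = prof[k])
}

# screening oracle: does the single-group profile likelihood argmax over a
# pi grid sit strictly at an interior (pi > 0) point?
gridScreenGroup <- function(t, r,
                            piGrid = c(0, exp(seq(log(1e-5), log(0.5),
                                                  length.out = 250))),
                            epsGrid = c(1e-8, exp(seq(log(1e-5), log(0.5),
                                                      length.out = 200)))) {
    ll <- gridLoglikGroup(t, r, piGrid, epsGrid)
    prof <- apply(ll, 1, max)
    # screen in when some pi > 0 beats pi = 0 (ties keep the locus)
    max(prof[-1]) >= prof[1]
}

# isotonic regression by the max-min formula (independent of the
# block-merging implementation)
isotonicMaxMin <- function(v, w = rep(1, length(v))) {
    n <- length(v)
    cw <- cumsum(w); cv <- cumsum(w * v)
    wmean <- function(j, k) (cv[k] - if (j > 1) cv[j - 1] else 0) /
                            (cw[k] - if (j > 1) cw[j - 1] else 0)
    vapply(seq_len(n), function(i) {
        max(vapply(seq_len(i), function(j)
            min(vapply(i:n, function(k) wmean(j, k), 0)), 0))
    }, 0)
}

# classical weighted burden score test on a known genotype matrix, with the
# efficient-score empirical variance written out longhand
handBurdenZ <- function(G, d, mafCap = 0.05) {
    n <- length(d); n1 <- sum(d)
    pis <- colMeans(G) / 2
    use <- which(pis > 0 & pis <= mafCap)
    w <- 1 / sqrt(pis[use] * (1 - pis[use]))
    S <- as.numeric(crossprod(G[, use, drop = FALSE], d - n1 / n))
    W <- sum(w * S)
    U <- (d - n1 / n) *
        as.numeric(sweep(G[, use, drop = FALSE], 2,
                         2 * pis[use]) %*% w)
    W / sqrt(sum(U^2))
}

# small deterministic read-data generator for property loops
randomLocus <- function(n = 30, depth = 8, eps = 0.01, pi = 0.02) {
    g <- rbinom(n, 2, pi)
    t <- rpois(n, depth)
    p <- ifelse(g == 0, eps, ifelse(g == 1, 0.5, 1 - eps))
    r <- rbinom(n, t, p)
    list(t = t, r = r, g = g)
}

# tiny GeneReadMatrix from explicit matrices
tinyGrm <- function(tt, rr, d) {
    GeneReadMatrix(tt, rr, d)
}
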