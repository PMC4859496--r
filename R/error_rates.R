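#' Method-of-moments beta prior for locus error rates
#'
#' Fits `Beta(a, b)` to a vector of per-locus error-rate estimates by
#' matching the sample mean and variance. When the per-locus read
#' exposures behind the estimates are supplied, the binomial counting
#' noise `mean(m (1 - m) / trials)` is subtracted from the raw variance
#' (the standard beta-binomial moment correction): at realistic error
#' rates the counting noise can exceed the true between-locus variance,
#' and an uncorrected fit produces a badly over-dispersed prior. Loci
#' with zero exposure carry no information and are excluded from the fit.
#' With zero (corrected) variance or a mean at 0 or 1 the prior is
#' flagged degenerate and downstream adjustment falls back to the raw
#' estimates.
#'
#' @param estimates per-locus error-rate estimates in `[0, 1]`.
#' @param group label stored in the result (`"case"` or `"control"`).
#' @param trials optional per-locus error-exposed read counts used for
#'   the sampling-noise correction.
#' @return An [ErrorPrior-class].
#' @export
fitBetaMoM <- function(estimates, group = "case", trials = NULL) {
    stopifnot(all(estimates >= 0), all(estimates <= 1))
    if (!is.null(trials)) {
        stopifnot(length(trials) == length(estimates))
        estimates <- estimates[trials > 0]
        trials <- trials[trials > 0]
    }
    if (length(estimates) < 2)
        return(methods::new("ErrorPrior", a = NA_real_, b = NA_real_,
                            group = group, degenerate = TRUE))
    m <- mean(estimates); v <- var(estimates)
    if (v <= 0 || m <= 0 || m >= 1)
        return(methods::new("ErrorPrior", a = NA_real_, b = NA_real_,
                            group = group, degenerate = TRUE))
    if (!is.null(trials)) {
        noise <- mean(m * (1 - m) / trials)
        # keep a sliver of the raw variance when the correction would
        # wipe it out entirely
        v <- max(v - noise, 0.05 * v)
    }
    ab <- m * (1 - m) / v - 1
    a <- max(m * ab, 1e-3)
    b <- max((1 - m) * ab, 1e-3)
    methods::new("ErrorPrior", a = a, b = b, group = group,
                 degenerate = FALSE)
}

#' Empirical-Bayes error-rate estimate
#'
#' Beta-binomial posterior mean `(a + e) / (a + b + t)` given the expected
#' number of mis-read bases `e` and exposed read trials `t` at a locus
#' (taken from the null EM's homozygote-weighted posteriors; heterozygote
#' reads carry no error information).
#'
#' @param e expected error-read count(s).
#' @param t expected error-exposed trial count(s).
#' @param prior an [ErrorPrior-class].
#' @return EB estimate(s).
#' @export
ebEstimate <- function(e, t, prior) {
    if (prior@degenerate) stop("cannot shrink with a degenerate prior")
    (prior@a + e) / (prior@a + prior@b + t)
}

#' Quantile-matched (adjusted) EB estimates
#'
#' Replaces the ordered EB estimates by the corresponding quantiles of the
#' fitted beta prior, at the median-unbiased plotting positions
#' `(k - 0.5) / M`. The ranks (and hence the locus ordering) of the input
#' are preserved exactly; only the marginal distribution is changed, undoing
#' the over-shrinkage of the plain EB estimator. Ties are broken by stable
#' input order.
#'
#' @param eb vector of EB estimates.
#' @param prior an [ErrorPrior-class].
#' @return vector of adjusted estimates, capped into `[0, 0.5]`.
#' @export
adjustedEB <- function(eb, prior) {
    if (prior@degenerate) stop("cannot adjust with a degenerate prior")
    M <- length(eb)
    if (M < 2) return(pmin(eb, 0.5))
    o <- order(eb, seq_along(eb))
    q <- qbeta((seq_len(M) - 0.5) / M, prior@a, prior@b)
    out <- numeric(M)
    out[o] <- q
    pmin(pmax(out, 0), 0.5)
}

#' Per-locus error-rate estimates for a whole gene
#'
#' Computes, separately for cases and controls, the per-locus error-rate
#' MLE (the null-EM estimate at screened-in loci; the total minor-read
#' fraction at screened-out loci, where all minor reads must be errors),
#' the EB shrinkage estimate under a method-of-moments beta prior fit to
#' all M loci of the gene, and the quantile-matched adjusted EB estimate
#' used to generate bootstrap reads.
#'
#' @param grm a [GeneReadMatrix-class].
#' @param fits list of per-locus [NullFit-class] covering at least the
#'   screened-in loci (others may be `NULL`).
#' @param keptLoci integer indices of screened-in loci.
#' @return list with matrices `mle`, `eb`, `aeb` (loci x 2, columns
#'   `case`/`ctrl`) and the two [ErrorPrior-class] objects `priorCase`,
#'   `priorCtrl`.
#' @export
geneErrorRates <- function(grm, fits, keptLoci = integer(0)) {
    tt <- totalReads(grm); rr <- altReads(grm)
    d <- phenotype(grm)
    L <- nrow(tt)
    mle <- eexp <- texp <- matrix(0, L, 2,
        dimnames = list(NULL, c("case", "ctrl")))
    # screened-out loci (the bulk): w0 = 1, every minor read is an error
    for (grp in 1:2) {
        i <- which(d == (2L - grp)) # grp 1 = case, 2 = ctrl
        st <- rowSums(tt[, i, drop = FALSE])
        sr <- rowSums(rr[, i, drop = FALSE])
        mle[, grp] <- ifelse(st > 0, sr / st, 0)
        eexp[, grp] <- sr; texp[, grp] <- st
    }
    for (j in keptLoci) {
        if (is.null(fits[[j]])) next
        f <- fits[[j]]
        w <- .fld(f, "postG")
        for (grp in 1:2) {
            i <- which(d == (2L - grp))
            eexp[j, grp] <- sum(w[i, 1] * rr[j, i] +
                                w[i, 3] * (tt[j, i] - rr[j, i]))
            texp[j, grp] <- sum((w[i, 1] + w[i, 3]) * tt[j, i])
            mle[j, grp] <- .fld(f, if (grp == 1) "epsCase" else "epsCtrl")
        }
    }
    mle <- pmin(mle, 0.5)
    priors <- list(fitBetaMoM(mle[, 1], "case", trials = texp[, 1]),
                   fitBetaMoM(mle[, 2], "control", trials = texp[, 2]))
    eb <- aeb <- mle
    for (grp in 1:2) {
        pr <- priors[[grp]]
        if (pr@degenerate) next # aeb falls back to the MLE
        eb[, grp] <- ebEstimate(eexp[, grp], texp[, grp], pr)
        aeb[, grp] <- adjustedEB(eb[, grp], pr)
    }
    list(mle = mle, eb = eb, aeb = aeb,
         priorCase = priors[[1]], priorCtrl = priors[[2]])
}
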