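#' Posterior-mode genotype calls
#'
#' Multi-sample hard calls at one locus: each sample is assigned the
#' genotype maximizing the posterior under the fitted null model (pooled
#' MAF, group-specific error rate). Ties resolve to the smaller genotype;
#' samples with no coverage get the prior mode (0 for a rare allele).
#'
#' @param fit a [NullFit-class].
#' @return integer vector of calls in `{0, 1, 2}`.
#' @export
callGenotypes <- function(fit) {
    as.integer(max.col(.fld(fit, "postG"), ties.method = "first") - 1L)
}

#' Burden test on called genotypes
#'
#' The genotype-calling comparator: hard calls from [callGenotypes()] are
#' treated as known genotypes in the classical weighted burden score test,
#' with the binomial (HWE) variance at the called allele frequency. This is
#' the approach whose type I error inflates under differential sequencing
#' quality between cases and controls.
#'
#' @inheritParams geneBurden
#' @return A [BurdenResult-class].
#' @export
cgBurdenTest <- function(grm, fits, loci = seq_len(nrow(grm)),
                         weighting = c("mb", "mb2", "none"),
                         mafCap = 0.05) {
    .cgCore(phenotype(grm), fits, loci, match.arg(weighting), mafCap)
}

.cgCore <- function(d, fits, loci, weighting = "mb", mafCap = 0.05) {
    n <- length(d); n1 <- sum(d); n0 <- n - n1
    calls <- lapply(loci, function(j)
        if (is.null(fits[[j]])) NULL else callGenotypes(fits[[j]]))
    pis <- vapply(calls, function(g)
        if (is.null(g)) NA_real_ else mean(g) / 2, 0)
    use <- which(!is.na(pis) & pis > 0 & pis <= mafCap)
    if (length(use) == 0)
        return(methods::new("BurdenResult", z = NA_real_, w = 0, v = 0,
            perLocusScore = numeric(0), weights = numeric(0),
            loci = integer(0), pAsym = NA_real_, degenerate = TRUE))
    wts <- madsenBrowningWeight(pis[use], weighting)
    s <- vapply(seq_along(use), function(k)
        sum((d - n1 / n) * calls[[use[k]]]), 0)
    W <- sum(wts * s)
    V <- (n1 * n0 / n) * sum(wts^2 * 2 * pis[use] * (1 - pis[use]))
    if (V <= 0)
        return(methods::new("BurdenResult", z = NA_real_, w = W, v = 0,
            perLocusScore = s, weights = wts,
            loci = as.integer(loci[use]), pAsym = NA_real_,
            degenerate = TRUE))
    z <- W / sqrt(V)
    methods::new("BurdenResult", z = z, w = W, v = V,
        perLocusScore = s, weights = wts, loci = as.integer(loci[use]),
        pAsym = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Dosage burden test with group-stratified robust variance
#'
#' The dosage comparator: the same posterior-dosage score statistic as
#' [geneBurden()], but with a robust variance that stratifies the empirical
#' variance of the per-individual weighted dosage sum by case-control group,
#' `V = (n0/n)^2 * SS_case + (n1/n)^2 * SS_ctrl`, accommodating different
#' dosage variances in high- and low-depth samples. Asymptotically
#' equivalent to [geneBurden()] when variant positions are known; severely
#' anticonservative when positions come from screening.
#'
#' @inheritParams geneBurden
#' @return A [BurdenResult-class].
#' @export
doseBurdenTest <- function(grm, fits, loci = seq_len(nrow(grm)),
                           weighting = c("mb", "mb2", "none"),
                           mafCap = 0.05) {
    .doseCore(phenotype(grm), fits, loci, match.arg(weighting), mafCap)
}

.doseCore <- function(d, fits, loci, weighting = "mb", mafCap = 0.05) {
    n <- length(d); n1 <- sum(d); n0 <- n - n1
    pis <- vapply(loci, function(j) {
        f <- fits[[j]]
        if (is.null(f)) NA_real_ else .fld(f, "pi0")
    }, 0)
    use <- loci[!is.na(pis) & pis > 0 & pis <= mafCap]
    if (length(use) == 0)
        return(methods::new("BurdenResult", z = NA_real_, w = 0, v = 0,
            perLocusScore = numeric(0), weights = numeric(0),
            loci = integer(0), pAsym = NA_real_, degenerate = TRUE))
    wts <- numeric(length(use)); s <- numeric(length(use))
    B <- numeric(n)
    for (k in seq_along(use)) {
        f <- fits[[use[k]]]
        wts[k] <- madsenBrowningWeight(.fld(f, "pi0"), weighting)
        dos <- .fld(f, "dosages")
        s[k] <- sum((d - n1 / n) * dos)
        B <- B + wts[k] * dos
    }
    W <- sum(wts * s)
    b1 <- B[d == 1]; b0 <- B[d == 0]
    V <- (n0 / n)^2 * sum((b1 - mean(b1))^2) +
         (n1 / n)^2 * sum((b0 - mean(b0))^2)
    if (V <= 0)
        return(methods::new("BurdenResult", z = NA_real_, w = W, v = 0,
            perLocusScore = s, weights = wts, loci = as.integer(use),
            pAsym = NA_real_, degenerate = TRUE))
    z <- W / sqrt(V)
    methods::new("BurdenResult", z = z, w = W, v = V,
        perLocusScore = s, weights = wts, loci = as.integer(use),
        pAsym = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}
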