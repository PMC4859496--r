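#' Per-locus score statistic
#'
#' Score for the case-control allele-frequency difference at one locus,
#' evaluated at the restricted null fit:
#' `S = sum_i (D_i - n1/n) * dosage_i`.
#'
#' @param fit a [NullFit-class].
#' @param d 0/1 case indicator in the same sample order as the fit.
#' @return numeric score.
#' @export
scoreStatistic <- function(fit, d) {
    stopifnot(length(d) == length(fit@dosages))
    sum((d - mean(d)) * fit@dosages)
}

#' Allele-frequency weight for the burden sum
#'
#' The standard rare-variant up-weighting `1 / sqrt(pi (1 - pi))`; mode
#' `"none"` returns 1 and mode `"mb2"` the squared version
#' `1 / (pi (1 - pi))`.
#'
#' @param pi0 pooled null MAF, strictly inside (0, 1).
#' @param mode `"mb"`, `"mb2"` or `"none"`.
#' @return weight value(s).
#' @export
madsenBrowningWeight <- function(pi0, mode = c("mb", "mb2", "none")) {
    mode <- match.arg(mode)
    if (any(pi0 <= 0) || any(pi0 >= 1))
        stop("weights require 0 < pi0 < 1")
    switch(mode,
        mb = 1 / sqrt(pi0 * (1 - pi0)),
        mb2 = 1 / (pi0 * (1 - pi0)),
        none = rep(1, length(pi0)))
}

# slot/field access that works for both NullFit objects and the raw fit
# lists used on the internal fast path
.fld <- function(f, name) {
    if (isS4(f)) methods::slot(f, name) else f[[name]]
}

# Per-individual score contributions at the null fit of one locus.
# Columns: beta score, then nuisance scores for the MAF logit and the two
# group error rates.  Heterozygote reads carry no error information, so the
# error-rate scores weight only the homozygote posteriors.
locusScorePieces <- function(fit, t, r, d) {
    w <- .fld(fit, "postG")
    pi <- .fld(fit, "pi0")
    e1 <- .fld(fit, "epsCase"); e0 <- .fld(fit, "epsCtrl")
    sAlpha <- .fld(fit, "dosages") - 2 * pi
    sBeta <- d * sAlpha
    epsScore <- function(e, grp) {
        s <- numeric(length(t))
        i <- which(d == grp & t > 0)
        s[i] <- w[i, 1] * (r[i] / e - (t[i] - r[i]) / (1 - e)) +
                w[i, 3] * ((t[i] - r[i]) / e - r[i] / (1 - e))
        s
    }
    nuis <- cbind(alpha = sAlpha,
                  eps1 = epsScore(e1, 1L),
                  eps0 = epsScore(e0, 0L))
    # a boundary error rate is not an interior nuisance parameter: drop it
    keep <- c(TRUE, e1 > 2 * EPS_MIN && e1 < EPS_MAX,
              e0 > 2 * EPS_MIN && e0 < EPS_MAX)
    list(beta = sBeta, nuisance = nuis[, keep, drop = FALSE])
}

#' Efficient-score residual for one locus
#'
#' Residualizes the per-individual score for the tested log-odds shift on
#' the per-individual scores for the nuisance parameters (MAF logit and
#' group error rates) by least squares; redundant (collinear) nuisance
#' columns are handled through the rank-revealing QR.
#'
#' @param beta per-individual score for the tested parameter.
#' @param nuisance matrix of per-individual nuisance scores.
#' @return per-individual efficient-score contributions.
#' @export
efficientScoreResidual <- function(beta, nuisance) {
    if (is.null(nuisance) || ncol(nuisance) == 0) return(beta)
    ok <- apply(nuisance, 2, function(x) any(abs(x) > 1e-12))
    if (!any(ok)) return(beta)
    qa <- qr(nuisance[, ok, drop = FALSE])
    as.numeric(beta - qr.fitted(qa, beta))
}

#' Gene-level burden test on posterior dosages
#'
#' Forms the weighted burden statistic `W = sum_j w_j S_j` over the supplied
#' loci (restricted to pooled null MAF in `(0, mafCap]`), the empirical
#' variance `V` of the per-individual efficient scores, and `Z = W/sqrt(V)`
#' with its two-sided normal p-value. The asymptotic p-value is valid when
#' the variant positions are known; after screening, significance should be
#' assessed with [bootstrapPvalue()] instead.
#'
#' @param grm a [GeneReadMatrix-class].
#' @param fits list of [NullFit-class], one per row of `grm` (entries for
#'   untested loci may be `NULL`).
#' @param loci integer indices of candidate loci (default: all rows).
#' @param weighting weight mode passed to [madsenBrowningWeight()].
#' @param mafCap test only loci with pooled null MAF `<= mafCap`.
#' @param variance `"efficient"` (default) uses the analytic efficient
#'   score `U_i = (D_i - n1/n) * sum_j w_j (dosage_ij - 2 pi0_j)`, the
#'   score for the tested log-odds shift with the MAF nuisance profiled
#'   out at its expected information; `"centered"` replaces the prior-mean
#'   centering by the sample mean of the weighted dosage sum;
#'   `"projected"` residualizes the per-individual score on the realized
#'   per-individual nuisance scores by least squares (degenerate for
#'   singleton-dominated genes, retained for diagnostics).
#' @return A [BurdenResult-class].
#' @export
geneBurden <- function(grm, fits, loci = seq_len(nrow(grm)),
                       weighting = c("mb", "mb2", "none"), mafCap = 0.05,
                       variance = c("efficient", "centered",
                                    "projected")) {
    .burdenCore(totalReads(grm), altReads(grm), phenotype(grm), fits,
                loci, match.arg(weighting), mafCap, match.arg(variance))
}

# matrix-level core shared with the bootstrap replicate loop
.burdenCore <- function(tt, rr, d, fits, loci = seq_len(nrow(tt)),
                        weighting = "mb", mafCap = 0.05,
                        variance = "efficient") {
    n <- length(d); n1 <- sum(d)

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
    U <- numeric(n); B <- numeric(n); C <- numeric(n)
    dc <- d - n1 / n
    for (k in seq_along(use)) {
        j <- use[k]
        f <- fits[[j]]
        pij <- .fld(f, "pi0")
        dos <- .fld(f, "dosages")
        wts[k] <- madsenBrowningWeight(pij, weighting)
        s[k] <- sum(dc * dos)
        B <- B + wts[k] * dos
        if (variance == "efficient")
            C <- C + wts[k] * (dos - 2 * pij)
        if (variance == "projected") {
            pc <- locusScorePieces(f, tt[j, ], rr[j, ], d)
            U <- U + wts[k] * efficientScoreResidual(pc$beta, pc$nuisance)
        }
    }
    if (variance == "efficient") U <- dc * C
    if (variance == "centered") U <- dc * (B - mean(B))
    W <- sum(wts * s)
    V <- sum(U^2)
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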