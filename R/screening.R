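#' Screening derivative of the profile likelihood at zero MAF
#'
#' Directional derivative of the single-group profile log-likelihood
#' `pl(pi) = max_eps log L(pi, eps)` at `pi = 0`. At zero allele frequency
#' every minor-allele read must be an error, so the inner maximizer is
#' `eps-hat = sum(r) / sum(t)` (capped into `[1e-8, 0.5]`), and by the
#' envelope theorem the derivative is
#' `2 * sum_i [ (0.5/eps)^r_i * (0.5/(1-eps))^(t_i - r_i) - 1 ]`.
#' Because `pl` is concave in `pi`, a non-positive derivative implies the
#' group MLE is `pi = 0`. A group with zero total depth returns `-Inf`.
#'
#' @param t,r read counts of a single homogeneous group, or matrices
#'   (loci x samples) to evaluate many loci at once.
#' @return derivative value(s), one per locus.
#' @export
profileDerivativeAtZero <- function(t, r) {
    if (is.matrix(t)) {
        storage.mode(t) <- "integer"; storage.mode(r) <- "integer"
        return(.cpp_screen_deriv(t, r, EPS_MIN))
    }
    .cpp_screen_deriv(matrix(as.integer(t), nrow = 1),
                      matrix(as.integer(r), nrow = 1), EPS_MIN)[1]
}

#' Screen a locus from reads alone
#'
#' A locus is retained iff the profile-likelihood derivative at zero MAF is
#' positive in the cases or in the controls. A derivative of exactly zero is
#' treated as screen-in (the EM decides downstream); a locus screened out in
#' both groups has pooled null MAF 0, hence all dosages 0 and a zero score.
#'
#' @param tCase,rCase,tCtrl,rCtrl per-sample read counts by group.
#' @return logical.
#' @export
screenLocus <- function(tCase, rCase, tCtrl, rCtrl) {
    d1 <- profileDerivativeAtZero(tCase, rCase)
    d0 <- profileDerivativeAtZero(tCtrl, rCtrl)
    d1 >= 0 || d0 >= 0
}

#' Screen every locus of a gene
#'
#' Applies the derivative test per locus in cases and controls and fits the
#' restricted null model at each screened-in locus to obtain its pooled MAF
#' estimate.
#'
#' @param grm a [GeneReadMatrix-class].
#' @param fits optional pre-computed list of [NullFit-class] per locus
#'   (length `nrow(grm)`); fitted on demand when `NULL`.
#' @return A [ScreenedGene-class].
#' @export
screenGene <- function(grm, fits = NULL) {
    tt <- totalReads(grm); rr <- altReads(grm)
    d <- phenotype(grm)
    dc <- .cpp_screen_deriv(tt[, d == 1L, drop = FALSE],
                            rr[, d == 1L, drop = FALSE], EPS_MIN)
    d0 <- .cpp_screen_deriv(tt[, d == 0L, drop = FALSE],
                            rr[, d == 0L, drop = FALSE], EPS_MIN)
    keep <- which(dc >= 0 | d0 >= 0)
    maf <- vapply(keep, function(j) {
        f <- if (!is.null(fits)) fits[[j]] else
            fitNull(tt[j, ], rr[j, ], d, screen = FALSE)
        .fld(f, "pi0")
    }, 0)
    methods::new("ScreenedGene", keptLoci = as.integer(keep),
        mS = length(keep), mSt = length(keep),
        mafHat = as.numeric(maf), derivCase = dc, derivCtrl = d0)
}

#' Singleton MAF threshold
#'
#' Removes screened-in loci whose estimated pooled MAF is strictly below
#' `1/(2n)`, the frequency of a singleton variant; the boundary value is
#' kept. Used by the thresholded ("STB") variant of the test.
#'
#' @param sg a [ScreenedGene-class].
#' @param n total sample count.
#' @return `sg` with `keptLoci`, `mafHat` and `mSt` updated; `mS` is
#'   unchanged (it refers to the screening step alone).
#' @export
applyMafThreshold <- function(sg, n) {
    cutoff <- 1 / (2 * n)
    keep <- sg@mafHat >= cutoff
    methods::new("ScreenedGene",
        keptLoci = sg@keptLoci[keep], mS = sg@mS, mSt = sum(keep),
        mafHat = sg@mafHat[keep],
        derivCase = sg@derivCase, derivCtrl = sg@derivCtrl)
}
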