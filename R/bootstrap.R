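# internal: screen matrices directly (kept indices + derivatives)
.screenMatrices <- function(tt, rr, d) {
    dc <- .cpp_screen_deriv(tt[, d == 1L, drop = FALSE],
                            rr[, d == 1L, drop = FALSE], EPS_MIN)
    d0 <- .cpp_screen_deriv(tt[, d == 0L, drop = FALSE],
                            rr[, d == 0L, drop = FALSE], EPS_MIN)
    which(dc >= 0 | d0 >= 0)
}

# internal: null fits at the given loci (list indexed by locus, NULL
# elsewhere); raw lists rather than NullFit objects to keep the bootstrap
# replicate loop cheap
.fitLoci <- function(tt, rr, d, loci) {
    fits <- vector("list", nrow(tt))
    for (j in loci) fits[[j]] <- .fitNullRaw(tt[j, ], rr[j, ], d)
    fits
}

.fitNullRaw <- function(t, r, d, tol = 1e-8, maxit = 500L) {
    f <- .cpp_fit_null(as.integer(t), as.integer(r), as.integer(d),
                       tol, maxit, EPS_MIN, EPS_MAX)
    list(pi0 = f$pi0, epsCase = f$eps1, epsCtrl = f$eps0,
         loglik = f$loglik, dosages = f$dosages, postG = f$postG,
         converged = f$converged, niter = f$niter, boundary = FALSE,
         epsFlags = c(f$epsCaseFlag, f$epsCtrlFlag))
}

#' Pooled-adjacent-violators isotonic regression
#'
#' Weighted least-squares fit of a nondecreasing vector to `values`, by
#' block merging: adjacent blocks violating monotonicity are pooled into
#' their weighted mean until none remain.
#'
#' @param values numeric vector.
#' @param weights positive weights of the same length.
#' @return the nondecreasing fit.
#' @examples
#' pava(c(1, 3, 2))   # 1, 2.5, 2.5
#' @export
pava <- function(values, weights = rep(1, length(values))) {
    n <- length(values)
    stopifnot(length(weights) == n, all(weights > 0))
    if (n == 0) return(numeric(0))
    # blocks as parallel stacks of (mean, weight, size)
    bm <- bw <- bs <- numeric(n)
    k <- 0
    for (i in seq_len(n)) {
        k <- k + 1
        bm[k] <- values[i]; bw[k] <- weights[i]; bs[k] <- 1
        while (k > 1 && bm[k - 1] > bm[k]) {
            w <- bw[k - 1] + bw[k]
            bm[k - 1] <- (bw[k - 1] * bm[k - 1] + bw[k] * bm[k]) / w
            bw[k - 1] <- w
            bs[k - 1] <- bs[k - 1] + bs[k]
            k <- k - 1
        }
    }
    rep(bm[seq_len(k)], times = bs[seq_len(k)])
}

#' Simulate the monomorphic twin of a gene
#'
#' Generates read data under the hypothesis that every locus of the gene is
#' monomorphic: the observed depth matrix is kept exactly, and the
#' minor-allele counts are redrawn as binomial errors at each sample's
#' group-specific (adjusted-EB) error rate. Comparing what screens in here
#' against the observed data calibrates how many observed "variants" are
#' sequencing artifacts.
#'
#' @param grm a [GeneReadMatrix-class].
#' @param aeb loci x 2 matrix of error rates (columns case, control).
#' @return a new [GeneReadMatrix-class] with identical depths.
#' @export
simulateMonomorphic <- function(grm, aeb) {
    tt <- totalReads(grm)
    d <- phenotype(grm)
    rr <- .monomorphicReads(tt, .epsBySample(aeb, d))
    GeneReadMatrix(tt, rr, d,
        rowRanges = SummarizedExperiment::rowRanges(grm),
        gene = geneName(grm))
}

# loci x samples error-rate matrix from the loci x 2 group matrix
.epsBySample <- function(aeb, d) {
    aeb[, 2L - (d == 1L), drop = FALSE]
}

.monomorphicReads <- function(tt, epsMat) {
    rr <- rbinom(length(tt), as.vector(tt), as.vector(epsMat))
    matrix(as.integer(rr), nrow = nrow(tt), dimnames = dimnames(tt))
}

#' Deconvolve the true-variant MAF distribution
#'
#' The screened-in MAFs of the observed gene are a mixture of truly
#' polymorphic loci and monomorphic artifacts:
#' `F_s(pi) = phi F_m(pi) + (1 - phi) F_p(pi)`. With `phi` estimated by
#' `M_m / M_s`, the true-variant CDF is recovered as
#' `(1 - phi)^(-1) (F_s - phi F_m)` evaluated at the pooled MAFs, made
#' monotone by [pava()], clipped to `[0, 1]`, and set to 1 beyond the
#' largest MAF. The estimated number of true variants is
#' `max(M_s - M_m, 0)`.
#'
#' @param obsMafs MAF estimates of the observed screened-in loci.
#' @param monoMafs MAF estimates of the monomorphic dataset's screened-in
#'   loci.
#' @return An [FpEstimate-class].
#' @export
estimateFp <- function(obsMafs, monoMafs) {
    mS <- length(obsMafs); mM <- length(monoMafs)
    stopifnot(mS >= 1)
    phi <- mM / mS
    mP <- max(mS - mM, 0L)
    support <- sort(c(obsMafs, monoMafs))
    Fs <- vapply(support, function(x) mean(obsMafs <= x), 0)
    if (mM == 0 || phi >= 1) {
        # no artifact component to subtract, or no evidence of polymorphism
        cdf <- pmin(pmax(pava(Fs), 0), 1)
    } else {
        Fm <- vapply(support, function(x) mean(monoMafs <= x), 0)
        raw <- (Fs - phi * Fm) / (1 - phi)
        cdf <- pmin(pmax(pava(raw), 0), 1)
    }
    methods::new("FpEstimate", support = support, cdf = cdf,
        phiHat = phi, mPHat = as.integer(mP),
        mS = as.integer(mS), mM = as.integer(mM))
}

#' Draw allele frequencies from a deconvolved CDF
#'
#' Inverse-CDF sampling from an [FpEstimate-class]; mass beyond the largest
#' support point (the CDF is 1 there) is assigned to the largest observed
#' MAF.
#'
#' @param fp an [FpEstimate-class].
#' @param n number of draws.
#' @return numeric vector of MAFs.
#' @export
sampleFromFp <- function(fp, n) {
    u <- runif(n)
    k <- findInterval(u, fp@cdf, left.open = TRUE) + 1L
    k <- pmin(k, length(fp@support))
    fp@support[k]
}

# internal replicate generator on raw matrices; returns list(tt, rr)
.replicateReads <- function(tt, d, aeb, fp, rejectCap = 1000L) {
    rr <- .monomorphicReads(tt, .epsBySample(aeb, d))
    mP <- fp@mPHat
    if (mP > 0) {
        snvLoci <- sample.int(nrow(tt), mP)
        for (j in snvLoci) {
            repeat {
                pj <- sampleFromFp(fp, 1)
                inj <- .cpp_inject_snv(tt[j, ], d, aeb[j, 1], aeb[j, 2],
                                       pj, as.integer(rejectCap), EPS_MIN)
                if (inj$ok) break # else hopeless pi: redraw it
            }
            rr[j, ] <- inj$r
        }
    }
    rr
}

#' Generate one bootstrap replicate of a gene
#'
#' Starting from a fresh monomorphic twin (depths fixed, errors redrawn),
#' `mPHat` loci chosen uniformly at random are made true variants: an
#' allele frequency is drawn from the deconvolved CDF, genotypes are drawn
#' from HWE identically in cases and controls (the bootstrap null), and the
#' reads at those loci are regenerated. Genotypes are redrawn (keeping the
#' same allele frequency, up to `rejectCap` tries before the frequency is
#' redrawn) until the injected locus screens in.
#'
#' @param grm a [GeneReadMatrix-class] (supplies depths and phenotype).
#' @param aeb loci x 2 error-rate matrix (case, control).
#' @param fp an [FpEstimate-class].
#' @param rejectCap genotype redraw cap per allele frequency.
#' @return a [GeneReadMatrix-class].
#' @export
makeBootstrapReplicate <- function(grm, aeb, fp, rejectCap = 1000L) {
    tt <- totalReads(grm)
    d <- phenotype(grm)
    rr <- .replicateReads(tt, d, aeb, fp, rejectCap)
    GeneReadMatrix(tt, rr, d,
        rowRanges = SummarizedExperiment::rowRanges(grm),
        gene = geneName(grm))
}

#' Sequentially stopped Monte Carlo p-value
#'
#' Draws statistics from `nextStat()` until either `lMin` of them exceed
#' the observed statistic (p-value `lMin / kObs`) or `kMax` draws are
#' reached (p-value `(lObs + 1) / (kMax + 1)`). Exceedance is two-sided,
#' `|Z*| >= |Z|`, by default.
#'
#' @param zObs observed statistic.
#' @param nextStat function of the replicate index returning the next
#'   bootstrap statistic (and optionally attributes used by the caller).
#' @param lMin early-stopping exceedance count.
#' @param kMax maximum number of replicates.
#' @param twoSided compare absolute values.
#' @return list with `pValue`, `kObs`, `lObs`, `stoppedEarly`, `zStar`.
#' @export
sequentialPvalue <- function(zObs, nextStat, lMin = 5L, kMax = 1000L,
                             twoSided = TRUE) {
    l <- 0L; k <- 0L
    zs <- numeric(0)
    thr <- if (twoSided) abs(zObs) else zObs
    while (k < kMax) {
        k <- k + 1L
        z <- nextStat(k)
        zs[k] <- z
        zz <- if (twoSided) abs(z) else z
        if (!is.na(zz) && zz >= thr) l <- l + 1L
        if (l >= lMin) break
    }
    if (l >= lMin)
        list(pValue = lMin / k, kObs = k, lObs = l, stoppedEarly = TRUE,
             zStar = zs)
    else
        list(pValue = (l + 1) / (kMax + 1), kObs = k, lObs = l,
             stoppedEarly = FALSE, zStar = zs)
}

#' Bootstrap p-value for the screened burden statistic
#'
#' The full significance procedure for a gene whose variant locations were
#' estimated by screening: a monomorphic twin of the gene calibrates the
#' number and MAF distribution of artifact variants ([estimateFp()]); each
#' bootstrap replicate rebuilds the gene under the null (equal allele
#' frequencies in cases and controls, observed depths, adjusted-EB error
#' rates), is screened and tested exactly like the original data, and the
#' sequential rule of [sequentialPvalue()] converts the exceedance count of
#' `|Z*| >= |Z|` into a p-value.
#'
#' @param grm a [GeneReadMatrix-class] (the observed gene, post-QC).
#' @param zObs observed burden statistic from the same pipeline.
#' @param aeb loci x 2 adjusted-EB error-rate matrix.
#' @param fp an [FpEstimate-class] from the observed gene; when `NULL` it
#'   is estimated here from one dedicated monomorphic run.
#' @param obsMafs observed screened-in MAFs (needed when `fp` is `NULL`).
#' @param lMin,kMax sequential stopping parameters.
#' @param mode `"SB"` (screening only) or `"STB"` (screening plus the
#'   singleton MAF threshold) — must match how `zObs` was computed.
#' @param weighting,mafCap,variance passed to the burden statistic.
#' @param twoSided exceedance on `|Z|`.
#' @param refitFp re-estimate the deconvolution inside every replicate
#'   (slower; default keeps the one gene-level estimate).
#' @return A [BootstrapOutcome-class].
#' @export
bootstrapPvalue <- function(grm, zObs, aeb, fp = NULL, obsMafs = NULL,
                            lMin = 5L, kMax = 1000L,
                            mode = c("SB", "STB"),
                            weighting = "mb", mafCap = 0.05,
                            variance = "efficient", twoSided = TRUE,
                            refitFp = FALSE) {
    mode <- match.arg(mode)
    tt <- totalReads(grm)
    d <- phenotype(grm)
    n <- length(d)
    epsMat <- .epsBySample(aeb, d)

    if (is.null(fp)) {
        stopifnot(!is.null(obsMafs))
        if (length(obsMafs) == 0)
            return(methods::new("BootstrapOutcome", pValue = 1,
                kObs = 0L, lObs = 0L, stoppedEarly = FALSE,
                log = data.frame()))
        fp <- .fpFromMonomorphicRun(tt, d, epsMat, obsMafs)
    }

    if (refitFp && is.null(obsMafs))
        stop("refitFp = TRUE requires obsMafs")

    mms <- integer(0); mps <- integer(0)
    nextStat <- function(k) {
        fpk <- fp
        if (refitFp)
            fpk <- .fpFromMonomorphicRun(tt, d, epsMat, obsMafs)
        rr <- .replicateReads(tt, d, aeb, fpk)
        kept <- .screenMatrices(tt, rr, d)
        mms[k] <<- length(kept) # screened-in count in the replicate
        mps[k] <<- fpk@mPHat
        if (length(kept) == 0) return(0)
        fits <- .fitLoci(tt, rr, d, kept)
        if (mode == "STB") {
            cutoff <- 1 / (2 * n)
            kept <- kept[vapply(kept, function(j) .fld(fits[[j]], "pi0"), 0) >=
                         cutoff]
            if (length(kept) == 0) return(0)
        }
        res <- .burdenCore(tt, rr, d, fits, kept, weighting, mafCap,
                           variance)
        if (res@degenerate) 0 else res@z
    }
    out <- sequentialPvalue(zObs, nextStat, lMin = lMin, kMax = kMax,
                            twoSided = twoSided)
    lg <- data.frame(replicate = seq_len(out$kObs),
                     mM = mms, mPHat = mps, zStar = out$zStar,
                     exceed = if (twoSided) abs(out$zStar) >= abs(zObs)
                              else out$zStar >= zObs)
    methods::new("BootstrapOutcome", pValue = out$pValue,
        kObs = as.integer(out$kObs), lObs = as.integer(out$lObs),
        stoppedEarly = out$stoppedEarly, log = lg)
}

# one monomorphic run: screen it, fit MAFs at its screened-in loci, and
# deconvolve against the observed MAFs
.fpFromMonomorphicRun <- function(tt, d, epsMat, obsMafs) {
    rr <- .monomorphicReads(tt, epsMat)
    kept <- .screenMatrices(tt, rr, d)
    monoMafs <- vapply(kept, function(j)
        .fitNullRaw(tt[j, ], rr[j, ], d)$pi0, 0)
    estimateFp(obsMafs, monoMafs)
}
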