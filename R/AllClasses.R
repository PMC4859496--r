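#' @import methods
#' @importFrom stats dbinom pbeta qbeta rbinom rnbinom rbeta runif rnorm
#'   optimize setNames quantile median sd var cor
#' @importFrom utils read.table write.table
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowRanges
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib ReadBurden, .registration = TRUE
NULL

#' GeneReadMatrix: per-gene read counts for a case-control sample
#'
#' Container for the read data of one gene: for every locus (row) and sample
#' (column) the total number of mapped reads and the number of reads carrying
#' the minor (non-reference) allele. Extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with assays `total` and
#' `alt`; the case/control indicator lives in `colData(x)$phenotype` (1 =
#' case, 0 = control). A total of zero encodes no coverage and is retained,
#' never dropped.
#'
#' @slot .  See [SummarizedExperiment::RangedSummarizedExperiment].
#' @export
setClass("GeneReadMatrix",
    contains = "RangedSummarizedExperiment")

setValidity("GeneReadMatrix", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("total", "alt") %in% a))
        return("assays 'total' and 'alt' are required")
    tt <- SummarizedExperiment::assay(object, "total")
    rr <- SummarizedExperiment::assay(object, "alt")
    if (any(tt < 0) || any(rr < 0))
        return("read counts must be non-negative")
    if (any(rr > tt))
        return("minor-allele reads exceed total reads at some (locus, sample)")
    ph <- object$phenotype
    if (is.null(ph) || !all(ph %in% c(0L, 1L)))
        return("colData(x)$phenotype must be a 0/1 case indicator")
    if (sum(ph == 1L) < 1L || sum(ph == 0L) < 1L)
        return("at least one case and one control are required")
    TRUE
})

#' NullFit: restricted maximum-likelihood fit at one locus
#'
#' Restricted MLEs under the null hypothesis of equal minor-allele frequency
#' in cases and controls: the pooled MAF, group-specific error rates, the
#' null log-likelihood, and per-sample posterior genotype probabilities and
#' dosages.
#'
#' @slot pi0 pooled null minor-allele frequency.
#' @slot epsCase,epsCtrl per-read error-rate estimates for cases/controls.
#' @slot loglik maximized null log-likelihood.
#' @slot dosages per-sample posterior minor-allele dosage in `[0, 2]`.
#' @slot postG n x 3 matrix of posterior genotype probabilities.
#' @slot converged logical; EM convergence flag.
#' @slot niter EM iterations used.
#' @slot boundary logical; TRUE when the locus screened out and the boundary
#'   solution `pi0 = 0` was returned without iteration.
#' @slot epsFlags logical length-2; TRUE where a group had zero total depth
#'   and inherited the other group's error rate.
#' @export
setClass("NullFit", representation(
    pi0 = "numeric", epsCase = "numeric", epsCtrl = "numeric",
    loglik = "numeric", dosages = "numeric", postG = "matrix",
    converged = "logical", niter = "integer", boundary = "logical",
    epsFlags = "logical"))

setValidity("NullFit", function(object) {
    if (length(object@pi0) != 1 || object@pi0 < 0 || object@pi0 > 1)
        return("pi0 must be a single value in [0, 1]")
    if (!is.finite(object@loglik)) return("loglik must be finite")
    if (length(object@dosages) &&
        (min(object@dosages) < -1e-9 || max(object@dosages) > 2 + 1e-9))
        return("dosages must lie in [0, 2]")
    TRUE
})

#' ScreenedGene: screening result for one gene
#'
#' @slot keptLoci integer indices of loci that screened in.
#' @slot mS number of screened-in loci.
#' @slot mSt number of screened-in loci that also pass the singleton MAF
#'   threshold (equal to `mS` until [applyMafThreshold()] is applied).
#' @slot mafHat pooled null MAF estimate at each kept locus.
#' @slot derivCase,derivCtrl per-locus screening derivatives (all loci).
#' @export
setClass("ScreenedGene", representation(
    keptLoci = "integer", mS = "integer", mSt = "integer",
    mafHat = "numeric", derivCase = "numeric", derivCtrl = "numeric"))

setValidity("ScreenedGene", function(object) {
    if (object@mSt != length(object@keptLoci))
        return("mSt must equal length(keptLoci)")
    if (object@mSt > object@mS) return("mSt cannot exceed mS")
    TRUE
})

#' ErrorPrior: beta prior for locus-specific error rates
#'
#' @slot a,b beta shape parameters (method-of-moments estimates).
#' @slot group `"case"` or `"control"`.
#' @slot degenerate TRUE when the locus estimates had zero variance and no
#'   prior could be fit.
#' @export
setClass("ErrorPrior", representation(
    a = "numeric", b = "numeric", group = "character",
    degenerate = "logical"))

setValidity("ErrorPrior", function(object) {
    if (!object@degenerate && (object@a <= 0 || object@b <= 0))
        return("shape parameters must be positive")
    TRUE
})

#' BurdenResult: gene-level burden test
#'
#' @slot z test statistic `W / sqrt(V)`.
#' @slot w weighted sum of per-locus score statistics.
#' @slot v efficient-score (or comparator) variance estimate.
#' @slot perLocusScore score statistic per tested locus.
#' @slot weights per-locus weights.
#' @slot loci indices of the tested loci.
#' @slot pAsym two-sided normal p-value (asymptotic, known-variant mode).
#' @slot degenerate TRUE when `v` was zero and no Z could be formed.
#' @export
setClass("BurdenResult", representation(
    z = "numeric", w = "numeric", v = "numeric",
    perLocusScore = "numeric", weights = "numeric", loci = "integer",
    pAsym = "numeric", degenerate = "logical"))

setValidity("BurdenResult", function(object) {
    if (length(object@v) && !is.na(object@v) && object@v < 0)
        return("variance must be non-negative")
    TRUE
})

#' FpEstimate: deconvolved MAF distribution of true variants
#'
#' Mixture deconvolution of the screened-in MAF distribution into its
#' monomorphic (artifact) and truly polymorphic components, with the CDF of
#' the polymorphic component estimated by isotonic regression.
#'
#' @slot support pooled sorted MAF values from the observed and monomorphic
#'   screened-in loci.
#' @slot cdf isotonic CDF estimate of the true-variant MAF distribution on
#'   `support`; 1 beyond the largest support point.
#' @slot phiHat estimated proportion of artifact loci among screened-in loci.
#' @slot mPHat estimated number of truly polymorphic loci (clamped at 0).
#' @slot mS,mM counts of screened-in loci in the observed and monomorphic
#'   data.
#' @export
setClass("FpEstimate", representation(
    support = "numeric", cdf = "numeric", phiHat = "numeric",
    mPHat = "integer", mS = "integer", mM = "integer"))

setValidity("FpEstimate", function(object) {
    if (length(object@cdf)) {
        if (is.unsorted(object@cdf)) return("cdf must be nondecreasing")
        if (min(object@cdf) < -1e-12 || max(object@cdf) > 1 + 1e-12)
            return("cdf must lie in [0, 1]")
    }
    if (object@mPHat < 0) return("mPHat must be non-negative")
    TRUE
})

#' BootstrapOutcome: sequentially stopped bootstrap p-value
#'
#' @slot pValue bootstrap p-value in (0, 1].
#' @slot kObs replicates generated at termination.
#' @slot lObs exceedances of the observed statistic at termination.
#' @slot stoppedEarly TRUE when the early stopping rule fired before
#'   `kMax`.
#' @slot log per-replicate data.frame (replicate, mM, mPHat, zStar, exceed).
#' @export
setClass("BootstrapOutcome", representation(
    pValue = "numeric", kObs = "integer", lObs = "integer",
    stoppedEarly = "logical", log = "data.frame"))

setValidity("BootstrapOutcome", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    TRUE
})

#' QcReport: read-based QC actions for one gene
#'
#' @slot masked data.frame (locus, sample, Q) of masked entries.
#' @slot droppedLoci integer indices of loci removed entirely.
#' @slot sampleExceedance named integer; per-sample count of Q exceedances.
#' @slot qMask,locusDrop thresholds used.
#' @export
setClass("QcReport", representation(
    masked = "data.frame", droppedLoci = "integer",
    sampleExceedance = "integer", qMask = "numeric", locusDrop = "numeric"))
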