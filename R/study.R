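#' Burden score test on true genotypes
#'
#' Gold-standard reference: the classical weighted burden score test
#' applied to the true simulated genotypes, with weights and binomial
#' variance at the sample allele frequencies.
#'
#' @param G n x m genotype matrix.
#' @param d 0/1 case indicator.
#' @param weighting weight mode (see [madsenBrowningWeight()]).
#' @param mafCap test only variants with sample MAF `<= mafCap`.
#' @return A [BurdenResult-class].
#' @export
trueGenotypeBurden <- function(G, d, weighting = c("mb", "mb2", "none"),
                               mafCap = 0.05) {
    weighting <- match.arg(weighting)
    n <- length(d); n1 <- sum(d); n0 <- n - n1
    pis <- colMeans(G) / 2
    use <- which(pis > 0 & pis <= mafCap)
    if (length(use) == 0)
        return(methods::new("BurdenResult", z = NA_real_, w = 0, v = 0,
            perLocusScore = numeric(0), weights = numeric(0),
            loci = integer(0), pAsym = NA_real_, degenerate = TRUE))
    wts <- madsenBrowningWeight(pis[use], weighting)
    s <- as.numeric(crossprod(G[, use, drop = FALSE], d - n1 / n))
    W <- sum(wts * s)
    V <- (n1 * n0 / n) * sum(wts^2 * 2 * pis[use] * (1 - pis[use]))
    z <- W / sqrt(V)
    methods::new("BurdenResult", z = z, w = W, v = V, perLocusScore = s,
        weights = wts, loci = as.integer(use),
        pAsym = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Replicated null/power simulation study
#'
#' Runs the simulator `nrep` times over a fixed base population and
#' applies the selected analysis methods to each replicate, returning one
#' row per replicate and method with the test statistic and asymptotic
#' p-value. Methods:
#' \describe{
#'   \item{new}{the read-based burden test ([geneBurden()]).}
#'   \item{cg}{hard genotype calls ([cgBurdenTest()]).}
#'   \item{dose}{posterior dosages with robust variance
#'     ([doseBurdenTest()]).}
#'   \item{true}{true genotypes ([trueGenotypeBurden()]).}
#' }
#' With `screen = FALSE` the true variant rows are analyzed (known
#' positions); with `screen = TRUE` the tested loci come from the
#' derivative screening rule (and `threshold = TRUE` additionally applies
#' the singleton MAF cutoff). Bootstrap p-values are not computed here;
#' see [bootstrapPvalue()].
#'
#' @param cfg a [simConfig()].
#' @param nrep replicate count.
#' @param methods subset of `c("new", "cg", "dose", "true")`.
#' @param lociMode `"snv"` simulates reads only at variant loci (cheap,
#'   known-position analyses); `"all"` simulates the whole gene (required
#'   when `screen = TRUE`).
#' @param screen use screening to select tested loci.
#' @param threshold apply the singleton MAF threshold after screening.
#' @param weighting,mafCap,variance burden options.
#' @param pop optional pre-built base population.
#' @return data.frame with columns `rep`, `method`, `z`, `p`, `mS`,
#'   `nTested`.
#' @export
simulationStudy <- function(cfg, nrep,
                            methods = c("new", "cg", "dose", "true"),
                            lociMode = c("snv", "all"), screen = FALSE,
                            threshold = FALSE, weighting = "mb",
                            mafCap = 0.05, variance = "efficient",
                            pop = NULL) {
    lociMode <- match.arg(lociMode)
    methods <- match.arg(methods, several.ok = TRUE)
    if (screen && lociMode != "all")
        stop("screening requires lociMode = 'all'")
    if (is.null(pop)) pop <- generateBasePopulation(cfg)
    out <- vector("list", nrep)
    for (b in seq_len(nrep)) {
        st <- .simStudyRaw(cfg, pop, lociMode)
        tt <- st$tt; rr <- st$rr; d <- st$d
        loci <- if (screen) .screenMatrices(tt, rr, d) else st$snvRows
        mS <- length(loci)
        fits <- .fitLoci(tt, rr, d, loci)
        if (threshold && length(loci)) {
            cut <- 1 / (2 * length(d))
            loci <- loci[vapply(loci, function(j) fits[[j]]$pi0, 0) >= cut]
        }
        rows <- lapply(methods, function(m) {
            res <- switch(m,
                new = .burdenCore(tt, rr, d, fits, loci, weighting,
                                  mafCap, variance),
                cg = .cgCore(d, fits, loci, weighting, mafCap),
                dose = .doseCore(d, fits, loci, weighting, mafCap),
                true = trueGenotypeBurden(st$G, d, weighting, mafCap))
            data.frame(rep = b, method = m, z = res@z, p = res@pAsym,
                       mS = mS, nTested = length(res@loci))
        })
        out[[b]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
}
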