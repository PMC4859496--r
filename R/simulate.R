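#' Simulation configuration
#'
#' Parameters of the case-control read simulator. Defaults describe the
#' reference study design used throughout: a 3-exon gene with 2,730 exonic
#' loci carrying 44 rare variants (MAF spectrum with density proportional
#' to `1/x` on `[1/nHaplotypes, 0.05]`, the neutral-like shape under which
#' singletons dominate), 500 cases and 500 controls, locus-specific mean
#' depths drawn from a rescaled beta law matched to the sequencing depth
#' (see `depthShapeCase`) with negative-binomial dispersion of the
#' per-sample counts,
#' locus-specific error rates from a `Beta(2, b)` with the requested mean,
#' and a logit disease model with equal attributable risk per variant
#' (`AR = 0` gives the null; the intercept -3 gives a disease rate near
#' 5%). Depths and error rates are drawn independently for cases and
#' controls at each locus (two sequencing pipelines) unless
#' `sharedPipeline = TRUE`.
#'
#' @param nHaplotypes base-population haplotype count.
#' @param lociPerGene number of exonic loci in the gene.
#' @param nExons exon count; introns are `intronFactor` times the exon
#'   length and carry no analyzed loci.
#' @param intronFactor intron/exon length ratio (layout only).
#' @param nSnv number of variant loci in the base population.
#' @param mafMax upper end of the variant MAF spectrum.
#' @param recomb recombination probability at each intron boundary when
#'   sampling gametes from the pool.
#' @param nCases,nControls sample sizes.
#' @param depthCase,depthCtrl mean sequencing depths.
#' @param errCase,errCtrl mean per-read error rates.
#' @param depthShapeCase,depthShapeCtrl beta shapes for locus mean depth;
#'   `NULL` resolves by target depth (high-depth exome-like profile
#'   `Beta(2.1, 4.1)` at 20x and above, low-depth genome-like profile
#'   `Beta(4.6, 4.8)` below), so equal target depths imply identical
#'   locus-depth laws in the two groups.
#' @param nbDispersion negative-binomial size parameter of individual
#'   depths (variance `c + c^2/size`).
#' @param errShape first beta shape for locus error rates; the second is
#'   solved from the mean.
#' @param AR attributable risk per variant.
#' @param alphaRisk disease-model intercept.
#' @param sharedPipeline reuse the same locus depth means and error rates
#'   for cases and controls.
#' @return a classed list of settings.
#' @export
simConfig <- function(nHaplotypes = 1e5, lociPerGene = 2730, nExons = 3,
                      intronFactor = 3, nSnv = 44, mafMax = 0.05,
                      recomb = 0.5, nCases = 500, nControls = 500,
                      depthCase = 30, depthCtrl = 6,
                      errCase = 2e-4, errCtrl = 2e-4,
                      depthShapeCase = NULL,
                      depthShapeCtrl = NULL,
                      nbDispersion = 5, errShape = 2,
                      AR = 0, alphaRisk = -3, sharedPipeline = FALSE) {
    cfg <- as.list(environment())
    shapeFor <- function(depth)
        if (depth >= 20) c(2.1, 4.1) else c(4.6, 4.8)
    if (is.null(cfg$depthShapeCase))
        cfg$depthShapeCase <- shapeFor(depthCase)
    if (is.null(cfg$depthShapeCtrl))
        cfg$depthShapeCtrl <- shapeFor(depthCtrl)
    stopifnot(cfg$depthCase > 0, cfg$depthCtrl > 0, cfg$errCase > 0,
              cfg$errCtrl > 0, cfg$AR >= 0, cfg$nSnv <= cfg$lociPerGene)
    class(cfg) <- "SimConfig"
    cfg
}

#' Generate the base haplotype population
#'
#' Rare-variant positions are placed uniformly among the exonic loci and
#' their MAFs drawn from the density proportional to `1/x` on
#' `[1/nHaplotypes, mafMax]` (inverse-CDF: `x = xmin * (xmax/xmin)^U`).
#' Haplotype alleles are independent across variants (rare variants carry
#' essentially no linkage disequilibrium); pools in which a variant ended
#' up with no carriers are redrawn at that variant.
#'
#' @param cfg a [simConfig()] object.
#' @return list with `pool` (haplotypes x variants 0/1 matrix), `snvLoci`
#'   (row indices of the variants among the gene's loci), `mafs` (realized
#'   pool frequencies), `exonOf` (exon index per locus), and `positions`
#'   (genomic coordinates of the exonic loci under the exon/intron
#'   layout).
#' @export
generateBasePopulation <- function(cfg) {
    L <- cfg$lociPerGene
    exonLen <- ceiling(L / cfg$nExons)
    exonOf <- ((seq_len(L) - 1) %/% exonLen) + 1
    # genomic ladder: exons separated by introns of intronFactor * exonLen
    offset <- (exonOf - 1) * exonLen * cfg$intronFactor
    positions <- seq_len(L) + offset

    xmin <- 1 / cfg$nHaplotypes; xmax <- cfg$mafMax
    mafTarget <- xmin * (xmax / xmin)^runif(cfg$nSnv)
    snvLoci <- sort(sample.int(L, cfg$nSnv))
    pool <- matrix(FALSE, cfg$nHaplotypes, cfg$nSnv)
    for (j in seq_len(cfg$nSnv)) {
        repeat {
            carriers <- runif(cfg$nHaplotypes) < mafTarget[j]
            if (any(carriers)) break
        }
        pool[, j] <- carriers
    }
    list(pool = pool, snvLoci = snvLoci, mafs = colMeans(pool),
         exonOf = exonOf, positions = positions)
}

#' Sample diploid genotypes from the haplotype pool
#'
#' Each individual receives two gametes; within a gamete the haplotype
#' index is constant inside an exon and switches to a fresh uniform draw at
#' each intron boundary with probability `recomb` (exon-internal haplotype
#' structure is never broken).
#'
#' @param pop result of [generateBasePopulation()].
#' @param n number of individuals.
#' @param recomb per-intron recombination probability.
#' @return n x nSnv genotype matrix with entries 0/1/2.
#' @export
sampleIndividuals <- function(pop, n, recomb = 0.5) {
    nHap <- nrow(pop$pool)
    nB <- max(pop$exonOf)
    nSnv <- ncol(pop$pool)
    blockOf <- pop$exonOf[pop$snvLoci]
    colBase <- (seq_len(nSnv) - 1L) * nHap
    gam <- function() {
        idx <- matrix(0L, n, nB)
        idx[, 1] <- sample.int(nHap, n, replace = TRUE)
        for (b in seq_len(nB - 1) + 1) {
            col <- idx[, b - 1]
            sw <- which(runif(n) < recomb)
            if (length(sw))
                col[sw] <- sample.int(nHap, length(sw), replace = TRUE)
            idx[, b] <- col
        }
        # gather alleles with one linear index over the pool matrix
        lin <- idx[, blockOf, drop = FALSE] +
            rep(colBase, each = n)
        matrix(pop$pool[lin] + 0L, n, nSnv)
    }
    gam() + gam()
}

#' Disease status under the equal-attributable-risk model
#'
#' `logit P(D = 1) = alphaRisk + sum_j G_j log(1 + AR / (2 pi_j))`: every
#' variant carries the same attributable risk, so rarer variants have
#' larger per-allele effects. The logit is clipped at +-30.
#'
#' @param G n x m genotype matrix.
#' @param mafs variant MAFs (positive).
#' @param AR attributable risk per variant.
#' @param alphaRisk intercept.
#' @return 0/1 disease indicator vector.
#' @export
assignPhenotype <- function(G, mafs, AR, alphaRisk = -3) {
    stopifnot(all(mafs > 0))
    eta <- alphaRisk + as.numeric(G %*% log(1 + AR / (2 * mafs)))
    eta <- pmin(pmax(eta, -30), 30)
    rbinom(length(eta), 1L, 1 / (1 + exp(-eta)))
}

#' Locus-specific mean depths and individual depth matrix
#'
#' Locus mean depths are beta draws rescaled so their expectation equals
#' the target mean; individual depths are negative-binomial around the
#' locus mean, giving overdispersed counts.
#'
#' @param L locus count.
#' @param n sample count.
#' @param meanDepth target average depth.
#' @param shape length-2 beta shapes.
#' @param size negative-binomial dispersion.
#' @return list with `c` (locus means) and `t` (L x n integer matrix).
#' @export
sampleDepths <- function(L, n, meanDepth, shape, size = 5) {
    cLoc <- meanDepth * rbeta(L, shape[1], shape[2]) *
        (shape[1] + shape[2]) / shape[1]
    tt <- matrix(as.integer(rnbinom(L * n, size = size, mu = cLoc)),
                 nrow = L)
    list(c = cLoc, t = tt)
}

#' Locus-specific error rates
#'
#' Beta draws with first shape `a` and mean equal to the target rate.
#'
#' @param L locus count.
#' @param meanErr target mean error rate.
#' @param a first beta shape.
#' @return vector of rates in (0, 1).
#' @export
sampleErrors <- function(L, meanErr, a = 2) {
    b <- a * (1 - meanErr) / meanErr
    rbeta(L, a, b)
}

#' Reads given depths, genotypes and error rates
#'
#' Elementwise binomial read generation: the minor-read rate is `eps`,
#' 0.5 or `1 - eps` for genotype 0, 1, 2.
#'
#' @param tt L x n depth matrix.
#' @param epsMat L x n (or L x 1, recycled) error-rate matrix.
#' @param g L x n genotype matrix (default all zero).
#' @return L x n integer matrix of minor-allele read counts.
#' @export
generateReads <- function(tt, epsMat, g = NULL) {
    if (is.null(g)) g <- matrix(0L, nrow(tt), ncol(tt))
    epsMat <- matrix(epsMat, nrow(tt), ncol(tt))
    p <- ifelse(g == 0L, epsMat, ifelse(g == 1L, 0.5, 1 - epsMat))
    matrix(as.integer(rbinom(length(tt), as.vector(tt), as.vector(p))),
           nrow = nrow(tt), dimnames = dimnames(tt))
}

#' Simulate a complete case-control sequencing study
#'
#' Composes the base population, gamete sampling, the disease model
#' (individuals are drawn until the configured numbers of cases and
#' controls are reached), per-group depth and error-rate generation, and
#' binomial read generation. Samples are ordered cases first. The truth
#' (genotypes, variant rows, MAFs, locus error rates and depth means) is
#' returned alongside the read data for parameter-recovery checks.
#'
#' @param cfg a [simConfig()] object.
#' @param pop optional pre-built [generateBasePopulation()] result, reused
#'   across replicates.
#' @param lociMode `"all"` simulates reads at every exonic locus;
#'   `"snv"` restricts the read matrices to the variant loci (the
#'   known-positions analysis mode).
#' @return list with `grm` (a [GeneReadMatrix-class]), `G` (n x nSnv true
#'   genotypes), `snvRows` (row indices of variants in `grm`), `mafs`,
#'   `epsCase`, `epsCtrl`, `depthMeanCase`, `depthMeanCtrl`.
#' @export
simulateCaseControlStudy <- function(cfg, pop = NULL,
                                     lociMode = c("all", "snv")) {
    lociMode <- match.arg(lociMode)
    if (is.null(pop)) pop <- generateBasePopulation(cfg)
    raw <- .simStudyRaw(cfg, pop, lociMode)
    pos <- if (lociMode == "all") pop$positions else
        pop$positions[pop$snvLoci]
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
    grm <- GeneReadMatrix(raw$tt, raw$rr, raw$d, rowRanges = gr,
                          gene = "simGene")
    list(grm = grm, G = raw$G, snvRows = raw$snvRows, mafs = raw$mafs,
         epsCase = raw$epsCase, epsCtrl = raw$epsCtrl,
         depthMeanCase = raw$depthMeanCase,
         depthMeanCtrl = raw$depthMeanCtrl)
}

# matrix-level generator behind simulateCaseControlStudy, shared with the
# replicated-study driver (skips container construction)
.simStudyRaw <- function(cfg, pop, lociMode) {
    n1 <- cfg$nCases; n0 <- cfg$nControls

    # accumulate cases/controls until both quotas are met; the expected
    # disease rate near exp(alphaRisk) sets the first batch size
    pDis <- 1 / (1 + exp(-cfg$alphaRisk))
    caseRows <- list(); ctrlRows <- list()
    nc <- 0L; n00 <- 0L
    while (nc < n1 || n00 < n0) {
        batch <- ceiling(1.25 * max((n1 - nc) / pDis,
                                    (n0 - n00) / (1 - pDis), 500))
        G <- sampleIndividuals(pop, batch, cfg$recomb)
        D <- assignPhenotype(G, pop$mafs, cfg$AR, cfg$alphaRisk)
        caseRows <- c(caseRows, list(G[D == 1L, , drop = FALSE]))
        ctrlRows <- c(ctrlRows, list(G[D == 0L, , drop = FALSE]))
        nc <- nc + sum(D == 1L); n00 <- n00 + sum(D == 0L)
    }
    Gc <- do.call(rbind, caseRows); G0 <- do.call(rbind, ctrlRows)
    G <- rbind(Gc[seq_len(n1), , drop = FALSE],
               G0[seq_len(n0), , drop = FALSE])
    d <- c(rep(1L, n1), rep(0L, n0))

    L <- if (lociMode == "all") cfg$lociPerGene else cfg$nSnv
    snvRows <- if (lociMode == "all") pop$snvLoci else seq_len(cfg$nSnv)

    dep1 <- sampleDepths(L, n1, cfg$depthCase, cfg$depthShapeCase,
                         cfg$nbDispersion)
    eps1 <- sampleErrors(L, cfg$errCase, cfg$errShape)
    if (cfg$sharedPipeline) {
        dep0 <- list(c = dep1$c * cfg$depthCtrl / cfg$depthCase,
                     t = matrix(as.integer(rnbinom(L * n0,
                         size = cfg$nbDispersion,
                         mu = dep1$c * cfg$depthCtrl / cfg$depthCase)),
                         nrow = L))
        eps0 <- eps1
    } else {
        dep0 <- sampleDepths(L, n0, cfg$depthCtrl, cfg$depthShapeCtrl,
                             cfg$nbDispersion)
        eps0 <- sampleErrors(L, cfg$errCtrl, cfg$errShape)
    }

    tt <- cbind(dep1$t, dep0$t)
    # error-only reads everywhere (the per-locus error rate recycles down
    # each group's column-major block), then overwrite variant carriers
    rr <- cbind(
        matrix(as.integer(rbinom(L * n1, as.vector(dep1$t), eps1)), L),
        matrix(as.integer(rbinom(L * n0, as.vector(dep0$t), eps0)), L))
    for (k in seq_along(snvRows)) {
        j <- snvRows[k]
        carriers <- which(G[, k] > 0L)
        if (!length(carriers)) next
        epsRow <- ifelse(carriers <= n1, eps1[j], eps0[j])
        p <- ifelse(G[carriers, k] == 1L, 0.5, 1 - epsRow)
        rr[j, carriers] <- as.integer(rbinom(length(carriers),
                                             tt[j, carriers], p))
    }

    list(tt = tt, rr = rr, d = d, G = G, snvRows = snvRows,
         mafs = pop$mafs, epsCase = eps1, epsCtrl = eps0,
         depthMeanCase = dep1$c, depthMeanCtrl = dep0$c)
}
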