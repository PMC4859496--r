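test_that("variant spectrum is singleton-heavy and reproducible under a seed", {
    cfg <- simConfig(nHaplotypes = 2e4, lociPerGene = 500, nSnv = 200)
    set.seed(430); p1 <- generateBasePopulation(cfg)
    set.seed(430); p2 <- generateBasePopulation(cfg)
    expect_identical(p1$mafs, p2$mafs)
    expect_identical(p1$snvLoci, p2$snvLoci)
    # 1/x density: more mass below 0.005 than in [0.005, 0.05]
    expect_gt(mean(p1$mafs < 0.005), mean(p1$mafs >= 0.005))
    expect_true(all(p1$mafs > 0))
})

test_that("average variant count per region is near its target over seeds", {
    set.seed(431)
    cfg <- simConfig(nHaplotypes = 2e4)
    counts <- replicate(5, {
        pop <- generateBasePopulation(cfg)
        sum(pop$mafs <= 0.05 & pop$mafs > 0)
    })
    expect_lt(abs(mean(counts) - 44) / 44, 0.2)
})

test_that("gamete sampling: intact haplotypes without recombination, HWE margins", {
    set.seed(432)
    cfg <- simConfig(nHaplotypes = 5000, lociPerGene = 300, nSnv = 60)
    pop <- generateBasePopulation(cfg)
    G <- sampleIndividuals(pop, 3000, recomb = 0)
    # genotype frequencies match HWE at pool MAFs (chi-square over loci)
    pis <- pop$mafs
    keep <- which(pis > 0.01)
    stat <- vapply(keep, function(j) {
        obs <- tabulate(G[, j] + 1L, 3)
        ex <- 3000 * c((1 - pis[j])^2, 2 * pis[j] * (1 - pis[j]), pis[j]^2)
        sum((obs - ex)^2 / pmax(ex, 1e-9))
    }, 0)
    # each is ~ chi-square(2); the mean over loci should be near 2
    expect_lt(mean(stat), 4)
    # recomb = 0: each gamete is one pool haplotype; exon-block alleles of
    # an individual must appear together in some pool haplotype pair
    G1 <- sampleIndividuals(pop, 5, recomb = 0)
    expect_true(all(G1 %in% 0:2))
})

test_that("disease model: baseline rate, carrier log-odds shift, rarer is stronger", {
    expect_equal(1 / (1 + exp(3)), 0.0474, tolerance = 1e-3)
    # carrier of one copy at pi = 0.005 under AR = 0.01 shifts by log 2
    expect_equal(log(1 + 0.01 / (2 * 0.005)), log(2))
    shift <- function(pi) log(1 + 0.01 / (2 * pi))
    expect_true(all(diff(shift(c(0.001, 0.005, 0.02, 0.05))) < 0))
    set.seed(433)
    D <- assignPhenotype(matrix(0L, 5000, 2), c(0.01, 0.02), AR = 0)
    expect_lt(abs(mean(D) - 0.0474), 0.012)
})

test_that("depths: rescaled beta means, overdispersion, shared-pipeline mode", {
    set.seed(434)
    dep <- sampleDepths(400, 300, meanDepth = 6, shape = c(4.6, 4.8))
    expect_lt(abs(mean(dep$t) - 6) / 6, 0.02)
    # negative binomial exceeds Poisson dispersion at the locus level
    v <- apply(dep$t[1:50, ], 1, var)
    m <- rowMeans(dep$t[1:50, ])
    expect_gt(mean(v / m), 1.2)
    cfgS <- simConfig(lociPerGene = 200, nSnv = 4, depthCase = 6,
                      depthCtrl = 6, sharedPipeline = TRUE,
                      nCases = 30, nControls = 30)
    st <- ReadBurden:::.simStudyRaw(cfgS, generateBasePopulation(cfgS),
                                    "all")
    expect_identical(st$epsCase, st$epsCtrl)
    expect_equal(st$depthMeanCase, st$depthMeanCtrl)
})

test_that("error rates: beta draws hit the target mean and stay in range", {
    set.seed(435)
    e <- sampleErrors(20000, 2e-4)
    expect_lt(abs(mean(e) - 2e-4) / 2e-4, 0.1)
    expect_true(all(e > 0 & e < 0.5))
    ks <- suppressWarnings(
        ks.test(e, function(q) pbeta(q, 2, 2 * (1 - 2e-4) / 2e-4)))
    expect_gt(ks$p.value, 0.001)
})

test_that("read generation follows the three genotype rates", {
    set.seed(436)
    tt <- matrix(20L, 3, 2000)
    g <- rbind(0L, 1L, 2L)[, rep(1, 2000), drop = FALSE]
    g <- matrix(rep(0:2, 2000), 3)
    rr <- generateReads(tt, matrix(0.01, 3, 2000), g)
    rates <- rowSums(rr) / rowSums(tt)
    expect_lt(abs(rates[1] - 0.01), 0.005)
    expect_lt(abs(rates[2] - 0.5), 0.01)
    expect_lt(abs(rates[3] - 0.99), 0.005)
    # zero error and reference genotypes give zero minor reads
    expect_true(all(generateReads(tt, matrix(1e-300, 3, 2000)) == 0))
})

test_that("a full study delivers exact quotas, null MAF balance, and a runnable gene", {
    set.seed(437)
    cfg <- simConfig(lociPerGene = 120, nSnv = 10, depthCase = 12,
                     depthCtrl = 6, nCases = 80, nControls = 90)
    st <- simulateCaseControlStudy(cfg)
    expect_identical(nCases(st$grm), 80L)
    expect_identical(nControls(st$grm), 90L)
    expect_identical(dim(totalReads(st$grm)), c(120L, 170L))
    # under AR = 0 case and control MAFs agree in expectation
    dAll <- phenotype(st$grm)
    mafCase <- colMeans(st$G[dAll == 1L, , drop = FALSE]) / 2
    mafCtrl <- colMeans(st$G[dAll == 0L, , drop = FALSE]) / 2
    expect_lt(abs(mean(mafCase - mafCtrl)), 0.01)
    # smoke: the full pipeline runs and logs sensible fields
    rec <- runGene(st$grm, mode = "SB", kMax = 40L, seed = 7L)
    expect_true(is.finite(rec$mS))
    expect_gt(rec$p, 0)
    expect_lte(rec$p, 1)
})
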