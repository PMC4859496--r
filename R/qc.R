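#' Goodness-of-fit statistic for the binomial read model
#'
#' Likelihood-ratio-type statistic comparing the saturated binomial fit at
#' the observed minor-read fraction against the best of the three
#' genotype-implied read rates `eps`, 0.5, `1 - eps`:
#' `Q = 2 * log[ (r/t)^r (1-r/t)^(t-r) / max_g e_g^r (1-e_g)^(t-r) ]`,
#' with the convention `0^0 = 1`. `Q >= 0` always; large values indicate
#' read data (mosaicism, contamination, CNVs, artifacts) that no genotype
#' explains. `t = 0` returns 0.
#'
#' @param r,t minor-allele and total read counts (vectorized).
#' @param eps per-read error rate used for the homozygote rates.
#' @return Q value(s).
#' @examples
#' qStatistic(3, 10, 0.01)  # 1.6457
#' @export
qStatistic <- function(r, t, eps) {
    n <- max(length(r), length(t), length(eps))
    r <- rep_len(r, n); t <- rep_len(t, n); eps <- rep_len(eps, n)
    stopifnot(all(r >= 0), all(r <= t), all(eps >= 0), all(eps <= 0.5))
    out <- numeric(n)
    pos <- t > 0
    if (!any(pos)) return(out)
    r <- r[pos]; t <- t[pos]; eps <- eps[pos]
    lsat <- ifelse(r > 0, r * log(r / t), 0) +
            ifelse(t - r > 0, (t - r) * log(1 - r / t), 0)
    lg <- function(p) r * log(p) + (t - r) * log1p(-p)
    lbest <- pmax(lg(pmin(pmax(eps, 1e-300), 1 - 1e-16)), lg(0.5),
                  lg(pmax(1 - eps, 1e-16)))
    out[pos] <- pmax(2 * (lsat - lbest), 0)
    out
}

#' Apply read-based QC to a gene
#'
#' Computes Q at each screened-in locus for every covered sample (using the
#' sample's group error rate), masks entries with `Q > qMask` by zeroing
#' both read counts, and drops loci where more than `locusDrop` samples
#' were masked. The rule boundaries are strict: `Q = qMask` is kept, and a
#' locus with exactly `locusDrop` masked samples is kept.
#'
#' @param grm a [GeneReadMatrix-class].
#' @param eps loci x 2 matrix of error rates (columns case, control),
#'   typically the adjusted-EB estimates from [geneErrorRates()].
#' @param loci loci at which to evaluate Q (the screened-in set).
#' @param qMask masking threshold on Q.
#' @param locusDrop maximum tolerated masked samples per locus.
#' @return list with the cleaned `grm` and a [QcReport-class].
#' @export
applyQc <- function(grm, eps, loci, qMask = 10, locusDrop = 5) {
    tt <- totalReads(grm); rr <- altReads(grm)
    d <- phenotype(grm)
    # per-sample column: the sample's own group's error rate at the locus
    epsMat <- eps[loci, , drop = FALSE][, 2L - (d == 1L), drop = FALSE]
    qs <- matrix(qStatistic(as.vector(rr[loci, , drop = FALSE]),
                            as.vector(tt[loci, , drop = FALSE]),
                            as.vector(epsMat)),
                 nrow = length(loci))
    bad <- which(qs > qMask, arr.ind = TRUE)
    masked <- data.frame(
        locus = if (nrow(bad)) loci[bad[, 1]] else integer(0),
        sample = if (nrow(bad)) bad[, 2] else integer(0),
        Q = if (nrow(bad)) qs[bad] else numeric(0))
    if (nrow(masked)) {
        idx <- cbind(masked$locus, masked$sample)
        tt[idx] <- 0L; rr[idx] <- 0L
    }
    perLocus <- table(factor(masked$locus, levels = loci))
    dropped <- loci[as.integer(perLocus) > locusDrop]
    if (length(dropped)) {
        keepRows <- setdiff(seq_len(nrow(tt)), dropped)
        tt <- tt[keepRows, , drop = FALSE]
        rr <- rr[keepRows, , drop = FALSE]
        grmOut <- GeneReadMatrix(tt, rr, d,
            rowRanges = SummarizedExperiment::rowRanges(grm)[keepRows],
            gene = geneName(grm))
    } else {
        grmOut <- GeneReadMatrix(tt, rr, d,
            rowRanges = SummarizedExperiment::rowRanges(grm),
            gene = geneName(grm))
    }
    exceed <- integer(ncol(tt))
    if (nrow(masked)) {
        tab <- table(factor(masked$sample, levels = seq_len(ncol(tt))))
        exceed <- as.integer(tab)
    }
    names(exceed) <- colnames(totalReads(grm))
    report <- methods::new("QcReport", masked = masked,
        droppedLoci = as.integer(dropped), sampleExceedance = exceed,
        qMask = qMask, locusDrop = locusDrop)
    list(grm = grmOut, report = report)
}

#' Flag samples with excessive QC exceedances
#'
#' Samples whose count of `Q > qMask` events exceeds `threshold` are
#' reported; such samples (batch artifacts, contamination) are candidates
#' for exclusion. The statistic itself does not define "excessive", so the
#' default threshold is the 99.9th percentile of the per-sample counts.
#'
#' @param report a [QcReport-class].
#' @param threshold exceedance-count threshold (strict `>`).
#' @return integer indices (or names) of flagged samples.
#' @export
flagSamples <- function(report,
                        threshold = quantile(report@sampleExceedance,
                                             0.999)) {
    which(report@sampleExceedance > threshold)
}

#' Serialize a QC report
#'
#' @param report a [QcReport-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeQcReport <- function(report, path) {
    m <- report@masked
    m$action <- "masked"
    if (length(report@droppedLoci))
        m$action[m$locus %in% report@droppedLoci] <- "locus_dropped"
    write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
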