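#' Read a per-locus read-count table
#'
#' Two tab-delimited layouts are accepted, detected from the header:
#' columns `chrom, pos, sample, t, r` (plain counts), or
#' `chrom, pos, ref, sample, counts` with an allele-count string such as
#' `"A10C1"` (10 reads of A, 1 of C). In string mode the minor-allele
#' count `r` pools every non-reference read (so `"A10C1G1"` with
#' reference A gives `t = 12, r = 2`) unless `alleleMode = "major"`, which
#' takes `t` as reference-plus-top-alternate reads only. Positions are
#' 1-based.
#'
#' @param path counts TSV.
#' @param alleleMode non-reference pooling rule for string mode.
#' @return data.frame with columns `chrom, pos, sample, t, r`.
#' @export
readCountsTable <- function(path, alleleMode = c("pooled", "major")) {
    alleleMode <- match.arg(alleleMode)
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (all(c("t", "r") %in% names(df))) {
        out <- df[, c("chrom", "pos", "sample", "t", "r")]
    } else if (all(c("ref", "counts") %in% names(df))) {
        parsed <- lapply(seq_len(nrow(df)), function(i) {
            s <- df$counts[i]
            m <- gregexpr("([ACGTN])([0-9]+)", s)
            if (m[[1]][1] == -1)
                stop("malformed allele-count string at line ", i + 1,
                     ": '", s, "'")
            pieces <- regmatches(s, m)[[1]]
            if (sum(nchar(pieces)) != nchar(s))
                stop("malformed allele-count string at line ", i + 1,
                     ": '", s, "'")
            al <- substr(pieces, 1, 1)
            ct <- as.integer(sub("^[ACGTN]", "", pieces))
            refCt <- sum(ct[al == df$ref[i]])
            altCt <- ct[al != df$ref[i]]
            if (alleleMode == "pooled")
                c(refCt + sum(altCt), sum(altCt))
            else {
                top <- if (length(altCt)) max(altCt) else 0L
                c(refCt + top, top)
            }
        })
        parsed <- do.call(rbind, parsed)
        out <- data.frame(chrom = df$chrom, pos = df$pos,
                          sample = df$sample,
                          t = parsed[, 1], r = parsed[, 2])
    } else stop("unrecognized counts-table header")
    if (any(out$t < 0) || any(out$r < 0) || any(out$r > out$t))
        stop("invalid counts at line(s) ",
             paste(which(out$r > out$t | out$t < 0 | out$r < 0) + 1,
                   collapse = ", "))
    if (anyDuplicated(out[, c("chrom", "pos", "sample")]))
        stop("duplicate (position, sample) rows")
    out
}

#' Read a phenotype file
#'
#' Tab-delimited with header `sample, status` (1 = case, 0 = control).
#'
#' @param path phenotype TSV.
#' @return named 0/1 integer vector.
#' @export
readPhenotype <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "status") %in% names(df)),
              all(df$status %in% 0:1))
    setNames(as.integer(df$status), df$sample)
}

#' Read gene regions from BED
#'
#' BED is 0-based half-open with the gene name in column 4; intervals of
#' the same gene are merged. Output coordinates are 1-based inclusive.
#'
#' @param path BED file.
#' @return [GenomicRanges::GRangesList] keyed by gene.
#' @export
readRegions <- function(path) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("readRegions requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0)
        return(GenomicRanges::GRangesList())
    nm <- gr$name
    if (is.null(nm) || anyNA(nm))
        stop("malformed BED: the 4th (name) column is required")
    grl <- GenomicRanges::split(gr, nm)
    GenomicRanges::reduce(grl)
}

#' Assemble per-gene read matrices
#'
#' Joins a counts table, phenotype vector and gene regions into one
#' [GeneReadMatrix-class] per gene. Every (locus, sample) pair inside a
#' region gets a cell; pairs absent from the table are zero coverage.
#'
#' @param counts data.frame from [readCountsTable()].
#' @param phenotype named vector from [readPhenotype()].
#' @param regions [GenomicRanges::GRangesList] from [readRegions()].
#' @return named list of [GeneReadMatrix-class].
#' @export
assembleGenes <- function(counts, phenotype, regions) {
    bad <- setdiff(unique(counts$sample), names(phenotype))
    if (length(bad))
        stop("samples without phenotype: ", paste(bad, collapse = ", "))
    samples <- names(phenotype)
    lapply(setNames(names(regions), names(regions)), function(g) {
        rg <- regions[[g]]
        pos <- unlist(lapply(seq_along(rg), function(k)
            seq(GenomicRanges::start(rg)[k], GenomicRanges::end(rg)[k])))
        chrom <- as.character(GenomicRanges::seqnames(rg)[1])
        sel <- counts$chrom == chrom & counts$pos %in% pos
        cc <- counts[sel, , drop = FALSE]
        tt <- matrix(0L, length(pos), length(samples),
                     dimnames = list(pos, samples))
        rr <- tt
        if (nrow(cc)) {
            idx <- cbind(match(cc$pos, pos), match(cc$sample, samples))
            tt[idx] <- as.integer(cc$t)
            rr[idx] <- as.integer(cc$r)
        }
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(pos, width = 1))
        GeneReadMatrix(tt, rr, phenotype, rowRanges = gr, gene = g,
                       chrom = chrom)
    })
}

#' Write a simulated study to disk
#'
#' Emits the counts TSV (plain layout), the phenotype TSV, a single-gene
#' BED region, and a truth TSV for recovery checks.
#'
#' @param study result of [simulateCaseControlStudy()].
#' @param dir output directory (created).
#' @param gene gene/region name.
#' @return named vector of file paths, invisibly.
#' @export
writeStudy <- function(study, dir, gene = "simGene") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    grm <- study$grm
    tt <- totalReads(grm); rr <- altReads(grm)
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(grm))
    samples <- colnames(tt)
    if (is.null(samples)) samples <- sprintf("S%04d", seq_len(ncol(tt)))
    nz <- which(tt > 0, arr.ind = TRUE)
    counts <- data.frame(chrom = "chr1", pos = pos[nz[, 1]],
                         sample = samples[nz[, 2]],
                         t = tt[nz], r = rr[nz])
    counts <- counts[order(counts$pos, counts$sample), ]
    paths <- c(counts = file.path(dir, "counts.tsv"),
               phenotype = file.path(dir, "phenotype.tsv"),
               regions = file.path(dir, "regions.bed"),
               truth = file.path(dir, "truth.tsv"))
    write.table(counts, paths["counts"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample = samples,
                           status = phenotype(grm)),
                paths["phenotype"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(sprintf("chr1\t%d\t%d\t%s", min(pos) - 1L, max(pos), gene),
               paths["regions"])
    write.table(data.frame(snvRow = study$snvRows,
                           pos = pos[study$snvRows],
                           maf = study$mafs),
                paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(paths)
}

#' Exome-wide Bonferroni threshold
#'
#' @param alpha family-wise error rate.
#' @param nGenes number of genes tested.
#' @return per-gene significance threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, nGenes) alpha / nGenes

#' Run the full pipeline on one gene
#'
#' Screening, read-based QC, optional singleton-MAF thresholding, null
#' fits, the weighted burden statistic, and the bootstrap p-value, in
#' order, returning a one-row summary record.
#'
#' @param grm a [GeneReadMatrix-class].
#' @param mode `"SB"` (screen + bootstrap) or `"STB"` (adds the singleton
#'   MAF threshold).
#' @param weighting,mafCap,variance burden options (see [geneBurden()]).
#' @param lMin,kMax sequential bootstrap parameters.
#' @param qc apply [applyQc()] between screening and testing.
#' @param bootstrap compute the bootstrap p-value (otherwise only the
#'   asymptotic record is returned, appropriate when variant positions
#'   were known rather than screened).
#' @param seed integer seed recorded in the output and applied before the
#'   stochastic steps.
#' @return one-row data.frame: gene, chrom, L, mS, mSt, mPHat, z, p, kObs,
#'   lObs, mode, seed.
#' @export
runGene <- function(grm, mode = c("SB", "STB"), weighting = "mb",
                    mafCap = 0.05, variance = "efficient",
                    lMin = 5L, kMax = 1000L, qc = TRUE,
                    bootstrap = TRUE, seed = NULL) {
    mode <- match.arg(mode)
    if (!is.null(seed)) set.seed(seed)
    chrom <- as.character(
        GenomicRanges::seqnames(SummarizedExperiment::rowRanges(grm))[1])
    L <- nrow(grm)
    rec <- function(mS, mSt, mPHat, z, p, kObs, lObs)
        data.frame(gene = geneName(grm), chrom = chrom, L = L, mS = mS,
                   mSt = mSt, mPHat = mPHat, z = z, p = p, kObs = kObs,
                   lObs = lObs, mode = mode,
                   seed = if (is.null(seed)) NA_integer_ else seed)

    sg <- screenGene(grm)
    if (sg@mS == 0)
        return(rec(0L, 0L, NA, NA_real_, 1, NA, NA))

    er <- geneErrorRates(grm, .fitLoci(totalReads(grm), altReads(grm),
                                       phenotype(grm), sg@keptLoci),
                         sg@keptLoci)
    if (qc) {
        cleaned <- applyQc(grm, er$aeb, sg@keptLoci)
        if (length(cleaned$report@droppedLoci) ||
            nrow(cleaned$report@masked)) {
            grm <- cleaned$grm
            if (length(cleaned$report@droppedLoci)) {
                keepRows <- setdiff(seq_len(L),
                                    cleaned$report@droppedLoci)
                er$aeb <- er$aeb[keepRows, , drop = FALSE]
            }
            sg <- screenGene(grm) # re-screen the cleaned data
            if (sg@mS == 0)
                return(rec(0L, 0L, NA, NA_real_, 1, NA, NA))
        }
    }

    d <- phenotype(grm)
    fits <- .fitLoci(totalReads(grm), altReads(grm), d, sg@keptLoci)
    sgTest <- if (mode == "STB") applyMafThreshold(sg, length(d)) else sg
    res <- geneBurden(grm, fits, sgTest@keptLoci, weighting = weighting,
                      mafCap = mafCap, variance = variance)
    if (res@degenerate || !bootstrap) {
        fpRec <- NA
        if (bootstrap) { # degenerate statistic: no evidence either way
            return(rec(sg@mS, sgTest@mSt, fpRec, NA_real_, 1, 0L, 0L))
        }
        return(rec(sg@mS, sgTest@mSt, fpRec, res@z, res@pAsym, NA, NA))
    }
    bo <- bootstrapPvalue(grm, res@z, er$aeb, obsMafs = sg@mafHat,
                          lMin = lMin, kMax = kMax, mode = mode,
                          weighting = weighting, mafCap = mafCap,
                          variance = variance)
    mPHat <- if (nrow(bo@log)) bo@log$mPHat[1] else NA
    rec(sg@mS, sgTest@mSt, mPHat, res@z, bo@pValue, bo@kObs, bo@lObs)
}
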