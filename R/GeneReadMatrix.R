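#' Construct a GeneReadMatrix
#'
#' @param total,alt integer matrices (loci x samples) of total and
#'   minor-allele read counts. Row/column names are propagated.
#' @param phenotype 0/1 case indicator, one per sample (1 = case).
#' @param rowRanges optional [GenomicRanges::GRanges] of locus positions; a
#'   dummy single-base ladder on `chrom` is built when absent.
#' @param gene gene identifier stored in the metadata.
#' @param chrom chromosome name used for the dummy ranges.
#'
#' @return A [GeneReadMatrix-class] object.
#' @examples
#' grm <- GeneReadMatrix(total = matrix(5L, 2, 4), alt = matrix(0L, 2, 4),
#'                       phenotype = c(1, 1, 0, 0))
#' nCases(grm)
#' @export
GeneReadMatrix <- function(total, alt, phenotype, rowRanges = NULL,
                           gene = "gene", chrom = "chr1") {
    total <- as.matrix(total); storage.mode(total) <- "integer"
    alt <- as.matrix(alt); storage.mode(alt) <- "integer"
    stopifnot(identical(dim(total), dim(alt)),
              ncol(total) == length(phenotype))
    if (is.null(rowRanges))
        rowRanges <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(seq_len(nrow(total)), width = 1))
    cd <- S4Vectors::DataFrame(phenotype = as.integer(phenotype))
    if (!is.null(colnames(total))) rownames(cd) <- colnames(total)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(total = total, alt = alt),
        rowRanges = rowRanges, colData = cd,
        metadata = list(gene = gene))
    methods::new("GeneReadMatrix", se)
}

#' @rdname GeneReadMatrix
#' @param x a `GeneReadMatrix`.
#' @export
totalReads <- function(x) SummarizedExperiment::assay(x, "total")

#' @rdname GeneReadMatrix
#' @export
altReads <- function(x) SummarizedExperiment::assay(x, "alt")

#' @rdname GeneReadMatrix
#' @export
phenotype <- function(x) x$phenotype

#' @rdname GeneReadMatrix
#' @export
nCases <- function(x) sum(x$phenotype == 1L)

#' @rdname GeneReadMatrix
#' @export
nControls <- function(x) sum(x$phenotype == 0L)

#' @rdname GeneReadMatrix
#' @export
geneName <- function(x) S4Vectors::metadata(x)$gene

setMethod("show", "GeneReadMatrix", function(object) {
    cat(sprintf(
        "GeneReadMatrix '%s': %d loci x %d samples (%d cases, %d controls)\n",
        geneName(object), nrow(object), ncol(object),
        nCases(object), nControls(object)))
    tt <- totalReads(object)
    cat(sprintf("  mean depth: %.2f (cases %.2f, controls %.2f)\n",
        mean(tt), mean(tt[, object$phenotype == 1L, drop = FALSE]),
        mean(tt[, object$phenotype == 0L, drop = FALSE])))
})

setMethod("show", "NullFit", function(object) {
    cat(sprintf(
        "NullFit: pi0 = %.4g, eps(case) = %.4g, eps(ctrl) = %.4g, loglik = %.4f%s\n",
        object@pi0, object@epsCase, object@epsCtrl, object@loglik,
        if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "ScreenedGene", function(object) {
    cat(sprintf("ScreenedGene: %d screened in, %d past MAF threshold\n",
                object@mS, object@mSt))
})

setMethod("show", "BurdenResult", function(object) {
    if (object@degenerate)
        cat("BurdenResult: degenerate (zero variance)\n")
    else
        cat(sprintf("BurdenResult: Z = %.4f (W = %.4f, V = %.4f), %d loci\n",
                    object@z, object@w, object@v, length(object@loci)))
})

setMethod("show", "FpEstimate", function(object) {
    cat(sprintf(
        "FpEstimate: M_s = %d, M_m = %d, phi-hat = %.3f, M_p-hat = %d\n",
        object@mS, object@mM, object@phiHat, object@mPHat))
})

setMethod("show", "BootstrapOutcome", function(object) {
    cat(sprintf(
        "BootstrapOutcome: p = %.4g (K_obs = %d, L_obs = %d, %s)\n",
        object@pValue, object@kObs, object@lObs,
        if (object@stoppedEarly) "stopped early" else "K_max reached"))
})
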