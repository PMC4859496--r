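#' Read-count likelihood given genotype
#'
#' Probability of observing `r` minor-allele reads among `t` total reads at a
#' locus, given the genotype `g` (number of minor alleles) and the per-read
#' error rate `eps`. Reads are modelled as binomial with success probability
#' `eps`, 0.5, or `1 - eps` for `g = 0, 1, 2`. A sample with no coverage
#' (`t = 0`) contributes a factor of 1.
#'
#' @param r minor-allele read count(s).
#' @param t total read count(s).
#' @param g genotype in `{0, 1, 2}` (recycled).
#' @param eps per-read error rate in `[0, 0.5]`.
#' @param log return log-probability.
#' @return numeric vector of (log-)probabilities.
#' @examples
#' readLikelihood(0, 3, 0, 0.01)   # (1 - 0.01)^3
#' readLikelihood(1, 2, 1, 0.3)    # 0.5 regardless of eps
#' @export
readLikelihood <- function(r, t, g, eps, log = FALSE) {
    if (any(r < 0) || any(t < 0) || any(r > t))
        stop("need 0 <= r <= t")
    if (any(eps < 0) || any(eps > 0.5))
        stop("eps must lie in [0, 0.5]")
    if (!all(g %in% 0:2)) stop("g must be 0, 1 or 2")
    p <- ifelse(g == 0, eps, ifelse(g == 1, 0.5, 1 - eps))
    out <- dbinom(r, t, rep_len(p, length.out = max(length(r), length(p))),
                  log = log)
    # t = 0: dbinom(0, 0, p) is already 1, any p
    out
}

#' Hardy-Weinberg genotype prior
#'
#' @param g genotype in `{0, 1, 2}`.
#' @param pi minor allele frequency in `[0, 1]`.
#' @return probability `(1-pi)^2`, `2 pi (1-pi)` or `pi^2`.
#' @examples hwePrior(1, 0.5)
#' @export
hwePrior <- function(g, pi) {
    if (any(pi < 0) || any(pi > 1)) stop("pi must lie in [0, 1]")
    if (!all(g %in% 0:2)) stop("g must be 0, 1 or 2")
    ifelse(g == 0, (1 - pi)^2, ifelse(g == 1, 2 * pi * (1 - pi), pi^2))
}

#' Posterior minor-allele dosage
#'
#' Expected genotype given the reads, under the HWE prior at allele frequency
#' `pi0` and error rate `eps`. With no coverage the prior mean `2 * pi0` is
#' returned; with `pi0 = 0` the dosage is 0.
#'
#' @param r,t minor-allele and total read counts (vectorized).
#' @param pi0 minor allele frequency.
#' @param eps per-read error rate.
#' @return dosage value(s) in `[0, 2]`.
#' @examples
#' posteriorDosage(0, 0, 0.05, 0.01)   # prior mean 0.1
#' @export
posteriorDosage <- function(r, t, pi0, eps) {
    if (any(pi0 < 0) || any(pi0 > 1)) stop("pi0 must lie in [0, 1]")
    n <- max(length(r), length(t))
    r <- rep_len(r, n); t <- rep_len(t, n)
    if (length(pi0) == 1 && pi0 == 0) return(rep(0, n))
    # log-space weights per genotype
    lw <- vapply(0:2, function(g)
        readLikelihood(r, t, g, eps, log = TRUE) + log(hwePrior(g, pi0)),
        numeric(n))
    lw <- matrix(lw, nrow = n)
    m <- apply(lw, 1, max)
    w <- exp(lw - m)
    as.numeric((w[, 2] + 2 * w[, 3]) / rowSums(w))
}
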