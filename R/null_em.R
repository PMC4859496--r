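EPS_MIN <- 1e-8
EPS_MAX <- 0.5

#' Restricted null fit at one locus
#'
#' Maximizes the retrospective read likelihood at a single locus under the
#' null hypothesis of equal minor-allele frequency in cases and controls,
#' over the pooled MAF and group-specific error rates, via EM. Samples with
#' no coverage contribute a factor of 1 and receive the prior-mean dosage.
#'
#' When `screen = TRUE` (default) the derivative-based screening rule is
#' evaluated first; a locus that screens out has its boundary solution
#' `pi0 = 0` returned exactly (all dosages 0) without running the EM.
#'
#' @param t,r integer vectors of total and minor-allele read counts, one per
#'   sample.
#' @param d 0/1 case indicator, aligned with `t` and `r`.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations.
#' @param screen detect the `pi0 = 0` boundary by the screening derivative.
#' @return A [NullFit-class] object.
#' @seealso [screenLocus()], [geneBurden()]
#' @export
fitNull <- function(t, r, d, tol = 1e-8, maxit = 500L, screen = TRUE) {
    t <- as.integer(t); r <- as.integer(r); d <- as.integer(d)
    stopifnot(length(t) == length(r), length(t) == length(d),
              all(r <= t), all(r >= 0))
    n <- length(t)
    if (screen &&
        !screenLocus(t[d == 1], r[d == 1], t[d == 0], r[d == 0])) {
        e1 <- groupErrorAtPiZero(t[d == 1], r[d == 1])
        e0 <- groupErrorAtPiZero(t[d == 0], r[d == 0])
        f1 <- is.na(e1); f0 <- is.na(e0)
        if (f1) e1 <- if (f0) EPS_MIN else e0
        if (f0) e0 <- e1
        ll <- .cpp_null_loglik(t, r, d, 0, e1, e0)
        postG <- cbind(rep(1, n), 0, 0)
        return(methods::new("NullFit", pi0 = 0, epsCase = e1, epsCtrl = e0,
            loglik = ll, dosages = rep(0, n), postG = postG,
            converged = TRUE, niter = 0L, boundary = TRUE,
            epsFlags = c(f1, f0)))
    }
    fit <- .cpp_fit_null(t, r, d, tol, as.integer(maxit), EPS_MIN, EPS_MAX)
    if (!fit$converged)
        warning("EM did not converge in ", maxit, " iterations")
    methods::new("NullFit", pi0 = fit$pi0, epsCase = fit$eps1,
        epsCtrl = fit$eps0, loglik = fit$loglik, dosages = fit$dosages,
        postG = fit$postG, converged = fit$converged,
        niter = as.integer(fit$niter), boundary = FALSE,
        epsFlags = c(fit$epsCaseFlag, fit$epsCtrlFlag))
}

# MLE of eps in a single group at pi = 0: every minor read is an error.
# NA when the group has no reads at all.
groupErrorAtPiZero <- function(t, r) {
    st <- sum(t)
    if (st == 0) return(NA_real_)
    min(max(sum(r) / st, EPS_MIN), EPS_MAX)
}

#' Profile log-likelihood of a homogeneous group at a fixed MAF
#'
#' Single-group read likelihood profiled over the error rate:
#' `pl(pi) = max_eps log L(pi, eps)` with `eps` restricted to
#' `[1e-8, 0.5]`. Used mainly as a slow, direct reference for the screening
#' rule; at `pi = 0` the maximizing `eps` is the total minor-read fraction.
#'
#' @param t,r read counts of a single (case-only or control-only) group.
#' @param pi allele frequency at which to profile.
#' @return list with elements `value` (profile log-likelihood) and `eps`
#'   (inner maximizer). With no reads at all, `value` is 0 (constant in
#'   `pi`) and `eps` is `NA`.
#' @export
groupProfileLoglik <- function(t, r, pi) {
    t <- as.integer(t); r <- as.integer(r)
    stopifnot(all(r <= t), pi >= 0, pi <= 1)
    if (sum(t) == 0) return(list(value = 0, eps = NA_real_, flag = TRUE))
    d <- rep(0L, length(t))
    ll <- function(e) .cpp_null_loglik(t, r, d, pi, e, e)
    if (pi == 0) {
        eps <- groupErrorAtPiZero(t, r)
        return(list(value = ll(eps), eps = eps, flag = FALSE))
    }
    opt <- optimize(ll, c(EPS_MIN, EPS_MAX), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    # boundary candidates: optimize() can miss maxima at the interval ends
    cand <- c(opt$maximum, EPS_MIN, EPS_MAX)
    vals <- vapply(cand, ll, 0)
    k <- which.max(vals)
    list(value = vals[k], eps = cand[k], flag = FALSE)
}
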