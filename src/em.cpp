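#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Restricted EM for one locus under the null pi1 = pi0.
// Parameters: pooled MAF pi, group-specific error rates eps1 (cases, d=1)
// and eps0 (controls, d=0).  Likelihood contributions depend on the sample
// only through (d, t, r), so the E/M steps run over aggregated unique
// triples (binomial coefficients cached once); per-sample posteriors are
// expanded from the aggregated weights afterwards.

// log marginal likelihood of one read pair given (pi, eps) with the
// log-binomial-coefficient supplied; fills the genotype posterior in wg.
static inline double logMarginalC(int r, int t, double lch, double pi,
                                  double leps, double l1eps, double *wg) {
    static const double LHALF = -0.6931471805599453;
    double lp[3];
    lp[0] = lch + r * leps + (t - r) * l1eps + 2.0 * std::log1p(-pi);
    lp[1] = (pi > 0.0)
        ? lch + t * LHALF + std::log(2.0 * pi) + std::log1p(-pi)
        : R_NegInf;
    lp[2] = (pi > 0.0)
        ? lch + r * l1eps + (t - r) * leps + 2.0 * std::log(pi)
        : R_NegInf;
    double m = std::max(lp[0], std::max(lp[1], lp[2]));
    double s = 0.0;
    for (int g = 0; g < 3; g++) s += std::exp(lp[g] - m);
    double lm = m + std::log(s);
    if (wg != nullptr)
        for (int g = 0; g < 3; g++) wg[g] = std::exp(lp[g] - lm);
    return lm;
}

// [[Rcpp::export(name = ".cpp_null_loglik")]]
double cpp_null_loglik(IntegerVector t, IntegerVector r, IntegerVector d,
                       double pi, double eps1, double eps0) {
    const int n = t.size();
    double ll = 0.0;
    for (int i = 0; i < n; i++) {
        if (t[i] == 0) continue; // factor 1
        double e = d[i] == 1 ? eps1 : eps0;
        ll += logMarginalC(r[i], t[i], R::lchoose(t[i], r[i]), pi,
                           std::log(e), std::log1p(-e), nullptr);
    }
    return ll;
}

// [[Rcpp::export(name = ".cpp_fit_null")]]
List cpp_fit_null(IntegerVector t, IntegerVector r, IntegerVector d,
                  double tol, int maxit, double epsMin, double epsMax) {
    const int n = t.size();

    // aggregate unique (d, t, r) triples with multiplicities, remembering
    // each sample's triple for the final expansion
    std::map<std::tuple<int, int, int>, int> agg;
    std::vector<int> which(n);
    for (int i = 0; i < n; i++) {
        auto key = std::make_tuple(d[i], t[i], r[i]);
        auto it = agg.find(key);
        if (it == agg.end()) {
            int id = (int)agg.size();
            agg[key] = id;
            which[i] = id;
        } else which[i] = it->second;
    }
    const int K = (int)agg.size();
    std::vector<int> ad(K), at(K), ar(K), am(K, 0);
    for (auto &kv : agg) {
        int id = kv.second;
        ad[id] = std::get<0>(kv.first);
        at[id] = std::get<1>(kv.first);
        ar[id] = std::get<2>(kv.first);
    }
    for (int i = 0; i < n; i++) am[which[i]]++;
    std::vector<double> lch(K);
    for (int k = 0; k < K; k++) lch[k] = R::lchoose(at[k], ar[k]);

    double sr1 = 0, st1 = 0, sr0 = 0, st0 = 0;
    for (int k = 0; k < K; k++) {
        if (ad[k] == 1) { sr1 += (double)am[k] * ar[k]; st1 += (double)am[k] * at[k]; }
        else            { sr0 += (double)am[k] * ar[k]; st0 += (double)am[k] * at[k]; }
    }
    double srt = sr1 + sr0, stt = st1 + st0;
    double rawRate = stt > 0 ? srt / stt : 0.0;

    // initialization: mass on both the allele-frequency and the error
    // explanation of the observed minor reads
    double pi = std::max(rawRate, 1.0 / (4.0 * n));
    if (pi > 1.0) pi = 1.0;
    double eps1 = std::min(st1 > 0 ? sr1 / st1 : rawRate, 0.01);
    double eps0 = std::min(st0 > 0 ? sr0 / st0 : rawRate, 0.01);
    eps1 = std::min(std::max(eps1, epsMin), epsMax);
    eps0 = std::min(std::max(eps0, epsMin), epsMax);

    bool e1Free = st1 > 0, e0Free = st0 > 0;

    std::vector<double> w0(K), w1(K), w2(K);
    std::vector<double> llTrace;
    double ll = R_NegInf;
    bool converged = false;
    int iter = 0;

    for (iter = 1; iter <= maxit; iter++) {
        // E-step + loglik
        double le1 = std::log(eps1), l1e1 = std::log1p(-eps1);
        double le0 = std::log(eps0), l1e0 = std::log1p(-eps0);
        double llNew = 0.0, wg[3];
        for (int k = 0; k < K; k++) {
            double le = ad[k] == 1 ? le1 : le0;
            double l1e = ad[k] == 1 ? l1e1 : l1e0;
            llNew += am[k] * logMarginalC(ar[k], at[k], lch[k], pi,
                                          le, l1e, wg);
            w0[k] = wg[0]; w1[k] = wg[1]; w2[k] = wg[2];
        }
        llTrace.push_back(llNew);

        // M-step
        double num = 0.0;
        double en1 = 0.0, ed1 = 0.0, en0 = 0.0, ed0 = 0.0;
        for (int k = 0; k < K; k++) {
            num += am[k] * (w1[k] + 2.0 * w2[k]);
            double e_n = w0[k] * ar[k] + w2[k] * (at[k] - ar[k]);
            double e_d = (w0[k] + w2[k]) * at[k];
            if (ad[k] == 1) { en1 += am[k] * e_n; ed1 += am[k] * e_d; }
            else            { en0 += am[k] * e_n; ed0 += am[k] * e_d; }
        }
        double piNew = num / (2.0 * n);
        piNew = std::min(std::max(piNew, 0.0), 1.0);
        double e1New = (e1Free && ed1 > 0) ? en1 / ed1 : eps1;
        double e0New = (e0Free && ed0 > 0) ? en0 / ed0 : eps0;
        e1New = std::min(std::max(e1New, epsMin), epsMax);
        e0New = std::min(std::max(e0New, epsMin), epsMax);

        if (iter > 1 && std::fabs(llNew - ll) < tol) {
            ll = llNew;
            converged = true;
            break;
        }
        ll = llNew;
        pi = piNew; eps1 = e1New; eps0 = e0New;
    }

    // a group with zero total depth carries no error information: inherit
    // the other group's estimate
    bool e1Flag = !e1Free, e0Flag = !e0Free;
    if (!e1Free) eps1 = eps0;
    if (!e0Free) eps0 = eps1;

    // final E-step at the returned parameters, once per unique triple
    {
        double le1 = std::log(eps1), l1e1 = std::log1p(-eps1);
        double le0 = std::log(eps0), l1e0 = std::log1p(-eps0);
        double wg[3];
        for (int k = 0; k < K; k++) {
            double le = ad[k] == 1 ? le1 : le0;
            double l1e = ad[k] == 1 ? l1e1 : l1e0;
            logMarginalC(ar[k], at[k], lch[k], pi, le, l1e, wg);
            w0[k] = wg[0]; w1[k] = wg[1]; w2[k] = wg[2];
        }
    }
    NumericMatrix W(n, 3);
    NumericVector dos(n);
    for (int i = 0; i < n; i++) {
        int k = which[i];
        W(i, 0) = w0[k]; W(i, 1) = w1[k]; W(i, 2) = w2[k];
        dos[i] = W(i, 1) + 2.0 * W(i, 2);
    }

    return List::create(
        _["pi0"] = pi, _["eps1"] = eps1, _["eps0"] = eps0,
        _["loglik"] = ll, _["niter"] = iter,
        _["converged"] = converged,
        _["llTrace"] = wrap(llTrace),
        _["postG"] = W, _["dosages"] = dos,
        _["epsCaseFlag"] = e1Flag, _["epsCtrlFlag"] = e0Flag);
}

// Screening derivative of the profile log-likelihood at pi = 0 for one
// homogeneous group: 2 * sum_i [ (0.5/eps)^r (0.5/(1-eps))^(t-r) - 1 ] with
// eps = sum(r)/sum(t) capped into [epsMin, 0.5].
// [[Rcpp::export(name = ".cpp_screen_deriv")]]
NumericVector cpp_screen_deriv(IntegerMatrix t, IntegerMatrix r,
                               double epsMin) {
    const int L = t.nrow(), n = t.ncol();
    NumericVector out(L);
    for (int j = 0; j < L; j++) {
        double st = 0, sr = 0;
        for (int i = 0; i < n; i++) { st += t(j, i); sr += r(j, i); }
        if (st == 0) { out[j] = R_NegInf; continue; }
        double eps = sr / st;
        eps = std::min(std::max(eps, epsMin), 0.5);
        double la = std::log(0.5) - std::log(eps);
        double lb = std::log(0.5) - std::log1p(-eps);
        double s = 0.0;
        for (int i = 0; i < n; i++) {
            if (t(j, i) == 0) continue;
            s += std::exp(r(j, i) * la + (t(j, i) - r(j, i)) * lb) - 1.0;
        }
        out[j] = 2.0 * s;
    }
    return out;
}

// Inject one true variant into a monomorphic row: draw HWE genotypes at
// allele frequency pj (allele-count allocation, exact for a finite sample),
// regenerate the row's reads, and repeat until the row screens in (the
// derivative test passes in cases or controls).  Returns the read row and
// the try count, or ok = false when the cap is hit (caller redraws pj).
// [[Rcpp::export(name = ".cpp_inject_snv")]]
List cpp_inject_snv(IntegerVector tRow, IntegerVector d,
                    double e1, double e0, double pj, int cap,
                    double epsMin) {
    const int n = tRow.size();
    IntegerVector rRow(n);
    std::vector<int> g(n);
    std::vector<char> used(2 * n, 0);
    std::vector<int> touched;
    for (int tries = 1; tries <= cap; tries++) {
        // genotypes: distribute Binomial(2n, pj) minor alleles over the 2n
        // chromosome slots without replacement (rejection on occupancy)
        std::fill(g.begin(), g.end(), 0);
        for (int slot : touched) used[slot] = 0;
        touched.clear();
        int kk = (int)R::rbinom(2.0 * n, pj);
        if (kk > 2 * n) kk = 2 * n;
        for (int a = 0; a < kk; a++) {
            while (true) {
                int slot = (int)(unif_rand() * 2.0 * n);
                if (slot >= 2 * n) slot = 2 * n - 1;
                if (used[slot]) continue;
                used[slot] = 1;
                touched.push_back(slot);
                g[slot / 2]++;
                break;
            }
        }
        // reads and per-group totals
        double st1 = 0, sr1 = 0, st0 = 0, sr0 = 0;
        for (int i = 0; i < n; i++) {
            double e = d[i] == 1 ? e1 : e0;
            double p = g[i] == 0 ? e : (g[i] == 1 ? 0.5 : 1.0 - e);
            rRow[i] = tRow[i] > 0 ? (int)R::rbinom(tRow[i], p) : 0;
            if (d[i] == 1) { st1 += tRow[i]; sr1 += rRow[i]; }
            else           { st0 += tRow[i]; sr0 += rRow[i]; }
        }
        // screening derivative per group
        bool keep = false;
        for (int grp = 0; grp <= 1 && !keep; grp++) {
            double st = grp == 1 ? st1 : st0, sr = grp == 1 ? sr1 : sr0;
            if (st == 0) continue;
            double eps = std::min(std::max(sr / st, epsMin), 0.5);
            double la = std::log(0.5) - std::log(eps);
            double lb = std::log(0.5) - std::log1p(-eps);
            double s = 0.0;
            for (int i = 0; i < n; i++) {
                if (tRow[i] == 0 || d[i] != grp) continue;
                s += std::exp(rRow[i] * la + (tRow[i] - rRow[i]) * lb)
                     - 1.0;
            }
            if (2.0 * s >= 0.0) keep = true;
        }
        if (keep)
            return List::create(_["ok"] = true, _["r"] = rRow,
                                _["tries"] = tries);
    }
    return List::create(_["ok"] = false, _["r"] = rRow, _["tries"] = cap);
}
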