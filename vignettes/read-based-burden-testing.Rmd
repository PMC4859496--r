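---
title: "Read-based rare-variant burden testing: model, screening, and the monomorphic bootstrap"
author: "ReadBurden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-based rare-variant burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control sequencing studies frequently sequence cases and controls at
different depths, on different platforms, or in different batches. The
standard analysis — call genotypes, then run a gene-level burden test on the
calls — is then confounded: genotyping error depends on depth and on the
base-calling error rate, and when those differ systematically between
groups, the burden statistic acquires a nonzero null mean and the test
rejects far too often. ReadBurden implements a likelihood-based burden test
that models the raw read counts directly, never calling genotypes, together
with the machinery needed to make that test valid when the variant
positions themselves must be estimated from the reads.

## Read model and test statistic

At a bi-allelic locus, an individual with genotype $G \in \{0,1,2\}$ (minor
allele count), total mapped reads $T$, and minor-allele reads $R$ is
modelled as

$$R \mid T, G \sim \mathrm{Binomial}(T,\; e_G(\epsilon)), \qquad
  e_G(\epsilon) = \epsilon,\ 0.5,\ 1-\epsilon \text{ for } G = 0, 1, 2,$$

where $\epsilon$ is a locus-specific per-read error rate (base-calling plus
alignment), treated as a free parameter and estimated from the read data.
Genotypes follow Hardy–Weinberg proportions at minor allele frequency
$\pi$. To respect case-control sampling the likelihood is retrospective:
cases and controls carry separate frequencies $(\pi_1, \pi_0)$ and error
rates $(\epsilon_1, \epsilon_0)$, and the null hypothesis is
$\pi_1 = \pi_0$, parameterized as a log-odds shift $\beta = 0$.

Under the null, `fitNull()` maximizes the likelihood over the pooled
frequency $\tilde\pi_0$ and the two error rates by EM (an Rcpp hot loop
aggregated over unique $(D, T, R)$ triples). The per-locus score for
$\beta$ is

$$S = \sum_{i=1}^n \left(D_i - \tfrac{n_1}{n}\right) \tilde G_i,$$

where $\tilde G_i$ is the posterior minor-allele dosage under the null fit
(`posteriorDosage()`); an uncovered sample contributes its prior mean
$2\tilde\pi_0$ and is never dropped. The gene-level statistic is
$W = \sum_j w_j S_j$ over loci with $\tilde\pi_{0j} \le 0.05$, with the
rare-variant weight $w_j = [\tilde\pi_{0j}(1-\tilde\pi_{0j})]^{-1/2}$
(`madsenBrowningWeight()`; the printed weight in our main reference is
ambiguous between this and its square, so both are provided, plus
unweighted). $Z = W/\sqrt{V}$ is asymptotically standard normal when the
variant positions are known.

### The variance $V$

$V$ is the empirical variance of per-individual efficient scores. We use
the analytic form
$U_i = (D_i - n_1/n)\sum_j w_j(\tilde G_{ij} - 2\tilde\pi_{0j})$,
$V = \sum_i U_i^2$: the score for $\beta$ with the frequency nuisance
projected out at its *expected* cross-products. A seemingly natural
alternative — residualizing the realized per-individual $\beta$-score on
the realized nuisance scores by least squares (available as
`variance = "projected"`) — degenerates for rare variants: at a singleton
locus the lone carrier makes the realized $\beta$-score exactly collinear
with the frequency score, the residual vanishes, and $V$ is understated
(we measured null sd(Z) ≈ 1.3 under that choice). The analytic form
calibrates correctly (null sd(Z) within a few percent of 1 at $n = 1000$)
and coincides with the sample-mean-centered fallback
(`variance = "centered"`) at interior EM fits, since the EM score equation
forces $\sum_i (\tilde G_i - 2\tilde\pi_0) = 0$.

## Screening unknown variant positions

Genome-wide, the variant locations are unknown, and testing every base
would be hopeless if each locus required an EM fit. A locus contributes
nothing when its pooled null MAF is zero, so screening asks, per group:
is the single-group profile likelihood $pl(\pi) = \max_\epsilon \log
L(\pi, \epsilon)$ maximized at $\pi = 0$? Because $pl$ is concave, it
suffices to check the sign of its derivative at zero. At $\pi = 0$ every
minor read is an error, the inner maximizer is
$\hat\epsilon = \sum r_i / \sum t_i$, and the envelope theorem gives the
closed form

$$pl'(0^+) = 2\sum_i\left[\left(\tfrac{0.5}{\hat\epsilon}\right)^{r_i}
  \left(\tfrac{0.5}{1-\hat\epsilon}\right)^{t_i - r_i} - 1\right],$$

evaluated in `profileDerivativeAtZero()` with $\hat\epsilon$ capped into
$[10^{-8}, 0.5]$. A locus is kept iff the derivative is non-negative in
cases *or* controls (`screenLocus()`); a derivative of exactly zero — a
measure-zero tie, e.g. a single sample whose reads are all minor so that
$\hat\epsilon$ caps at 0.5 — screens *in*, deliberately conservative: the
EM decides downstream, and no true variant is lost to a tie rule.
Screening is $O(n)$ per locus with no iteration. The thresholded variant
of the test (`applyMafThreshold()`, mode `"STB"`) additionally removes
loci with $\tilde\pi_0 < (2n)^{-1}$, the frequency of a singleton; the
comparison is strict, so an exact singleton estimate survives.

## Why screening breaks the asymptotic test, and the bootstrap that fixes it

A truly monomorphic locus occasionally screens in on error reads alone.
When controls are sequenced at lower depth, such loci screen in more often
on the control side, each contributing a score with negative mean; summed
over a gene this biases $W$ below zero even with identical allele
frequencies in both groups. The asymptotic reference is then wrong, and
`bootstrapPvalue()` replaces it:

1. **Monomorphic twin.** Holding the observed depth matrix $T$ fixed,
   redraw every $R$ as pure error reads (`simulateMonomorphic()`). Screen
   it: $M_m$ loci with their MAF estimates approximate the artifact
   component of the $M_s$ observed screened-in loci.
2. **Deconvolution.** The observed screened-in MAF distribution is the
   mixture $F_s = \phi F_m + (1-\phi) F_p$; with $\hat\phi = M_m/M_s$,
   `estimateFp()` recovers the true-variant CDF
   $(1-\hat\phi)^{-1}(\hat F_s - \hat\phi \hat F_m)$ at the pooled
   support, made monotone by weighted PAVA (`pava()`), clipped to
   $[0,1]$, and set to 1 beyond the largest MAF. The estimated variant
   count is $\hat M_p = \max(M_s - M_m, 0)$.
3. **Replicates.** Each replicate is a fresh monomorphic twin with
   $\hat M_p$ loci (uniformly chosen) turned into variants: a MAF drawn
   from $\hat F_p$ by inverse CDF, genotypes drawn from HWE *identically
   in cases and controls*, reads regenerated. Genotypes are redrawn until
   the locus screens in (cap 1000 tries per MAF draw, then the MAF is
   redrawn); retaining each injected variant at a concrete locus keeps
   its real depth pattern, which is the point of conditioning on $T$.
4. **Sequential stopping.** Replicates are screened and tested exactly
   like the observed gene; exceedance is two-sided,
   $|Z^*| \ge |Z|$. Sampling stops at $L_{\min} = 5$ exceedances
   (p-value $L_{\min}/K_{obs}$) or at $K_{\max}$ replicates (p-value
   $(L_{obs}+1)/(K_{\max}+1)$). For a null gene the replicate count at
   termination has the analytic marginal $P(K \le k) = (k-4)/(k+1)$, so
   its median is 9–10: null genes are abandoned almost immediately.

The deconvolution is estimated once per gene before the replicate loop
(the design our flowchart reading implies, and far cheaper); re-estimating
it inside every replicate is available via `refitFp = TRUE`. Whether
exceedance should be one- or two-sided is not dictated by the method;
two-sided is the default because burden effects may be protective, with a
`twoSided = FALSE` switch.

## Error rates for the bootstrap: adjusted empirical Bayes

Bootstrap validity hinges on generating error reads from the right
error-rate *distribution*. Per-locus MLEs are over-dispersed at realistic
error rates (at a mean of 0.02% most loci see zero error reads, so MLEs
pile up at zero); plain empirical-Bayes posterior means are over-shrunk.
`geneErrorRates()` therefore fits, separately for cases and controls, a
$\mathrm{Beta}(a, b)$ prior to all $M$ per-locus estimates in the gene by
method of moments (screened-in loci contribute their EM estimate;
screened-out loci the error-only fraction $\sum r/\sum t$, since under
$\pi = 0$ all minor reads are errors; zero-exposure loci are excluded),
with the binomial counting noise $\overline{m(1-m)/t_j}$ subtracted from
the raw variance — at a 0.02% mean the counting noise exceeds the true
between-locus variance, and without the correction the fitted prior is
badly over-dispersed, which (screen-in probability being concave in
$\epsilon$) makes the monomorphic twin under-produce artifact loci and
biases $\hat M_p$ upward — computes beta-binomial EB posterior
means $(a + e_j)/(a + b + t_j)$ from the EM's homozygote-weighted expected
error counts, and then — the adjustment — replaces the *ordered* EB values
by the prior quantiles at plotting positions $(k - 0.5)/M$
(`adjustedEB()`). Ranks are preserved exactly; the marginal distribution
becomes the fitted prior, which with $M$ in the hundreds is estimated
accurately. The exact moment formulas of the original supplementary
derivation are not reproducible from the main text, so plain method of
moments is used and the binding contract is distributional recovery: in
tests, the adjusted estimates are closer (Kolmogorov–Smirnov) to the true
error-rate sample than the MLEs are. A zero-variance estimate vector
yields a degenerate-prior flag and the MLEs pass through unchanged.

## Read-based QC

Some read data fit no genotype (mosaicism, contamination, CNVs,
artifacts). For each covered sample at each screened-in locus,
`qStatistic()` compares the saturated binomial likelihood at rate $r/t$
against the best genotype rate:

$$Q = 2\log\frac{(r/t)^r (1-r/t)^{t-r}}
  {\max_g e_g(\epsilon)^r (1-e_g(\epsilon))^{t-r}}, \qquad 0^0 := 1.$$

$\epsilon$ here is the group's adjusted-EB estimate at the locus (QC runs
after fitting; the statistic treats $\epsilon$ as known). `applyQc()`
masks entries with $Q > 10$ by zeroing both counts and drops loci where
more than 5 samples were masked; both boundaries are strict. QC applies
to the observed data only — bootstrap reads are generated from the
binomial model, so re-running QC inside replicates would only add noise.
`flagSamples()` reports samples with excessive exceedance counts; no
principled universal cutoff exists, so the threshold is configurable with
a 99.9th-percentile default.

## The simulator

`simulateCaseControlStudy()` generates the study design used throughout
validation, replacing an external coalescent simulator with an internal
spectrum sampler — the downstream claims (type-I error control, inflation
of the comparators, recovery of $\hat M_p$) depend on the rare-variant
frequency spectrum and the depth/error laws, not on coalescent fine
structure:

* **Base population** (`generateBasePopulation()`): a gene of 2,730
  exonic loci in 3 exons (introns 3 times the exon length separate them)
  carrying 44 variants by default, with MAFs drawn from the density
  $\propto 1/x$ on $[1/10^5, 0.05]$ — the neutral-like shape under which
  singletons dominate — realized over $10^5$ haplotypes with independent
  alleles across variants (rare variants carry essentially no LD).
* **Individuals** (`sampleIndividuals()`): two gametes per individual;
  haplotype indices switch at intron boundaries with probability 0.5
  (configurable), never inside an exon.
* **Disease** (`assignPhenotype()`):
  $\mathrm{logit}\, P(D=1) = \alpha + \sum_j G_j \log(1 + AR/2\pi_j)$
  with $\alpha = -3$ (≈5% disease rate) and equal attributable risk per
  variant, so rarer variants act more strongly; sampling continues until
  the case and control quotas (500 + 500) are filled. $AR = 0$ is the
  null.
* **Depths** (`sampleDepths()`): per-locus mean depths are beta draws
  rescaled to the target mean — $\mathrm{Beta}(2.1, 4.1)$ for high-depth
  (≥20×, exome-like capture variability) and $\mathrm{Beta}(4.6, 4.8)$
  for low-depth (genome-like) profiles, resolved from the target depth so
  that equal average depths imply identical locus-depth laws — then
  per-sample depths are negative binomial with dispersion size 5
  (variance $c + c^2/5$). The dispersion and the error-beta shape
  ($a = 2$, second shape solved from the mean) are documented defaults:
  the exact values behind the original simulations are not recoverable,
  and the artifact screen-in rate per gene — hence the magnitude (not the
  sign) of the post-screening bias — is sensitive to them.
* **Errors and reads** (`sampleErrors()`, `generateReads()`): per-locus
  error rates from the beta law; reads binomial given $(T, G, \epsilon)$.
  Depths and errors are drawn independently for cases and controls at
  each locus (two pipelines) unless `sharedPipeline = TRUE`.

What the simulator deliberately does not emulate: linkage disequilibrium
among rare variants, error correlation across neighboring loci, phred- or
alignment-score structure, indels, and multi-allelic sites. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to those real-data features.

## Comparators

`cgBurdenTest()` is the genotype-calling baseline: posterior-mode hard
calls under the fitted null model (ties to the smaller genotype; no
coverage calls 0 for a rare allele), treated as known genotypes in the
classical weighted burden score test with the binomial HWE variance at
the called allele frequency. `doseBurdenTest()` keeps the posterior-dosage
score but uses a group-stratified robust variance
$(n_0/n)^2 \mathrm{SS}_\text{case} + (n_1/n)^2 \mathrm{SS}_\text{ctrl}$
of the weighted dosage sums (the robust-variance construction of the
dosage-test literature; the exact original scaling is not printed, so the
binding contract is asymptotic equivalence with the read-based test under
known positions — their Z statistics correlate above 0.99 in tests).
Both control type I error with known variant positions at equal
sequencing quality, and both fail — mildly (calling) or catastrophically
(screened dosage with asymptotic inference) — under differential depth,
which is the negative control motivating the bootstrap.
`trueGenotypeBurden()` on the simulated truth is the gold standard.

## Numerical choices and degenerate inputs

* $\epsilon$ is capped into $[10^{-8}, 0.5]$ wherever estimated: the read
  model is symmetric about 0.5, and $\epsilon = 0$ creates zero-likelihood
  singularities at any $r > 0$.
* EM: initialization $\pi^{(0)} = \max(\sum r/\sum t,\ 1/(4n))$,
  $\epsilon^{(0)}_d = \min(\sum r/\sum t\ \text{in group } d,\ 0.01)$ —
  mass on both the frequency and the error explanation; convergence on
  absolute log-likelihood change $< 10^{-8}$, at most 500 iterations
  (the best iterate is returned with a flag otherwise). All likelihood
  work is in log space; depths in the hundreds are routine.
* A group with zero total depth inherits the other group's error
  estimate, flagged; a gene with no screened-in loci gets p-value 1 by
  convention; zero burden variance is flagged degenerate rather than
  producing an infinite Z.
* Ties in the EB values are broken by stable input order before quantile
  matching; deconvolution CDF values are clipped to $[0,1]$ after PAVA.
* Inverse-CDF draws beyond the largest support point (where the CDF is
  forced to 1) return the largest observed MAF, keeping injected
  frequencies inside the observed range.
* The screened-in MAF fed to the deconvolution is the pooled-sample null
  MLE $\tilde\pi_0$ — the only MAF the method computes under the null and
  the quantity the bootstrap must reproduce; group-specific frequencies
  are never estimated.

## Problem sizes used in the shipped checks

The package's statistical acceptance tests run, per check: 2,000
known-position null replicates at 6×/6× (nominal level 1%); 110 full
screening-plus-bootstrap studies on a 500-locus gene at 30×/6× with
$K_{\max} = 300$ (nominal 5%, binomial envelope at $n = 110$); 800
genotype-calling replicates at 30×/6×; 150 screened dosage replicates at
30×/10× with 1% errors; 200 screened and 400 known-position replicates
for the bias contrast; 100 replicates for variant-count recovery; and
2,000 surrogate streams for the stopping rule. The acceptance script
(`scripts/acceptance.R`) re-runs the corresponding quantities at 2,000 /
1,000 / 250 / 250 / 2,000 replicates on the full 2,730-locus gene. These
sizes were chosen so each Monte Carlo envelope is decisive for the claim
it checks while the whole suite remains a routine desk run.

## Known limitations

Single-source cases and controls (one error-rate law per group); no
covariates or population-structure adjustment; no LD-aware bootstrap; no
phred-informed error model; burden statistics only (a variance-component
statistic would need a properly centered score after screening, which the
bootstrap here does not provide). These mirror the method's stated scope;
the package surfaces are designed so the extensions would slot into
`geneErrorRates()` (per-source rates) and `makeBootstrapReplicate()`
(haplotype-preserving injection) without touching the test statistic.
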