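---
title: "Combining dependent p-values with generalized mean p-values"
author: "gmpcomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining dependent p-values with generalized mean p-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmpcomb)
```

## The statistic

Given $K$ p-values $p_1,\dots,p_K$ testing related hypotheses, the
generalized mean p-value (GMP) with exponent $r$ is

$$M_{r,K}(p_1,\dots,p_K) = \left(\frac{p_1^r + \dots + p_K^r}{K}\right)^{1/r}.$$

The family contains the working statistics of several classical combined
tests: the minimum ($r \to -\infty$, Bonferroni/Šidák), the harmonic mean
p-value (HMP, $r = -1$), the geometric mean ($r \to 0$, equivalent to
Fisher's method), the arithmetic mean ($r = 1$) and the maximum
($r \to \infty$).  As $r$ decreases the statistic is increasingly driven by
the smallest p-values.  `compute_gmp()` evaluates the mean through a
log-sum-exp, so exponents like $r = -10$ applied to p-values near
$10^{-300}$ neither overflow nor underflow; exponents within $10^{-8}$ of
zero are routed to the geometric mean, because dividing by $r$ amplifies
rounding noise faster than the power mean changes.

A GMP is **not** itself uniform under the grand null hypothesis (that all
$K$ constituent nulls hold), so it must be compared against a significance
threshold $\Psi_{r,K}(\epsilon)$ chosen so that
$\Pr(M_{r,K} \le \Psi_{r,K}(\epsilon)) \le \epsilon$.  The package
implements two threshold families resting on opposite dependence
assumptions, and the maps between them.

## GCLT thresholds (independence, with heavy-tail robustness)

Under the null, $X_i = p_i^r$ is Beta$(1/r, 1)$ for $r > 0$ and
Pareto$(1, -1/r)$ for $r < 0$; in the latter case the tail index is
$\lambda = -1/r$.  By the generalized central limit theorem the
standardized sum $(\sum_i X_i - a_{r,K})/b_{r,K}$ converges to the
extremal stable law $S_{\lambda,1}$ (maximal skew $\beta = 1$), which for
$\lambda \ge 2$ is simply Normal$(0, 2)$.  Inverting that limit yields

$$\Psi_{GCLT,r,K}(\epsilon) =
  \left[\frac{a_{r,K} + b_{r,K}\, F^{-1}_{\lambda,1}(1-\epsilon)}{K}\right]^{1/r}
  \quad (r < 0),$$

with the lower Normal$(0,2)$ quantile replacing the upper stable quantile
when $r > 0$.  `gclt_coefficients()` returns the centering and scaling by
regime: $a = 0$ for $r < -1$; $a = K\log K$, $b = (\pi/2)K$ at the
harmonic point $r = -1$; $a = K/(1+r)$ with a stable or Normal scaling
above that.  The derivation assumes independence, but for $r \le -1$ the
heavy tails confer robustness to realistic dependence (the
Davis–Resnick tail-independence condition), which is the central
power-robustness trade-off the package is built to explore.

Two caveats are built into the interface.  First, `gclt_threshold()`
warns when $\epsilon > 0.2$: the stable approximation is a tail
approximation and degrades toward the centre of the distribution.
Second, at moderate $K$ the $r = -1$ threshold is known to be slightly
anticonservative at $\epsilon = 0.05$ (empirically a false positive rate
of about 0.052 at $K = 1000$ under independence); this is a property of
the limit construction itself, shared by all implementations of it, and
it shrinks as $\epsilon \to 0$.

### Numerics of the extremal stable law

No closed form exists for $F_{\lambda,1}$ except at $\lambda = 2$
(Normal) and $\lambda = 1/2$ (Lévy), and no stable-distribution package
ships with the environments this package targets, so the law is computed
from first principles in `pexstable()` / `qexstable()`:

* **Parameterization.** Nolan's S1 with $\alpha = \lambda$, $\beta = 1$,
  $\sigma = 1$, $\mu = 0$.  Internally the CDF integral uses the S0 form;
  the S1→S0 location shift $\beta\tan(\pi\alpha/2)$ is applied
  explicitly, and the test suite pins the convention by checking the
  Lévy closed form, the Normal case, and quantiles of samples from the
  Chambers–Mallows–Stuck construction, which shares no code with the
  CDF path.
* **Integration.** Nolan's (1997) integral representation, with the
  survival function computed through `expm1` so the deep upper tail
  retains relative accuracy.  The integrand can sweep hundreds of orders
  of magnitude across $(-\theta_0, \pi/2)$, so the interval is split
  where $cV(\theta)$ crosses $e^{-30}$, $1$ and $e^{30}$; saturated or
  negligible pieces are evaluated by a trapezoid (exact there to
  $\sim 10^{-13}$), the transition piece by adaptive quadrature at
  relative tolerance $10^{-11}$, with a fixed 2000-point Simpson rule as
  a fallback where the adaptive rule reports failure.
* **Small tail indices.** For $\lambda < 0.1$ — exponents below about
  $r = -10$ — the quantiles exceed double-precision range, so the
  convergent tail series of the positive stable law is used on the log
  scale, and `gclt_threshold()` assembles $\log\Psi$ without ever
  forming the quantile itself.  This is what lets the thresholds at,
  say, $r = -10^6$ reproduce the Šidák limit to a relative $10^{-3}$.
* **Quantiles** are obtained by monotone root-finding bracketed around
  the first-order Pareto tail approximation, to a tolerance of about
  $10^{-13}$ relative; results are memoized, since sweeps and closed
  testing traversals re-request the same $(\lambda, \epsilon)$ values
  thousands of times.

## RRA thresholds (worst-case dependence)

Robust risk analysis (Vovk–Wang) gives thresholds valid under *arbitrary*
dependence: $\Psi = \frac{r+1}{r}\epsilon K^{-(1+1/r)}$ for $r < -1$,
$\epsilon/\log K$ at $r = -1$, and $\epsilon\,(r+1)^{-1/r}$ for $r > -1$
(multiplier $e$ at the geometric mean, $2$ at the arithmetic mean).  The
printed source for the $-1 < r < -1/2$ row is typographically ambiguous;
the package adopts $\epsilon\,(r+1)^{-1/r}$, the only reading consistent
with both the arithmetic-mean worst case (a doubling, hence the 0.96
figure below) and the $r \to 0$ limit.  These bounds are *precise*: some
dependence structure attains them, which justifies reading their inverse
as a worst case.

Because the RRA map is linear in $\epsilon$, two diagnostics come cheaply:

```{r}
psi_amp <- gclt_threshold(1, 1000, 0.01)$psi
fpr_worst_case(psi_amp, 1, 1000)        # AMP threshold under worst case
psi_hmp <- gclt_threshold(-1, 1000, 0.01)$psi
fpr_worst_case(psi_hmp, -1, 1000) / 0.01  # HMP: fold-inflation
fpr_under_independence(rra_threshold(-1, 1000, 0.01)$psi, -1, 1000)
```

The first shows why the arithmetic mean GMP with a calibrated
(independence) threshold is fragile — its worst-case false positive rate
at a nominal 1% is 0.96 — while the harmonic mean's inflation is bounded
at 6.2-fold; the third shows the price of the worst-case guarantee under
independence.  `small_eps_threshold()` provides the
$\epsilon \to 0$ closed form $\epsilon K^{-(1+1/r)}$ for $r < -1/2$ (it
refuses $r \ge -1/2$, where the heavy-tail characterization that
justifies it no longer holds); at $r = -2$ it exceeds the RRA threshold
exactly two-fold, independent of $K$ and $\epsilon$.

## The dependence simulator

Dependent p-values are generated as likelihood-ratio-test tail
probabilities.  Each test $i$ has $v$ standardized score components; its
deviance $2\log R_i$ is their squared norm, marginally chi-squared($v$),
and the p-value is the chi-squared upper tail (with $v = 2$, exactly
$1/R_i$).  "Analogous" components are equicorrelated across tests with a
single coefficient $\rho \in [0,1]$, so the joint deviances are the
diagonal of a Wishart matrix with an equicorrelation scale matrix — a
Wishart-Multivariate-Gamma law.  Sampling uses the one-factor
representation $s = \sqrt{\rho}\,z_0 + \sqrt{1-\rho}\,e$ per component:
exact for equicorrelation, $O(vK)$ per replicate rather than the
$O((vK)^2)$ of a Cholesky route, and non-degenerate at $\rho = 1$ (where
all deviances coincide, as they must).  Alternatives add a mean shift
$Z$ to **every** score component of an affected test (noncentrality
$vZ^2$); the shift is added after the null draws so that a zero shift
reproduces the null random stream bit for bit.

The four study scenarios fix $K = 1000$, $v = 2$, $\epsilon = 5\%$ and
differ in how many tests carry signal and how strong it is: none
(*null*), one test at $Z = 3.0$ (*needle*), 100 at $Z = 1.25$
(*mixture*), all 1000 at $Z = 0.7$ (*pervasive*).  The shifts are
calibrated so each alternative gives roughly 50% power under
independence; with the all-components convention the needle/Bonferroni
power is analytically 0.490, which is how that convention was fixed (a
single-component shift gives 0.139 and is not compatible with the 50%
calibration).

What the simulator does *not* emulate: heterogeneous degrees of freedom
across tests, correlations between non-analogous parameter estimates,
sparse or clustered (rather than globally dense) dependence, and
conservative or discrete null p-values.  Passing tests therefore
demonstrate calibration and power under dense equicorrelated
likelihood-ratio dependence with uniform nulls, not under arbitrary real
data; the worst-case RRA bounds are the instrument for the latter.

## Multilevel (closed testing) procedures

To reject subsets $\mathcal{R}$ of the $K$ hypotheses while controlling
the strong-sense family-wise error rate, the subset GMP
$\bar p_{r,\mathcal{R}}$ is compared with a deflated threshold
$f_{|\mathcal{R}|}\Psi_{r,|\mathcal{R}|}(\epsilon)$, with
$f_{|\mathcal{R}|}$ the largest factor for which rejecting the subset
forces rejection of the full set even if every complement p-value
equals 1 (consonance).  The exact partition identity
$K\bar p_r^r = |\mathcal{R}|\bar p_{r,\mathcal{R}}^r +
|\mathcal{R}'|\bar p_{r,\mathcal{R}'}^r$ drives the derivation.  For
$r < 0$ the package uses the slightly more stringent factor
$f = \min\{1, [\Psi_{r,K}^r / ((|\mathcal{R}|/K)
\Psi_{r,|\mathcal{R}|}^r)]^{1/r}\}$, which keeps consonance a fortiori
and collapses *exactly* to $|\mathcal{R}|/K$ for $r < -1$, where both
threshold families satisfy
$\Psi_{r,K}/\Psi_{r,|\mathcal{R}|} = (|\mathcal{R}|/K)^{1+1/r}$.  For
$r > 0$ the general factor applies and subsets smaller than
$K(1 - \Psi_{r,K}(\epsilon)^r)$ are flagged `NA` (not rejectable): no
subset evidence can offset complement p-values of 1, a structural limit
of this single-subset shortcut rather than of closed testing as such.
For $-1 < r < 0$ the construction is offered but inherits the inflated
false positive rates of the GCLT thresholds in that range.  Singleton
subsets under RRA with $r < -1$ are more stringent than the Bonferroni
per-test threshold by exactly $(r+1)/r$ — the price of group-level
claims.  The full $2^K$ closed-testing enumeration is out of scope; the
shortcut factors make the procedure $O(1)$ per subset.

## The simulation harness

`estimate_rejection_rate()`, `gmp_sweep()`, `roc_curve()` and
`inherent_power()` reduce every procedure to a statistic on a common
"smaller is more significant" scale (the GMP value; the minimum p-value
for Bonferroni/Šidák; the Simes statistic $\min_i K p_{(i)}/i$; the
chi-squared combined p-value for Fisher) with an analytic threshold per
nominal level.  Design choices:

* Within a sweep cell (scenario × $\rho$), one set of replicates is
  shared by all methods and exponents, removing between-method Monte
  Carlo noise from comparisons; given a seed, output is byte-identical
  across runs.
* ROC curves share one pair of null/alternative replicate sets across
  the whole level grid, so the curves are monotone by construction.
* *Inherent power* — the power a test would have if its threshold hit
  the target false positive rate exactly under the operative dependence
  — has no analytic form under this dependence model, so it is
  estimated by Monte-Carlo calibration: the threshold is the empirical
  $\epsilon$-quantile (order statistic, rounded down) of the statistic
  under the matched null scenario at the same $\rho$ and the same
  number of replicates.  Actual power above inherent power diagnoses an
  inflated false positive rate; below, conservatism.
* The reference design is 10,000 replicates of $K = 1000$ over
  $r \in \{-10, -5, -2, -1.25, -1, -0.75, -0.25, 10^{-6}, 1, 2\}$ and
  $\rho \in \{0, 0.2, 0.4, 0.6, 0.8, 1\}$.  The test suite exercises the
  same machinery at reduced sizes (2,000–10,000 replicates; $K$ of
  200–1000 for property checks, the full $K = 1000$ for the headline
  calibration and power checks, and $10^5$ independent-uniform
  replicates for the threshold/Monte-Carlo oracle comparison), with
  tolerances of 3–4 binomial Monte-Carlo standard errors chosen to
  match those sizes.

## Degenerate inputs and edge cases

A p-value of exactly 0 makes the GMP undefined for $r < 0$ and is
rejected at validation; an explicit `floor` argument (exposed as
`--floor` in the CLI) clips instead, so silent truncation is always
opt-in.  $\rho = 1$ is handled exactly by the factor construction.
Subset sizes of 1 are permitted in the multilevel functions even though
the size-$m$ threshold formulas are asymptotic in $m$; this mirrors the
closed forms, whose singleton limits (Bonferroni-like thresholds) are
the intended behaviour.  `eps` above 0.2 triggers a warning rather than
an error, since the RRA bounds remain exact there even though the GCLT
approximation degrades.

## Known limitations

Equal weights throughout (weighted GMPs are not implemented); uniform
null p-values are assumed (conservative or discrete nulls would erode
power in ways not modelled here); no dependence-adjusted CLT for
$r > -1/2$ (which would need the covariances of $p_i^r$); Brown's
method and full closed-testing enumeration are out of scope.  The GCLT
thresholds should not be trusted for $r > -1$ outside verified
independence — the package's own sweep reproduces their pronounced
false positive inflation under even mild equicorrelation — and the RRA
thresholds, while always valid, are typically less powerful than
Bonferroni; the harmonic-mean region $r \in [-2, -1]$ with GCLT
thresholds is where the power-robustness trade-off is favourable.
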