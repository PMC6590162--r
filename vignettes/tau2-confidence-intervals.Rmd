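---
title: "Confidence intervals for the between-study variance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence intervals for the between-study variance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A random-effects meta-analysis observes $k$ independent effect estimates
$Y_i = \mu + u_i + \varepsilon_i$, with random effects
$u_i \sim N(0, \tau^2)$ and sampling errors
$\varepsilon_i \sim N(0, \sigma_i^2)$, all independent. The between-study
variance $\tau^2$ measures how much the true effects differ across
studies; because its point estimates are imprecise at realistic $k$, an
interval estimate is what should be reported. This package implements the
two interval methods built on the Q-statistic, and a simulation apparatus
for studying how they behave when the model's assumptions — normal
sampling distributions and *known* sampling variances — fail, as they do
for the log odds ratio with small studies and rare events.

Both methods start from the generalized Q-statistic
$$Q(\tau^2) = \sum_{i=1}^k \frac{(Y_i - \hat\mu)^2}{\tau^2 + \hat\sigma_i^2},
\qquad \hat\mu = \frac{\sum w_i Y_i}{\sum w_i},\quad w_i = \frac{1}{\tau^2 + \hat\sigma_i^2},$$
which at the true $\tau^2$ is a $\chi^2_{k-1}$ pivot under the model
assumptions. Note that $\hat\mu$ is recomputed at every candidate
$\tau^2$ — the pivot is defined with matching weights, not with weights
frozen at some estimate.

**Q-profile** (`q_profile_ci`) inverts the pivot directly: the bounds
solve $Q(\hat\tau^2_{LB}) = \chi^2_{k-1;(1+level)/2}$ and
$Q(\hat\tau^2_{UB}) = \chi^2_{k-1;(1-level)/2}$. $Q(\tau^2)$ is strictly
decreasing, so each equation has at most one root. When $Q(0)$ falls
below the upper quantile the lower bound is negative in principle and is
truncated to zero; when $Q(0)$ falls below the *lower* quantile even
$\tau^2=0$ lies above the interval and the result is the null (empty)
set. The Paule–Mandel point estimate — the root of $Q(\tau^2)=k-1$, zero
when $Q(0)\le k-1$ — always lies inside this interval, since $k-1$ sits
between the two $\chi^2_{k-1}$ quantiles at any conventional level.

**GENQ** (`genq_ci`) fixes positive weights $a_i$ that do not depend on
$\tau^2$ — here $a_i = 1/\hat\sigma_i^2$ ("variance") or
$a_i = 1/\hat\sigma_i$ ("se") — and uses the *exact* distribution of
$q_a = \sum a_i (Y_i - \hat\mu_a)^2$: a weighted sum
$\sum_i \lambda_i \chi^2_i(1)$ whose weights are the eigenvalues of
$S^{1/2} B S^{1/2}$, $S = \operatorname{diag}(\tau^2+\hat\sigma_i^2)$,
$B = \operatorname{diag}(a) - aa^\top/\sum a_i$. The tail probability
$P(Q_a \ge q_a \mid \tau^2)$ is continuous and increasing in $\tau^2$, so
test inversion again reduces to two monotone root-finding problems, with
the same truncation and null-set conventions. Weight schemes that depend
on an estimated $\tau^2$ are deliberately out of scope: they break
exactness even under the model.

## Numerical choices

*Root finding.* All inversions use plain bisection on $\tau^2$ with an
absolute tolerance of $10^{-9}$, bracketing the root by doubling from 1
up to a hard cap of $10^7$ (an error beyond, signalling a pathological
sample). Both target functions are monotone, so bisection cannot fail
inside the bracket; this is slower than derivative-based schemes but
immune to the flat-tail behaviour of $Q(\tau^2)$ at large $\tau^2$.

*Weighted chi-square tail.* `weighted_chisq_sf` first tries the
Farebrother/Ruben expansion of the quadratic-form distribution as an
infinite mixture of central chi-squares with scale $\beta=\min_i\lambda_i$;
the mixture coefficients are positive and sum to one, so the series is cut
when the missing mass drops below $10^{-10}$ — a rigorous error bound. For
spectra too disparate for 5000 terms (or whose leading coefficient
underflows) it falls back to Imhof's oscillatory integral evaluated by
adaptive quadrature. The implementation was validated against the exact
chi-square special cases ($\lambda \equiv c$), against an independent
Imhof implementation, and against $10^6$-draw Monte-Carlo tails (see the
test suite); accuracy is far inside the $10^{-6}$ absolute contract.
Eigenvalues are computed on the symmetric form; values in
$(-10^{-10}, 0)$ are clipped to zero, anything more negative is an error,
and relative noise below $10^{-12}$ of the largest eigenvalue is dropped
before quadrature.

*Degenerate input.* If all $y_i$ coincide, $Q(0)=0$ and $q_a=0$: every
$\tau^2$ is rejected from above and both methods correctly return the
null set — this is a statement about the data, not an error. Null-set
intervals carry an explicit `status` instead of sentinel numbers because
coverage accounting must score them as non-covering and exclude them
from width averages.

## The synthetic-data generator

`simulate_meta` reproduces a binomial two-arm world: true log odds
ratios $\theta_i \sim N(\mu, \tau^2)$; control-arm events
$x^C \sim \mathrm{Bin}(n, \pi^C)$; experimental-arm probability
$\pi^E = \pi^C e^{\theta_i}/(1-\pi^C+\pi^C e^{\theta_i})$ so the
log odds difference is exactly $\theta_i$; $x^E \sim \mathrm{Bin}(n, \pi^E)$.
Every cell of every table gets $+0.5$ before the log odds ratio and its
variance are computed — the correction is unconditional, not restricted
to zero-cell tables. Per-group sizes follow the fixed pattern
(30, 50, 100, 150, 300) replicated $k/5$ times, keeping the average study
size constant in $k$; constant-size designs (heat-map grids) pass an
explicit size instead. Arms are equal-sized within a study by design.

Two switches matter for the assumption-violation experiments:

- `variance_mode = "exact"` keeps each observed $y_i$ but replaces
  $\hat\sigma_i^2$ with the *true* sampling variance of the corrected log
  odds ratio, obtained by enumerating all $(n^E+1)(n^C+1)$ tables at study
  $i$'s own $(\pi^E(\theta_i), \pi^C)$ (`exact_log_or_moments`). This
  isolates the known-variance assumption from the normality assumption.
  The true variance is the central second moment $E[Y^2]-(E[Y])^2$;
  enumeration uses log-space binomial masses and is memoized on
  $(n^E, n^C, \pi^E, \pi^C)$ at full float precision.
- `generator_mode = "ideal_normal"` draws
  $y_i \sim N(\mu, \tau^2+\sigma_i^2)$ directly with known fixed
  $\sigma_i^2 = 8/n_i$ — the large-sample variance of a log odds ratio
  from a balanced table at event probability one half — satisfying every
  model assumption. In this mode both methods are exact, which the test
  suite verifies empirically; it is the calibration control, not a model
  of real data.

What a green coverage test on this generator does *not* establish:
behaviour under unequal arm sizes, under effect measures other than the
log odds ratio, under correlated sampling errors, or on real data whose
heterogeneity is not normal. The generator draws fresh $\theta_i$ every
repetition, so coverage averages over both the random-effects and the
sampling layer.

*Reproducibility.* Each condition owns a seed; repetitions run on
L'Ecuyer-CMRG substreams spawned per repetition, so results are invariant
to the worker count and bit-identical across runs.

## Experiment conventions

- Coverage is scored on the $\tau^2$ scale: covered iff the interval is
  not the null set and $lb \le \tau^2 \le ub$. Null sets count as
  non-covering.
- The width of a null set is undefined; such repetitions are excluded
  from width means/SDs and tracked through the null-set proportion. (The
  original reports do not state their convention; this one is ours and
  is visible in the output columns.)
- Width comparisons between methods count strict wins; repetitions where
  either width is undefined fall into the tie bucket so wins + losses +
  ties always equals the repetition count.
- The distribution study (`qstat_distribution`) evaluates the pivot at
  the condition's true $\tau^2$ with matching weights
  $1/(\tau^2+\hat\sigma_i^2)$. The source material does not pin down this
  choice explicitly; evaluating the pivot exactly as the Q-profile method
  defines it is the only internally consistent reading. Likewise, in
  exact-variance mode the GENQ weights are built from the substituted
  true variances (consistent substitution).
- The pooled-mean estimate recorded per repetition uses weights
  $1/(\hat\tau^2_{PM} + \hat\sigma_i^2)$ at the Paule–Mandel estimate,
  feeding the bias-versus-coverage correlation across conditions.

## Scale choices in the shipped checks

The original coverage designs use 10,000 (study 1) and 3,000 (study 2)
repetitions per condition and a 5,000-replicate distribution study. The
distribution-study checks run at the full 5,000; coverage checks are
scaled to 1,000 repetitions (widths to 2,000) to fit a single-CPU test
budget, with tolerances widened to the corresponding Monte-Carlo error.
The ideal-normal exactness check runs at 2,500 repetitions against a
3.5-standard-error band. Headline full-grid quantities that need the
entire 450-condition design (bias-coverage correlations near
−0.18/−0.23/−0.26, complete heat maps) are not reproduced at desk scale;
the machinery for them (`coverage_grid`, `bias_coverage_correlation`,
the shipped grid presets) is exercised on small grids instead.

## Known limitations

- GENQ inversion at $k=160$ costs ~0.1 s per interval (one $k\times k$
  eigendecomposition per bisection step); large coverage grids need
  either patience or `workers > 1`.
- The enumeration behind exact variances is $O(n^E n^C)$ per distinct
  probability pair; at $n=800$ a single enumeration is still fast, but
  heterogeneous $\theta_i$ defeat the memoization by design.
- Only two-arm binomial tables with equal arm sizes are generated;
  risk-difference and standardized-mean-difference worlds are out of
  scope, as are CIs for $I^2$ and for $\mu$.
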