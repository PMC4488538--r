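---
title: "Score-type confidence intervals for the Youden Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-type confidence intervals for the Youden Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(youdenci)
```

## The estimand

A continuous diagnostic marker is measured in a non-diseased group
$X_1,\dots,X_m$ and a diseased group $Y_1,\dots,Y_n$, with the diseased
group assumed stochastically larger.  For a cut point $c$ the test calls a
subject positive when the marker is at least $c$, so
$\mathrm{Sen}(c) = P(Y \ge c)$ and $\mathrm{Spe}(c) = P(X \le c)$.  The
Youden Index

$$J = \max_c\,[\mathrm{Sen}(c) + \mathrm{Spe}(c) - 1]
    = \max_c\,[P(X \le c) - P(Y < c)]$$

summarizes the ROC curve by the best achievable trade-off with equal weight
on sensitivity and specificity; $J = 0$ means the marker is uninformative
and $J = 1$ a perfect separator.  The maximizing threshold $c^*$ is the
optimal cut point.  The theoretical range of $J$ is $[-1, 1]$, but negative
values have no practical interpretation; the estimators here return values
in $[0, 1]$ and warn when the estimate is near zero, the usual symptom of a
swapped group orientation (we never flip automatically, because that would
silently change the estimand).

## Point estimators

`youden_empirical()` maximizes the plug-in objective
$D(c) = \#\{x_i \le c\}/m - \#\{y_j < c\}/n$.  $D$ is a step function that
changes value only at observed data points, so the package maximizes over
the pooled unique values plus one sentinel below the pooled minimum, where
$D = 0$; this finite search is exact, and the sentinel guarantees a
non-negative estimate.  Two conventions matter and are applied literally:
$X \le c$ is inclusive and $Y < c$ is strict, so a value tied with the cut
counts towards specificity and is *not* counted against sensitivity.  On
tie-free data the result coincides with maximizing
$\mathrm{Sen} + \mathrm{Spe} - 1$ over realizable thresholds (the pROC
cross-check in the test suite); with cross-group ties it can exceed it,
because a tied value is credited to both groups.

Among tied maximizers the smallest cut is returned.  Exact ties are decided
in integer arithmetic (the objective is scaled to
$n\,\#\{x_i \le c\} - m\,\#\{y_j < c\}$) because the floating-point
objective can order exactly tied cells inconsistently (in doubles,
$1 - 2/3 > 1/3$).

`youden_ac()` is the Agresti–Coull-adjusted version: each proportion
$k/N$ is replaced by $(k + z^2/2)/(N + z^2)$ with
$z = z_{1-\alpha/2}$ — at the 95% level roughly "add two successes and two
failures" — and the objective is re-maximized over the same candidate set.
The adjusted maximizer may differ from the empirical one; we re-maximize
rather than plugging in the empirical cut because the adjusted estimator is
defined as its own maximum.

## The NP and NPAC intervals

At the selected cut, $J = p_1 - p_2$ with $p_1 = P(X \le c^*)$,
$p_2 = P(Y < c^*)$ two independent binomial proportions.  Each gets a
Wilson score interval — the roots of
$(p - \hat p)^2 = z^2\,p(1-p)/N$, which treats the $p$ inside the variance
as unknown instead of plugging in $\hat p$ — and the two intervals are
combined by the square-and-add (MOVER) rule centred at $\hat J$:

$$ (J_L,\,J_U) = \bigl(\hat J - A,\; \hat J + B\bigr), \quad
A = z\sqrt{\tfrac{l_1(1-l_1)}{m} + \tfrac{u_2(1-u_2)}{n}}, \quad
B = z\sqrt{\tfrac{u_1(1-u_1)}{m} + \tfrac{l_2(1-l_2)}{n}}. $$

`ci_np()` runs this pipeline with the empirical estimate and proportions;
`ci_npac()` with the adjusted estimate and adjusted fractions.  One design
point was genuinely open: which denominators the Wilson roots should use in
the NPAC variant.  We treat the adjusted fraction as a proportion out of
$\tilde N = N + z^2$ effective trials, so its Wilson roots use $\tilde N$,
while $A$ and $B$ keep the raw $m$ and $n$ exactly as the combination
formula is written.  This pairing is internally consistent (the
Agresti–Coull estimate *is* the centre of the Wilson interval on $\tilde N$
trials) and reproduces the standard worked-example results for this data
set to all printed digits; the alternative raw-denominator reading differs
in the third decimal.

Both intervals are clipped to $[-1, 1]$, the theoretical range of $J$ (not
$[0, 1]$: the lower limit of an uninformative marker can legitimately be
negative).  A single `conf.level` drives both the $z$ inside the adjusted
estimator and the interval $z$.

## The BAC comparator

`ci_bac()` is the bootstrap mean-and-variance interval for the adjusted
estimate: $B$ within-group resamples ($m$ from $x$, $n$ from $y$, with
replacement), the adjusted estimate re-maximized on each, and the interval
$\bar{J^*} \pm z\,\widehat{\mathrm{sd}}(J^*)$ with the $(B-1)$-denominator
sample standard deviation.  The centre is the bootstrap mean, not the
original-sample estimate.  Degenerate resamples (a group collapsing to one
repeated value) are kept — the estimator is well defined on them and
redrawing would bias the bootstrap distribution.  A resample is represented
internally by the multinomial vector of resampling weights on the original
observations: a resample's objective only jumps at resampled values, which
are a subset of the original pooled values, so the original candidate grid
is exact for every resample, and the cumulative counts become two
triangular matrix products.  This is statistically identical to naive index
resampling (the weights are a sufficient statistic for the resample) and
makes full-replication coverage studies of the bootstrap interval feasible
on one CPU.  The seed is a mandatory, documented argument (default 1234)
so published intervals are reproducible; the caller's RNG state is restored
afterwards.

## Scenario machinery

`dist_spec()` supports the three families used in the coverage studies:
normal, gamma in the **rate** parameterization (density
$\theta^\kappa/\Gamma(\kappa)\,x^{\kappa-1}e^{-\theta x}$, mean
$\kappa/\theta$ — a sampling test guards against rate/scale confusion), and
the standard (unscaled) Student-$t$.  `true_youden()` maximizes
$F_X(c) - F_Y(c)$ with a 512-point grid over the union of the two
$[10^{-4}, 1-10^{-4}]$ quantile ranges followed by bounded refinement in
the best grid cell (tolerance $10^{-9}$).  The grid stage matters: for
unequal variances or shapes the densities cross twice and the objective is
bimodal, so a pure local optimizer can be captured by the wrong mode.

`solve_target_param()` calibrates a scenario to a target index by
root-solving $J(\text{param}) - J_{\text{target}} = 0$ (`uniroot`,
parameter tolerance $10^{-10}$, giving $|\Delta J| < 10^{-6}$).  The
default brackets encode the monotonicities of the four scenario families:
$J$ increases in a normal mean, and increases as a gamma rate decreases
below the non-diseased rate (the diseased mean $\kappa/\theta$ must exceed
the non-diseased mean for a positive index).  A bracket that does not
straddle the target is reported with the attained $J$ at both ends.
Because published scenario parameters are rounded to four decimals,
round-trip checks of parameter $\to J$ use a $5\times10^{-3}$ tolerance
rather than machine precision.

## The coverage engine and what the generator emulates

`simulate_coverage()` draws `n_sims` independent samples from a calibrated
scenario and reports, per method, the fraction of intervals containing the
scenario's pre-defined index (closed-interval containment — boundary hits
are measure-zero here) and the average width.  Per-replicate seeds are
derived from the master seed up front, so every method sees the identical
sample within a replicate (paired design) and any method subset reproduces
the same per-method results.  Failures in a single replicate are counted
and excluded rather than aborting the cell.  When a scenario is declared
with a pre-defined target (parameters printed to 4 decimals), coverage is
assessed against that target, matching how such studies define the
estimand.

The generator draws iid continuous values from clean parametric families.
Real diagnostic-marker data differ in ways the simulations deliberately do
not model: recording precision produces heavy ties (the prostate example
has five cross-group tied values), case-control sampling can induce
covariate structure, and marker distributions are rarely exactly normal or
gamma.  Passing coverage tests therefore validate the interval
constructions under the stated families, not the behaviour of any
particular clinical marker.

Default study sizes follow the conventional design: `n_sims = 5000`
replicates, `B = 500` bootstrap resamples, 95% nominal level.  The package
test suite runs the three spot-checked coverage cells at the full 5000
replicates (the paired engine makes this take seconds, and roughly ten
seconds for the bootstrap cell); a handful of supporting property tests use
300–500 replicates, where the binomial Monte-Carlo error
$\sqrt{p(1-p)/n_{\text{sims}}}$ is the stated tolerance.

## Known limitations

- The NPAC interval inherits the adjusted estimator's bias towards $1/2$
  differences: for large true $J$ (around 0.9) its coverage drops well
  below nominal, and for small $J$ it is very conservative with wide
  intervals.  The BAC interval can collapse to near-zero coverage for small
  samples and large $J$.  The NP interval is the robust default — this is
  exactly the behaviour the coverage tables quantify.
- One-sided intervals, continuity-corrected Wilson variants, weighted or
  cost-ratio generalizations of the index, and smoothed/kernel ROC
  estimation are out of scope.
- The orientation assumption (diseased stochastically larger) is the
  user's responsibility; the near-zero-estimate warning is a heuristic, not
  a guarantee.

## A worked example

```{r example}
s <- prostate_nodal()
youden_empirical(s)
youden_ci(s, seed = 1)
```
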