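---
title: "Eliciting skew-normal priors in five steps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting skew-normal priors in five steps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitsn)
```

## The problem

Experts hold knowledge that is often worth formalizing as a prior
distribution — for forecasting a business quantity, enriching a small
sample, or diagnosing whether incoming data contradict prior belief.
But experts are demonstrably poor at stating variances or full
distributions in one pass.  **elicitsn** therefore decomposes the
elicitation into small steps with visual, repeatable feedback:

1. capture the expert's *location* belief as chips on a grid
   (trial roulette / chips-and-bins);
2. fit a distribution to the chips and let the expert accept or adjust;
3. ask only for a *reasonable lower and upper bound* around the accepted
   location;
4. fit scale and shape from those bounds, again with accept/adjust;
5. use the elicited prior in a Bayesian analysis: update it with data,
   or score a prior-data conflict.

Everything interactive in the original protocol is represented here as
pure batch re-invocation: "adjust" means calling the fitting function
again with edited inputs, and each call is logged in the record's
`iterations` field.  There is no hidden state and no implicit seed.

## The skew normal used throughout

Uncertainty around a best guess is rarely symmetric, so the package
represents beliefs with a skewed normal: a standard normal base density
$f$ made asymmetric by allocating mass around the mode,

$$p(\epsilon \mid \gamma) \;=\; \frac{2}{\gamma + 1/\gamma}
  \left\{ f(\epsilon/\gamma)\, I_{[0,\infty)}(\epsilon)
        + f(\gamma\epsilon)\, I_{(-\infty,0)}(\epsilon) \right\},$$

with mode at $0$ and shape $\gamma > 0$.  A fraction
$\gamma^2/(1+\gamma^2)$ of the mass lies above the mode; $\gamma = 1$
recovers the normal exactly, and replacing $\gamma$ by $1/\gamma$
mirrors the density about the mode.

The raw variable $\epsilon$ has mean
$m_\gamma = \sqrt{2/\pi}\,(\gamma - 1/\gamma)$ and second moment
$\gamma^2 - 1 + \gamma^{-2}$.  The package exposes the *moment
parameterization*: the user-facing variable is
$x = \mu + \sigma\,(\epsilon - m_\gamma)/s_\gamma$, so the declared
`mean` and `sd` are the true first two moments for every shape.  This
choice is what lets the fitting stages hold the moments fixed while
optimizing only the shape: the location the expert accepted cannot
drift when the skewness changes.  The raw form, with its mode and
standardization constants, is available through `sn_raw_moments()` and
`sn_mode()`.

The cdf is piecewise normal,

$$F(\epsilon) = \begin{cases}
  \dfrac{2}{1+\gamma^2}\,\Phi(\gamma\epsilon), & \epsilon < 0,\\[2ex]
  \dfrac{1}{1+\gamma^2} + \dfrac{2\gamma^2}{1+\gamma^2}
    \left[\Phi(\epsilon/\gamma) - \tfrac12\right], & \epsilon \ge 0,
\end{cases}$$

and inverts in closed form (two `qnorm` branches), so `qskewnorm()` is
exact rather than iterative; sampling is by inversion of uniforms,
which makes every stochastic routine exactly reproducible from its
seed.

## Step 1: the roulette grid

The grid is 600 columns by 300 rows by default.  Columns discretize the
value axis in equal steps from the expert's reasonable minimum to
maximum (the two range-defining chips occupy the end columns); rows
only stack chips and carry no numeric meaning.  Each chip contributes
one copy of its column's value to the elicited vector, so with $k$
chips each chip carries $100/k$ percent of the mass — 5% each under the
classic 20-chip variant.  The adopted procedure is the more flexible
one: at least 7 chips, no fixed total, with the fit re-drawn after
every chip.

One design point: an interactive renderer may light up several pixels
per click, but mass is carried per chip, so the package collapses a
chip to a single cell.  This keeps chip weights integral and makes the
chips-to-values map exactly invertible (the value histogram equals the
per-column chip counts).

## Steps 2–4: constrained maximum likelihood

`snorm_fit()` implements both constraint patterns:

* **Location stage** (`mean = NULL`): `mean` and `sd` are fixed at the
  sample mean and sample sd (denominator $n-1$; any consistent
  convention is absorbed by the moment parameterization) and only
  $\gamma$ is estimated, by maximizing the log-likelihood over
  $\log\gamma \in [\log 0.01, \log 100]$.  The location passed forward
  to step 3 is the fitted distribution's mean.
* **Uncertainty stage** (`mean = mu0`): the input is the deterministic
  `bounds_sample()` — $\mu_0$ repeated 100 times, the lower and upper
  bound 10 times each, 120 values in all — and $(\sigma, \gamma)$ are
  estimated jointly with the distribution mean constrained to $\mu_0$
  exactly.

The 10:100:10 weighting is what turns two bound statements into both a
scale and a shape: symmetric bounds yield $\gamma \approx 1$, while an
upper bound farther from $\mu_0$ than the lower bound pulls
$\gamma > 1$, and widening it never decreases the fitted shape.

### Numerical choices

The likelihood is continuous but *kinked* in the parameters: whenever a
data value crosses the fitted mode, the density switches branch.
Golden-section or quasi-Newton search alone can stall on these kinks,
so both stages use a coarse log-scale grid to bracket the optimum
before refining (401 points in 1-D; a 25 × 41 grid, L-BFGS-B, and three
coordinate-wise refinement sweeps in 2-D).  Parameter tolerances are
$10^{-8}$ on the log scale or better; the test suite holds both stages
to within $10^{-4}$ log-likelihood units of exhaustive grid-search
oracles.  The shape box $[0.01, 100]$ is a practical choice: values at
its edges indicate an effectively one-sided belief (bounds so
asymmetric that the ML shape diverges), and the box keeps such fits
finite and reportable.  Degenerate inputs — all chips in one column,
bounds that fail to bracket $\mu_0$, a bounds sample whose variance
underflows — raise validation errors rather than returning a fit.

## Scale harmonization

Experts may reason per product, per type, per region, or in totals.  A
`scale_spec(a, b, label)` records the linear map
$\theta^* = a\theta + b$ from an expert's scale to a common reference
scale; under it a distribution's mean becomes $a\mu + b$ and its sd
$|a|\sigma$.  The family is closed under affine maps: the shape is
unchanged for $a > 0$ and becomes $1/\gamma$ (the mirror image) for
$a < 0$ — negative multipliers are supported for completeness.
`harmonize_panel()` routes every record through the reference scale to
any target scale, preserving order and keeping source labels for
audit.  Stored values are full precision; two-decimal display is left
to reporting.

A worked four-expert example: with 104 products in 9 types, per-product
means (1.8, 2.1) and per-type means (23, 24.5) harmonize to totals
(187.2, 218.4, 207, 220.5), or per-product (1.80, 2.10, 1.99, 2.12 at
two decimals).

```{r table2}
pp <- scale_spec(104, label = "per product")
pt <- scale_spec(9, label = "per type")
harmonize_panel(list(1.8, 2.1, 23, 24.5), list(pp, pp, pt, pt),
                target = scale_spec(1, label = "total"))
```

## Step 5: updating and prior-data conflict

The elicited prior concerns a mean parameter $\theta$, so the minimal
observation model consistent with that use is
$y_i \sim N(\theta, \sigma_y^2)$ with a known (typically plug-in)
`likelihood_sd`.  With a skewed prior the posterior has no closed form;
`posterior_grid()` evaluates prior $\times$ likelihood on a
deterministic, equally spaced axis and normalizes by the trapezoid
rule, so results are exactly reproducible without sampling.  The axis
is placed in two passes — a wide provisional axis, then a final axis at
the provisional posterior mean $\pm 8$ posterior sd (4001 points by
default) — leaving truncated mass far below $10^{-8}$.  With a shape-1
prior this reproduces the conjugate normal-normal posterior to well
under $10^{-6}$ in mean and sd.

`summarize_posterior()` collapses the grid back to the reporting form
$SN(\mu_1, \sigma_1^2, \gamma_1)$: mean and sd are the grid moments,
held exactly, and the shape minimizes the integrated squared deviation
from the gridded density — self-consistent to $10^{-3}$ when the grid
really is a skew normal.

The protocol calls for a prior-data conflict check without fixing a
statistic, so the package adopts the standard prior-predictive
two-sided tail probability of the observed sample mean: simulate
$\theta$ from the prior, then a sample mean from the likelihood, and
report $2\min\{P(\bar y_{sim} \le \bar y), P(\bar y_{sim} \ge \bar
y)\}$.  Scores near 1 mean agreement; values below 0.05 conventionally
flag conflict.  Under data truly drawn from the prior predictive the
score is approximately uniform (slightly conservative), which the suite
checks empirically over 500 replicates.

## Synthetic experts and what passing tests mean

`simulate_expert()` generates the chip placements of an ideally
calibrated expert: draws from a known skew normal, binned to the
nearest column, with the two range chips forced into the end columns
and out-of-range draws clamped to them.  It emulates the *mechanics* of
the elicitation — binning, range chips, integral chip weights — under
the study-scale conditions: 100 chips per expert, step-3 bounds at the
generating distribution's 5th/95th percentiles, shapes between 0.5 and
2, panels of 10 synthetic experts.

With 100 chips the chip-average has Monte-Carlo error exactly
$0.1\sigma$, so recovery is asserted at the panel level: the mean
absolute error of the recovered location across the 10 pipelines must
be at most $0.1\sigma$ (its expectation is $\approx 0.08\sigma$).  A
per-pipeline bound at the same number would amount to a one-standard-
error test that fails a third of ideal experts by construction.

Synthetic experts do **not** emulate human behavior: no anchoring, no
overconfidence, no rounding to favorite numbers, no disagreement
between the chips and the later bounds.  Passing recovery tests
therefore validates the *machinery* (grid mechanics, fitting,
transformation, updating), not the behavioral quality of any real
elicitation — that requires feedback with actual experts, which is
exactly why the protocol keeps its accept/adjust loops.

## Problem sizes and limitations

The suite runs fits on vectors of 120–5000 values, posterior grids of
2001–4001 points, conflict scores from $10^3$–$10^5$ prior-predictive
draws, and 10-expert synthetic panels; these sizes make every check
exact enough to hold at the stated tolerances while keeping a full run
to well under a minute.  Known limitations: quantile-based elicitation
is deliberately out of scope (bounds are the only uncertainty input);
the observation model is a normal likelihood for a mean — other
likelihoods require gridding your own posterior; experts are summarized
individually, with no pooled consensus prior; and only linear scale
maps are supported.
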