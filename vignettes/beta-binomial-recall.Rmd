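---
title: "Hierarchical beta-binomial analysis of 2x2 recall experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical beta-binomial analysis of 2x2 recall experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallbb)
```

## The scientific setting

The package analyses cued-recall experiments in which participants study
cue–target pairs (e.g. foreign-language vocabulary) and are tested after a
delay. Two manipulations are crossed: the *delivery* of the task
instructions (enthusiastic vs. neutral) and the *sequencing* of study
repetitions (massed: all repetitions of an item back-to-back; spaced:
every repetition separated by all other items — the classic spacing
manipulation). Two outcomes are recorded per participant: the number of
items recalled exactly correctly, and the number of items answered at all.
The second outcome matters because motivational manipulations often shift
a participant's *response criterion* — how willing they are to guess —
without improving memory itself.

## Model

For participant $p$ in cell $(e,s)$ with $y_p$ correct out of $n$ items:

$$y_p \sim \mathrm{Binomial}(\theta_p, n), \qquad
\theta_p \sim \mathrm{Beta}(\alpha_{e,s}, \beta_{e,s})$$

with the beta written in its mode–concentration form

$$\alpha_{e,s} = \mu_{e,s}(\kappa_{e,s}-2)+1, \qquad
\beta_{e,s} = (1-\mu_{e,s})(\kappa_{e,s}-2)+1 .$$

$\mu_{e,s} \in (0,1)$ is the cell's most credible recall proportion and
$\kappa_{e,s} > 2$ its concentration: the larger $\kappa$, the more
tightly participants bunch around $\mu$. Priors are vague and informed
only by the scale of the data: $\mu_{e,s} \sim \mathrm{Beta}(1,1)$ and a
gamma prior with mode 10 and standard deviation 100 on the concentration.

**Where the gamma prior sits.** A gamma with support $(0,\infty)$ placed
directly on $\kappa$ would put mass on $\kappa < 2$, where
$\alpha = \mu(\kappa-2)+1$ can go non-positive and the mode
parameterization breaks down. The package therefore places the
Gamma(mode 10, sd 100) prior on $\kappa - 2$, the standard implementation
of this parameterization; with datasets of tens of participants per cell
the two-unit shift is negligible relative to the prior's spread
(sd 100). `prior_spec(kappa_prior_on = "kappa")` switches to the
unshifted reading (states with $\kappa \le 2$ then simply get zero prior
mass) for sensitivity analysis.

Applied to attempted-response counts, the same model captures the ceiling
structure of that outcome: the mode sits at the maximum in every
condition, so condition differences express themselves through $\kappa$ —
a higher concentration means responses bunched harder against the ceiling,
i.e. fewer blanks.

## Sampler

`run_mcmc()` is a Metropolis-within-Gibbs sampler written for exactly
this model:

* every $\theta_p$ is drawn *exactly* from its conjugate full
  conditional $\mathrm{Beta}(\alpha + y_p,\ \beta + n - y_p)$ — no
  tuning, no rejection;
* each cell's $(\mu, \kappa)$ is updated jointly by random-walk
  Metropolis on $(\mathrm{logit}\,\mu,\ \log(\kappa-2))$, with the
  log-Jacobian $\log\mu + \log(1-\mu) + \log(\kappa-2)$ included in the
  acceptance ratio. Given the $\theta$'s, the cell target depends on the
  data only through $\sum\log\theta_p$ and $\sum\log(1-\theta_p)$, so a
  cell update costs O(1) after those sums.

Proposal scales start at 0.3 (logit scale) and 0.5 (log scale) and are
tuned multiplicatively every 25 iterations toward ~0.3 acceptance during
the adaptation phase *only*, then frozen — adaptation during sampling
would invalidate the invariant distribution. The default protocol is four
chains of 1,000 adaptation + 4,000 burn-in + 60,000 sampling steps
thinned by 3, i.e. 20,000 retained draws per chain, 80,000 pooled.
Thinning applies to the sampling phase only, so retained draws per chain
are `floor(n_samples / thin)`.

Numerical guards: $\theta$ draws are clamped to
$[10^{-12}, 1-10^{-12}]$ before taking logs (a conjugate draw can round
to exactly 1 when the posterior piles against the ceiling), and proposals
outside the support evaluate to $-\infty$ and are rejected rather than
erroring.

**Initialization.** $\mu$ starts at each cell's empirical mean proportion
clipped to (0.01, 0.99); $\kappa$ at prior mode + 2; $\theta_p$ at
$(y_p+1)/(n+2)$. Data-informed starts shorten burn-in without touching
the stationary distribution. Chains are seeded from independent streams
derived from the master seed, and the whole fit is bit-reproducible.

**Diagnostics.** `gelman_rubin()` implements the classic PSRF
$\sqrt{((n-1)/n\,W + B/n)/W}$; `effective_sample_size()` implements
$N/(1 + 2\sum\rho_t)$ with the initial-positive-sequence truncation
(consecutive lag pairs accumulated while their sum stays positive,
autocorrelations capped at lag 2,000). Monitored parameters are the four
$\mu$ and four $\kappa$; $\theta$ draws are retained only behind
`save_theta = TRUE` to bound memory.

## Posterior summaries and contrasts

All contrasts are computed draw-wise on the pooled retained draws:

* **Main effects** — the unweighted mean of the two cell parameters at
  one factor level minus the mean at the other, fixed order
  spaced − massed and enthusiastic − neutral. (Cells in these designs are
  near-balanced; an unweighted collapse is the transparent choice, and a
  weighted variant would only matter under severe imbalance.) On the
  $\mu$ scale the contrast is multiplied by the number of items, so
  effects read in items recalled.
* **Interaction** — (enthusiastic − neutral | massed) −
  (enthusiastic − neutral | spaced).
* **Difference of main effects** — spacing effect − enthusiasm effect,
  in items.

Each contrast is summarized by a 95% **HDI** — the narrowest window
containing `ceiling(0.95 N)` sorted draws, ties broken deterministically
by the lowest starting index — and a **posterior mode**, the argmax of a
Gaussian KDE (Silverman bandwidth, 512-point grid). The KDE mode is
documented deliberately: mode estimates of sub-item effects are
bandwidth-sensitive, and an alternative estimator (coarse histogram
argmax) agrees only to within about one bandwidth, which is the realistic
precision for mode comparisons. The decision rule is the usual one: an
effect is treated as reliable when its 95% HDI excludes zero.

## Robust two-group model for ratings

Rating items (instructor-enthusiasm checks, memorability, motivation) are
treated as numeric and compared with a robust model: each group's values
follow $t(\nu, m_g, s_g)$, so a handful of extreme ratings cannot drag
the group means the way a normal likelihood allows. The stated structure
fixes the mean prior's center at the pooled mean and the scale prior's
magnitude at 5× the pooled SD; the remaining pieces are under-determined,
and the package adopts the widely used defaults for this model family:

* $m_g \sim \mathrm{Normal}(\text{pooled mean},\ 1000 \times \text{pooled SD})$ —
  effectively flat over the data range;
* $s_g \sim \mathrm{Uniform}(\text{pooled SD}/1000,\ 5 \times \text{pooled SD})$ —
  the 5× figure as a hard upper bound (a `half_normal` reading, with the
  5× figure as a scale parameter, is available behind `scale_prior`);
* $\nu - 1 \sim \mathrm{Exponential}(\text{mean } 29)$ — prior mass
  spread across both heavy-tailed and near-normal regimes.

Sampling reuses the same chain protocol via coordinate-wise adaptive
Metropolis on $(m_1, m_2, \log s_1, \log s_2, \log(\nu-1))$. The reported
quantity is the posterior of $m_1 - m_2$ (first − second in sorted label
order), summarized like every other contrast.

## What the simulator emulates — and what it does not

`simulate_experiment()` draws data from the model's own generative chain:
per-cell $\theta$ from the mode/concentration beta, recall counts
binomially, and attempt counts from a second beta-binomial at the
ceiling, clamped so attempts ≥ correct (a correct answer is necessarily
non-blank). Study sequences follow the two schemes exactly: massed keeps
each item's repetitions contiguous (gap 1) in a random item order; spaced
repeats one random permutation, the unique block structure in which every
repetition is separated by all other items. Massed item order is
randomized per participant seed — whether real experiments re-randomize
per participant is usually unstated, and nothing downstream consumes the
order, only the counts.

Default attempt-generating parameters are mode 0.999, concentration 40.
The closed-form ceiling probability
$P(\text{all } 36 \text{ attempted}) = B(\alpha+36,\beta)/B(\alpha,\beta)$
is then ≈ 0.51, reproducing the roughly-half-at-ceiling pattern typical
of attempted-response counts; concentration 200 would push this to ≈ 0.82.
The default recall truth used in the acceptance simulations assigns modes
(0.30, 0.35) to the massed cells and (0.55, 0.50) to the spaced cells —
a spacing effect of 0.2 (7.2 items) with an exactly null enthusiasm
effect — so the two HDI decisions have known ground truth: the spacing
HDI should exclude zero, and the enthusiasm HDI should include it at its
nominal rate.

Because the simulator *is* the model, passing recovery tests demonstrates
correct inference, not model adequacy for real data. Real recall data
add per-item difficulty, participant covariates, retention-interval
variation, scoring ambiguity and non-beta heterogeneity, none of which
the count-level simulator represents. Exclusion decisions (incomplete
sessions, duplicate ids) are likewise upstream of this package: the
loader validates and optionally drops structurally invalid rows, but does
not re-decide study-specific exclusions.

## Numerical and design choices

* All densities are computed in log space; binomial coefficients via
  `lchoose`/`lbeta`.
* The gamma mode/sd solve uses the closed form
  $r = (m + \sqrt{m^2 + 4s^2})/(2s^2)$, $k = 1 + mr$, exact to machine
  precision (mode 0 degenerates to the exponential).
* `hdi()` requires ≥ 20 draws; `posterior_mode()` ≥ 100 (a constant
  sample returns the constant).
* Degenerate diagnostics (zero-variance chains) warn and return `NA`
  rather than fabricate a number.
* Item indices in exported trial sequences are 0-based.
* Cell allocation defaults to equal sizes; `study_design()` accepts a
  named per-cell vector to mimic unbalanced real samples.

## Problem sizes used in the test suite

The tests favour many short chains over few long ones: unit fits use 2
chains × 500–1,500 retained draws; the quadrature cross-check runs 4
chains × 5,000 retained draws against a 400 × 400 grid oracle (cells are
independent in that construction, so per-cell two-dimensional quadrature
over $(\mu, \log(\kappa-2))$ with the beta-binomial marginal is exact up
to grid error); prior-recovery uses 20,000 pooled draws thinned by 10;
and the calibration study uses 20 replicates of a 200-participant
experiment at 2 chains × 4,000 draws. These sizes give Monte-Carlo error
comfortably inside every asserted tolerance while keeping the whole suite
in the single-digit minutes.

## Known limitations

* No per-item or trial-level model; the unit of analysis is the
  per-participant count.
* No covariates, no ordinal treatment of rating scales, no Bayes factors
  or ROPE decisions — the decision rule is HDI-excludes-zero only.
* The Metropolis cell update is serial across the four cells; for this
  model's size that is far from a bottleneck, but the sampler makes no
  attempt at within-chain parallelism.
* The robust model's label-swap symmetry holds distributionally, not
  bit-for-bit, because the coordinate scan consumes RNG draws in a fixed
  order.
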