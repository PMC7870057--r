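---
title: "Limiting-dilution inference: models, belts, and design choices"
author: "ldassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limiting-dilution inference: models, belts, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldassay)
```

## The experimental setting

Two closely related limiting-dilution experiments are covered.

**Transfection efficiency.** After electroporation and selection, known
fractions $f_i$ of a transfection are distributed across 96-well plates and
the number of wells containing growing, drug-resistant cells is counted.
Routine transfections are plated at 20% and 4% on two plates; very
efficient ones at 2% and 0.4%. The quantity of interest is $N$, the number
of independent stable transfectants in the whole transfection.

**Selectable-marker loss.** A population in which an inducible
endonuclease may have excised a resistance cassette is plated without drug
at a nominal 1.5 cells per well, grown out, and replica-plated with and
without the drug. A well that grows without drug but not with it contained
only cells that lost the marker. The quantity of interest is $q$, the
per-cell probability that the marker was lost before plating.

## The Poisson single-hit model

Cells are deposited independently, so the number of clone founders per
well is Poisson with mean $\lambda$ and

$$P(\text{well positive}) = 1 - e^{-\lambda}.$$

For a plate of $W$ wells carrying fraction $f$ of a transfection of $N$
clones, $\lambda = N f / W$ and the positive count is
$k \sim \mathrm{Binomial}(W,\, 1 - e^{-Nf/W})$. A single plate inverts in
closed form, $\hat\lambda = -\ln(1 - k/W)$ and $\hat N = \hat\lambda W/f$.
Several plates from the same transfection are combined through the joint
binomial likelihood over a shared $N$ (not by averaging the per-plate
estimates): this uses saturated plates' information gracefully and weights
plates by their actual information content. The objective is unimodal in
$N$, so the MLE is found by bounded one-dimensional search on the log
scale (relative tolerance $10^{-8}$), bracketed by the per-plate closed
forms. Counts are of wells, not cells; outgrowth kinetics and cell death
after plating are not modelled.

A plate with $k = W$ leaves $\lambda$ unbounded. With at least one
unsaturated plate the joint fit remains two-sided; if every plate is
saturated the fit degenerates to a one-sided lower bound — the smallest
$N$ whose probability of producing all-positive wells on every plate
exceeds $1 - \text{ci\_level}$ — and the result is flagged.

## The marker-loss model

Marker loss is assumed complete before plating (induction precedes
plating by 48 h), so each founder has independently lost the marker with
probability $q$. A populated well is drug-sensitive iff *all* its
founders lost the marker. Conditioning on occupancy,

$$p_{\text{sens}}(\lambda, q)
  = \frac{e^{-\lambda(1-q)} - e^{-\lambda}}{1 - e^{-\lambda}},$$

which tends to $q$ as $\lambda \to 0$ (clonal wells) and to the
appropriate boundary at $q \in \{0, 1\}$. The plating density is
estimated from the same plate's populated count, $\hat\lambda =
-\ln(1 - n/W)$, with the nominal 1.5 cells/well available as a fallback
for saturated plates. Given $\hat\lambda$, the sensitive count is
binomial in $p_{\text{sens}}$, and the MLE of $q$ inverts the observed
fraction in closed form:

$$\hat q = 1 + \frac{1}{\lambda}
  \ln\!\Big(\tfrac{s}{n}\big(1 - e^{-\lambda}\big) + e^{-\lambda}\Big).$$

The boundary cases $s = 0 \mapsto 0$ and $s = n \mapsto 1$ are returned
exactly, not through the logarithm.

## Confidence intervals by grid inversion

Both intervals are built the same way, as simulated confidence belts:

1. Lay a grid over the parameter — log-spaced cells-per-well from 0.001
   to 10 (200 points by default) for plating problems; a 0.005-step grid
   on $[0,1]$ for $q$.
2. At each grid value, simulate platings (the default budget of $10^6$
   total platings is divided equally across grid points) and record the
   equal-tailed central interval of the observable at the nominal level.
3. Accept every grid value whose band contains the observation; report
   the smallest and largest accepted values.

For the loss interval, each simulated plating first resamples the
density, $\lambda^* \sim \mathcal N(\hat\lambda, \mathrm{SE})$ truncated
at zero, with the delta-method spread
$\mathrm{SE}(\hat\lambda) = \sqrt{\hat p / (W(1-\hat p))}$, $\hat p =
n/W$; then draws populated wells and sensitive wells from the compound
model. This propagates the uncertainty of the plating density into the
interval for $q$.

Numerical choices worth recording:

* **Equal-tailed $\alpha/2$ bands throughout.** Intervals whose endpoint
  sits on the parameter boundary ($s = 0$ or $s = n$) are flagged
  `one_sided` but use the same band construction. For the 0/71
  experiment this reports the largest $q$ at which a zero count is still
  inside the central 90% band, i.e. $P(S = 0 \mid q) \ge 0.05$ — about
  0.08. Re-deriving the bound with the full 10% in one tail would give
  about 0.065; the $\alpha/2$ convention was chosen because it treats
  interior and boundary observations identically.
* **Monotonisation of band edges.** Raw simulated quantiles ripple with
  Monte-Carlo noise; edges are made non-decreasing by a widening-only
  pass (suffix-minimum for the lower edge, prefix-maximum for the
  upper). This guarantees the accepted set is an interval and never
  removes a grid value the raw bands accepted, at the cost of a ripple's
  worth of extra width.
* **Multi-plate statistic.** The belt needs a scalar observable; the
  total positive-well count $\sum_i k_i$ is used. Its expectation
  gradient in $N$ is $\sum_i f_i e^{-\lambda_i}$ per well — the same
  relative weights the likelihood score gives the plates — so inverting
  it is locally equivalent to likelihood inversion and the interval
  brackets the joint MLE. (An earlier candidate, the fraction-weighted
  sum $\sum_i k_i/f_i$, overweights the dilute plate about five-fold
  under the standard designs and can exclude the MLE on discordant
  draws.)
* **Degenerate inputs.** $k = 0$ is reported one-sided with lower
  endpoint 0; an all-saturated observation runs into the top of the grid
  and is flagged; an empty acceptance set (possible only under extreme
  budget/step combinations) triggers one 5-fold grid refinement and,
  failing that, an `NA` interval with a warning.
* **Tie behaviour.** Simulated quantiles use the inverse-CDF convention
  (`type = 1`), matching the exact binomial quantile in the
  infinite-budget limit.
* **Reproducibility.** All randomness flows from the single seed in
  `sim_config()`; every fit echoes its config and the number of
  simulated platings actually used.

The single-plate belt agrees with the Clopper–Pearson interval mapped
through $\lambda = -\ln(1-p)$: with exact binomial quantiles the two
coincide in continuous $\lambda$, so on a grid the endpoints land within
one grid cell, which is how the agreement is asserted in the tests (the
belt endpoint's grid index within one of the cell containing the mapped
Clopper–Pearson endpoint). Finite simulation can flip a band edge at
grid points where the binomial CDF sits within Monte-Carlo noise of
$\alpha/2$; the index-based comparison absorbs exactly one such flip.

## What the generators emulate — and what they do not

`gen_transfection()` draws plate counts from the exact forward model;
`gen_loss_experiment()` simulates cell by cell (Poisson founders,
binomial losses, replica readout), so its marginal behaviour checks the
closed-form $p_{\text{sens}}$ rather than assuming it. The generators
reproduce the study conditions: 96-well plates, the 20%/4% and 2%/0.4%
designs over their stated working ranges (100–6000 and 1000–60000
clones), nominal 1.5 cells/well plating for loss experiments.

They do not emulate pipetting error in $f_i$, cross-well contamination,
cell death between plating and outgrowth, partial drug resistance, or
marker loss continuing during outgrowth. Passing coverage on synthetic
data therefore validates the inference machinery under the stated model,
not the model's adequacy for any particular bench dataset.

## Validation at desk scale

The test suite checks, among others:

* exact closed-form identities and limits of `p_positive`, `q_mle`,
  `p_sensitive`, and the per-generation conversion;
* belt quantiles against exact binomial quantiles, and the single-plate
  inversion against Clopper–Pearson as above;
* empirical coverage of the 90% intervals: clone numbers drawn
  log-uniformly over each design's working range (500 replicates per
  design), and loss scenarios at $q \in \{0.2, 0.35, 0.5\}$,
  $\lambda \in \{1.5, 3\}$ (500 replicates each), all required to land
  in $[0.85, 0.95]$, with clone-recovery relative bias below 5%.

Simulation sizes in the routine tests are scaled to roughly $10^4$–$10^6$
platings per belt — enough that Monte-Carlo noise is far below the
widths being asserted — while the headline replica-plating re-analyses
use $10^5$ platings per grid point.

Two conservatism caveats are documented rather than "fixed". First, the
belt inverts a *discrete* count: when the expected number of sensitive
wells is very small (roughly below 5 — e.g. $q = 0.05$ at any plating
density, or low densities with few populated wells), the attainable
coverage jumps above 95% no matter the simulation budget, exactly as a
Clopper–Pearson interval over-covers at small $n$. Coverage assertions
are therefore made on scenarios with adequately informative expected
counts. Second, the $s = 0$ upper bound is *not* monotone in the
populated count when $\lambda$ is re-estimated from the same plate: a
nearly saturated plate implies many founders per well, and an all-lost
well then becomes weak per-cell evidence (bounds 0.154/0.087/0.082/0.144
for $n = 20/45/71/90$ of 96). The clean monotone-evidence property is in
plate size at fixed density, and that is what the suite asserts.

## Open choices made here

* The published grid ("$10^6$ simulated platings at 0.001 to 10 cells
  per well") does not state spacing or resolution; a log-spaced
  200-point grid is used, because the designs' informative ranges span
  four decades.
* "Accurate estimates" over each design's working range is quantified as
  relative 90% interval width below 1.0; the suite verifies this across
  both stated ranges.
* The per-generation conversion takes the doubling time as an explicit
  argument: converting "17% over 48 h" with the 10.3 h doubling time
  gives 3.9% per generation, and no assumption about the intended
  doubling time is baked in.
* Whether the two plating fractions of a transfection are combined or
  reported separately is left to the caller; the joint fit is the
  default, per-plate fits are one `estimate_efficiency()` call per row.
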