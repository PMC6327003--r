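---
title: "A sequential likelihood for sexual isolation in multiple-choice mating assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequential likelihood for sexual isolation in multiple-choice mating assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esii)
```

## The assay and why order matters

A multiple-choice mating assay places both sexes of two classes of flies in
one chamber — in the standard design, 12 females and 12 males of each class —
and records every copulation in sequence until all flies have mated, over
five replicate chambers (120 matings, 240 flies per assay). The classical
Sexual Isolation Index, `SII = (nho - nhe)/N`, compares homogamic to
heterogamic counts and ignores the order in which matings happened.

Order is not ignorable in this design. Partners are finite: every copulation
removes a female (and, largely, a male) from the pool, so the last pairs are
chosen from whatever the first pairs left behind. If one class of one sex
mates systematically earlier — a faster courtship, a general preference for
that class — the early part of the sequence is enriched for pairs involving
that class and the late part for pairs involving the other. With both sexes
of class A mating early, A×A pairs dominate the start, B×B pairs the end,
and the heterogamic combinations are squeezed into the middle: the naive SII
rises above zero although every individual choice was random. The sequential
model removes this artifact by modelling each copulation conditionally on who
is still available.

## The model

Let `k_c` be the number of matings so far by sex–class `c` in the current
replicate, out of `N_c` individuals. The effective availability of that class
is

$$A(c) = \max(N_c - k_c,\, 0) + r \cdot \min(k_c,\, N_c),$$

with `r` the remating rate of that sex: a mated individual re-enters the pool
down-weighted by `r`. Identities are not recorded in the assay, so
availability is deliberately a function of counts, not of individuals. Each
pair type carries a weight

$$w(f,m) = \frac{1 + h\,[f = m] - h\,[f \ne m]}{2}\; b_f^{[f=A]}\, b_m^{[m=A]},$$

i.e. homogamic pairs get `(1+h)/2`, heterogamic pairs `(1-h)/2`, multiplied
by the order-bias parameters `b_f` (female of class A) and `b_m` (male of
class A). The probability that the next observed copulation is of type
`(f, m)` is

$$P(f,m) = \frac{A_\mathrm{f}(f)\,A_\mathrm{m}(m)\,w(f,m)}
               {\sum_{f',m'} A_\mathrm{f}(f')\,A_\mathrm{m}(m')\,w(f',m')}.$$

The replicate log-likelihood is the sum of log step probabilities along the
observed order, updating the counts after every event; replicates are
independent chambers sharing one parameter triple, so the assay
log-likelihood is their sum. At `h = 0` and unit biases every step
probability reduces to availability-weighted random mating; at `h = ±1`
heterogamic (resp. homogamic) events have probability exactly zero and the
likelihood of a sequence containing one is `-Inf` by construction.

This form was chosen because it pins the interpretable anchor points — `h=0`
is random mating, `h → ±1` complete preference for likes/unlikes, matching
the endpoints of the classical index — and because under symmetric
availability the expected naive SII approximately equals `h`, so the
estimate is readable on the familiar scale. The bias parameters are
per-class multiplicative propensities; a value above 1 can equally reflect a
general preference for that class or a faster mating speed, and the model
does not attempt to distinguish the two readings.

## Parameters, defaults, units

| parameter | meaning | default | domain |
|---|---|---|---|
| `h` | assortative-mating coefficient (eSII) | estimated | `(-1+1e-3, 1-1e-3)` during optimisation |
| `b_female`, `b_male` | order-bias multipliers for class A | estimated | `[0.01, 100]`, optimised on the log scale |
| `r_male` | assumed male remating rate | 0.5 | fixed, `[0, 1]` |
| `r_female` | female remating rate | 0.001 | fixed; numerical smoother only |

`r_male` is a nuisance assumption, not an estimate: in an assay observed to
exhaustion every fly mates about once, and the fitted `h` is nearly invariant
to the assumed rate (see `remating_sensitivity()`), so a mid-range 0.5 is
used by default. `r_female = 0.001` exists only so that female availability
never reaches exactly zero inside the likelihood; realized female remating is
excluded throughout — a replicate ends after `2 * n_females` events, when
every female has mated once.

The null model of the likelihood-ratio test fixes `h = 0` but re-estimates
both biases, so the test has one degree of freedom and asks specifically
whether mating is assortative, not whether order biases exist. An estimate
pinned at the `h` bound — routine for fully isolated assays, where every
observed mating is homogamic — is reported with `boundary = TRUE` and the
LRT is still valid (the null remains interior).

## Numerical choices

Availabilities depend only on the observed sequence and the fixed remating
rates, never on the parameters, so they are precomputed once per dataset;
each likelihood evaluation is then a few vector operations and the gradient
is analytic. Optimisation is bounded L-BFGS-B restarted from a fixed 3×3×3
grid (`h ∈ {-0.6, 0, 0.6}`, log-biases `∈ {-log 3, 0, log 3}`), plus a start
at the null solution so the full fit can never fall below the null;
convergence tolerance is about `1e-8` relative on the log-likelihood, and
the whole fit is deterministic. Degenerate inputs are handled explicitly:
empty datasets are refused; a dataset containing an event that is impossible
under the assumed rates (e.g. a 13th mating by one male class with
`r_male = 0`) yields a fit flagged `converged = FALSE` with `-Inf`
log-likelihoods rather than a silent answer.

## What the simulator emulates — and what it does not

`simulate_assay()` draws sequences from exactly the model above: the same
availability rule for males and hard removal of mated females, stopping at
`2 * n_females` events. Using the generating model for validation makes
parameter recovery a well-posed test; it also means passing simulations show
the estimator is *self-consistent*, not that real chambers obey the model.
Real assays have features the simulator deliberately omits: individual
heterogeneity in attractiveness and eagerness, courtship-duration dynamics,
time-of-day and spatial effects, and simultaneous copulations (the recorder
must break ties before the data enter the package). Two-class designs only.

Simulated study conditions follow the standard assay: 12 + 12 flies per sex,
5 replicates. For studies of the exhaustion regime itself — the order-bias
correction and the remating-sensitivity check — data are generated with a
true male remating rate of 0, because an assay scored until all flies have
copulated yields two flies per mating (240 flies, 120 matings): realized
remating is absent in such data, and a male class that remated in simulation
could not even be evaluated under an assumed rate of 0. Parameter-recovery
and power studies use the general-analysis rate 0.5 for both simulation and
fitting.

The Monte-Carlo suite (`type1_error_study()`, `power_curve()`,
`bias_correction_study()`) uses 1000 simulated assays for null calibration
and 500 per scenario elsewhere, with `h` recovery checked at
`{0, 0.3, 0.6, 0.9}` over 200 assays per point — sizes at which Monte-Carlo
standard errors are small against the tolerances of interest. All studies
take a single integer seed and are exactly reproducible.

## A small demonstration

```{r demo}
design <- assay_design(c("A", "B"))

## random mating, but class-A females and males both mate 3x earlier
biased <- simulate_assay(assay_design(c("A", "B"), r_male = 0),
                         model_params(h = 0, b_female = 3, b_male = 3),
                         seed = 7)
naive_sii(biased)   # inflated although mating is random
esii(biased)        # h estimated near 0, biases near 3
```

```{r power, eval = FALSE}
## power of the order-aware LRT vs the order-blind Fisher test
pc <- power_curve(c(0.15, 0.3, 0.45), design, n_sims = 200, seed = 1)
plot(pc)
```

## Known limitations

- The eSII is reported without a confidence interval; inference is via the
  LRT only.
- The female remating rate is never estimated, and male remating is a fixed
  assumption rather than a fitted quantity.
- With very few events (single short replicate) the chi-square reference for
  the LRT is approximate; the calibration study quantifies the size at the
  standard design, not for arbitrary small assays.
- Bias parameters at their bounds (`0.01` or `100`) indicate a pathological
  sequence (e.g. one class entirely absent from one sex's matings) and
  should be read qualitatively.
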