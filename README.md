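# esii

Order-corrected estimation of sexual isolation from multiple-choice mating
assays.

## The problem

In a multiple-choice assay, females and males of two classes (semispecies,
strains, treatment groups) are placed together in one chamber and every
copulation is recorded in sequence until all flies have mated. The classical
Sexual Isolation Index summarises the pooled counts,

    SII = (nho - nhe) / N

where `nho` is the number of homogamic matings (female and male of the same
class), `nhe` the number of heterogamic matings, and `N` their total. It runs
from -1 (complete preference for unlikes) through 0 (random mating) to +1
(complete preference for likes).

Because the pool of partners is finite and remating is limited, the choice of
the last pairs is conditioned by the choices of the first: if one class of
one sex simply mates *earlier* (faster, or more readily), homogamic pairs
pile up at the start and the end of the sequence and the naive SII signals
assortative mating where there is none. `esii` implements a sequential
conditional-choice likelihood that corrects this. At each observed
copulation, the probability that the next pair is of type (f, m) is

    P(f, m) ∝ A_f(f) · A_m(m) · w(f, m)

where `A_f`, `A_m` are the effective availabilities of each female and male
class (`max(N_c - k_c, 0) + r · min(k_c, N_c)` for a class that has mated
`k_c` times, with remating rate `r`), and the pair weight is

    w(f, m) = (1 + h)/2 · b_f^[f = A] · b_m^[m = A]   for homogamic pairs
    w(f, m) = (1 - h)/2 · b_f^[f = A] · b_m^[m = A]   for heterogamic pairs

Here `h` is the assortative-mating coefficient — the estimated Sexual
Isolation Index (eSII) — and `b_f`, `b_m` are per-class mating-order bias
multipliers. `h = 0` with unit biases is random mating. The triple
`(h, b_f, b_m)` is estimated by maximum likelihood over the observed mating
order (replicates share parameters), with the male remating rate fixed at an
assumed value (0.5 by default; the estimate is insensitive to this choice)
and a near-zero female remating rate (0.001) kept purely as a numerical
smoother. Departure from random mating is tested by a likelihood-ratio test
of `h = 0` against a null that still re-estimates both biases (chi-square,
1 df).

## Worked example

```r
library(esii)

design <- assay_design(c("wt", "kd"))   # 12 + 12 females and males per class
obs <- simulate_assay(design, model_params(h = 0.7, b_male = 2),
                      seed = 42, assay_id = "demo")

naive_sii(obs)
#> naive SII = 0.6667  (homogamic 100, heterogamic 20, N = 120)

fit <- esii(obs)
fit
#> Sequential mate-choice model fit: assay 'demo' (120 events, 5 replicates)
#>   eSII (h)    = +0.6775
#>   order bias  : b_female = 0.866, b_male = 1.559
#>   LRT vs random mating: chi^2(1) = 58.739, p = 1.8e-14
```

The assay was simulated with true `h = 0.7` and a two-fold order bias on
wild-type males. The naive index (0.667) and the model estimate (0.678) both
detect the strong isolation; the fit additionally attributes the early
preponderance of wt-male matings to an order bias (`b_male` = 1.56) rather
than letting it contaminate `h`, and the LRT rejects random mating
decisively. The estimate barely moves under other assumed male remating
rates:

```r
remating_sensitivity(obs, c(0.25, 0.5, 0.75))
#>   r_male     h_hat lrt_stat      p_value converged
#> 1   0.25 0.6764629 58.33647 2.209109e-14      TRUE
#> 2   0.50 0.6775473 58.73933 1.800074e-14      TRUE
#> 3   0.75 0.6784273 59.01286 1.566452e-14      TRUE
```

Monte-Carlo validation tools: `type1_error_study()` (LRT size under random
mating), `power_curve()` (LRT vs Fisher homogeneity test power),
`bias_correction_study()` (spurious naive SII under order bias vs the
corrected eSII), all built on `simulate_assay()`. Observed data come in via
`read_assay()` from delimited text with columns `assay_id`, `replicate`,
`order`, `female_class`, `male_class`. A small command-line wrapper lives at
`inst/cli/esii-cli.R` (subcommands `fit`, `simulate`, `calibrate`).

## Notes

- Two-class assays only; order ranks must be strictly increasing within a
  replicate (ties must be broken by the data recorder — the model conditions
  on a total order).
- Wall-clock times and chamber locations may be present as extra columns;
  they are carried through I/O untouched and never modelled.
- See the methods vignette (`vignettes/mate-choice-model.Rmd`) for the model,
  its assumptions, and the design choices.
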