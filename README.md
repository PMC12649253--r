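# depstate

Multi-state modelling of depressive-symptom dynamics in longitudinal
CES-D panel surveys, with simultaneous per-transition risk-factor
selection by adaptive-Lasso penalized partial likelihood.

## What it does, and for whom

Ageing-cohort panels (CHARLS-style: a 10-item CES-D screen at a handful of
survey waves, plus baseline risk factors) show people moving through
distinct symptom phases: a first **episode**, **persistence**,
**remission**, **relapse**. Epidemiologists want the transition rates
between these states and the risk factors specific to each move — with
many candidate covariates and interactions, and too few events per
transition to fit everything unpenalized.

`depstate` implements that analysis end to end:

* **CES-D scoring** (reverse-scored items 5/8, person-mean fill-in for up
  to two missing items, invalid-wave rule) and **five-state
  classification** with the permissible moves
  `S = {1→2, 2→3, 2→4, 3→4, 4→5}`.
* A **stacked counting-process design**: per-transition records with
  delayed entry, per-path risk sets `R_h(t)`, and coefficient sharing
  across transitions (default: one remission block for 2→4 and 3→4).
* The **estimator**: for each transition `h→g`,
  `λ_ihg(t) = λ0_hg(t) exp(β_hg' X_i)`, fitted by minimizing the
  Breslow-tie stacked negative log partial likelihood plus an
  adaptive-Lasso penalty `Σ λ_hg Σ_r |β_hg,r| / |β̃_hg,r|` (initial
  estimate `β̃` from an unpenalized Newton fit), with per-group BIC
  tuning of `λ_hg`, a KKT certificate on every fit, and post-selection
  Wald inference by unpenalized refit on the active set.
* **Reporting**: transition rate ratios `TRR = exp(β̂)`, 95% confidence
  limits `exp(β̂ ∓ z₀.₉₇₅·SE)`, significance marks (`**` p ≤ 0.001,
  `*` p ≤ 0.05), and onset-age distributions with a 60-year early/late
  split.
* A **seeded synthetic cohort generator** emulating a four-wave national
  ageing survey (covariate marginals, latent continuous-time five-state
  process, wave-censored observation, CES-D emission), so the whole
  pipeline is testable without access-restricted microdata.

## Worked example

The `analysis/` directory runs the demo study as six numbered stages over
`analysis/config.yaml` (3,916 subjects, waves at 0/2/4/7 years, seed 11):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_states.R
# ... through analysis/06_report.R
```

Stage 2 prints the observed event mix:

```
Observed transition events:
  12   23   24   34   45
1489  450  497   53  110
(episodes 1489 | persistence 450 | remission 550 | relapse 110 )
```

— about 38% of subjects have a first episode within 7 years, with roughly
1.2 remissions per persistence event, the regime the generator was
calibrated to. Stage 6 prints the selected effects, e.g.:

```
 block      term     est     se    trr cl_low cl_high sig
 onset residence -0.1682 0.0677 0.8452 0.7401  0.9652   *
 onset      pain  0.2452 0.0586 1.2779 1.1393  1.4334  **
 onset sex_x_age  1.3038 0.0975 3.6831 3.0428  4.4583  **
```

Read: urban residence is associated with a 15% lower episode rate
(TRR 0.85), current body pain with a 28% higher rate, both with
confidence limits excluding 1; the sex×age product absorbs the correlated
sex/age signal, the usual lasso behaviour among collinear columns.

Equivalently in R:

```r
library(depstate)
res <- run_pipeline(list(n_subjects = 2000, seed = 42), out_dir = "demo")
format_effect_table(res$effects)
```

## Layout

```
R/                 package code (generator, scoring/states, design,
                   estimator, reporting, pipeline)
analysis/          numbered stage scripts for the demo study
inst/extdata/      reference effect table (plain CSV)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette (model, assumptions, design choices)
```
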