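# pairguard

Dyadic proximity and mate-guarding analysis from GPS telemetry.

## What it is for

In socially polyandrous, sex-role-reversed shorebirds (the motivating system
is the red phalarope, *Phalaropus fulicarius*), both pair members may benefit
from guarding the mate: the male protects his paternity, the female secures a
care-giving male. With both members of a breeding pair carrying GPS tags at a
10-min fix schedule, mate-guarding intensity is measurable. `pairguard`
implements the full analysis chain for such data:

- **Plausibility filtering** of raw fix streams: fixes > 500 km from the
  capture site, fixes implying > 105 km/h, and single outliers (> 2.5 km from
  both temporal neighbours that are themselves within 100 m), with a per-rule
  audit report.
- **Together classification**: fixes of a dyad recorded within 10 min of each
  other are paired greedily by time gap; a paired observation is *together*
  when its distance is below a dynamic threshold (30 m + 12 m/min × gap), a
  bout is confirmed only if some distance is below the fixed 30 m threshold,
  and a confirmed bout ending > 30 m apart loses its final observation (the
  separating flight is not "together").
- **Separation events**: every together → not-together transition, attributed
  to the member that moved farthest between the bracketing fixes, with
  displacement bookkeeping and a stationary-partner flag (≤ 30 m).
- **Nest attendance**: within 15 m of the nest, or together with a partner
  who is; per-sex daily decomposition into with-mate / alone / away.
- **Random-pair null model**: opposite-sex dyads that did not breed together,
  with ≥ 50% day coverage and at least one together slot, sampled 50 per
  focal day.
- **Clutch-initiation phenology**: a five-channel decision cascade
  (laying back-count, hatch arithmetic with 17/19-day incubation, flotation
  ageing, manual override, male visit onset) plus within-year date
  standardisation and clutch ordering.
- **Mixed models**: beta-binomial (daily proportions), binomial (binary
  together, mover sex) and Gaussian (separation distance) GLMMs with logit
  links, nest-level random intercepts and day slopes (Laplace approximation
  via glmmTMB), automatic dropping of nonsignificant quadratic terms, sine /
  cosine time-of-day terms, and back-transformed marginal means with
  delta-method SEs.
- **A ground-truthed simulator** of paired tracks (correlated random walks
  around shared foraging sites, scripted separation flights, planted filter
  violations, known together / mover / at-nest truth per slot) so that every
  stage is testable without field data.

The central daily quantity is the proportion of paired 10-min slots a dyad is
together,

```
p(pair, day) = together slots / recorded slots,
```

modelled as `cbind(together, n - together) ~ day + day² + season + season² +
(1 + day | nest)` with a beta-binomial likelihood and logit link, fitted
separately for the pre-laying (day −5..−1) and laying (day 0..3) windows.

## Worked example

```r
library(pairguard)

cfg <- sim_config(n_pairs = 12, rng_seed = 1)   # defaults encode the study conditions
run <- run_pipeline(cfg)

print(run$filter_report)
#> Fix filter report: 62208 input; removed 0 (deployment clip), 0 (>dist),
#>   0 (>speed), 0 (single outlier); 62208 retained

round(run$summary, 2)
#> filtered_retention_pct            100.00
#> median_pairing_gap_min              2.39
#> together_prelaying_pct             89.83
#> together_laying_pct                57.26
#> together_post_pct                  10.01
#> together_day0_model_pct            83.44
#> together_day3_model_pct            28.76
#> male_nest_day0_model_pct           19.55
#> male_nest_day3_model_pct           64.42
#> sep_per_pairday_prelaying           2.20
#> sep_per_pairday_laying              4.90
#> female_mover_share_prelaying_pct   44.70
#> female_mover_share_laying_pct      53.19
#> first_nest_visit_mean_day          -3.00
#> phenology_mean_abs_error_days       0.00

run$marginals$together_laying[, c("day_rel", "estimate", "se")]
#>   day_rel  estimate          se
#> 1       0 0.8344019 0.006918523
#> 2       1 0.6847501 0.006816705
#> 3       2 0.4835622 0.007255097
#> 4       3 0.2875653 0.009270372
```

Reading the output: these 12 simulated pairs spent ~90% of paired slots
together in the five days before the first egg and only ~10% after laying
(like random dyads), the back-transformed model means fall from 83% on the
first laying day to 29% on the last, males rose from ~20% to ~64% of slots at
the nest over the same days, and females made ~45% of the separating moves
before laying — the generator's configured season, recovered end to end
through filtering, pairing, classification and model fitting. With your own
data, pass `fixes` and `nests` tables (see `read_fixes_csv()`,
`read_nests_csv()`) instead of simulating.

A thin command-line wrapper ships in `inst/scripts/pairguard.R`
(`simulate`, `filter`, `run` subcommands).

## Documentation

The methods vignette (`vignettes/mate-guarding-methods.Rmd`) documents the
classification rules and their boundary conventions, the model families and
the random-effect fallback ladder, the simulator's design (and what it
deliberately does not emulate), and the numerical choices.
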