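---
title: "Quantifying mutual mate guarding from paired GPS tracks: methods and design"
author: "pairguard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutual mate guarding from paired GPS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In socially polyandrous, sex-role-reversed shorebirds such as the red
phalarope (*Phalaropus fulicarius*), females compete for care-giving males and
males risk paternity loss, so both pair members may benefit from staying close
to the mate. With miniaturised GPS tags scheduled at one fix per 10 minutes on
both members of a breeding pair, mate-guarding intensity becomes measurable
as (i) the proportion of time the dyad is "together", (ii) who performs the
movements that separate the pair, and (iii) how this trades off against nest
attendance as laying progresses. `pairguard` implements that analysis chain —
from raw fix streams to mixed-model summaries — together with a simulator of
paired tracks whose ground truth is known, so every classifier can be scored.

# Pipeline and conventions

## Plausibility filtering

Raw fixes are clipped to the deployment interval (closed on both ends) and
then filtered by three rules, in this order:

1. **Distance**: fixes strictly farther than 500 km from the capture site.
2. **Speed**: a forward scan per individual removes any fix whose arrival leg
   from the previous *retained* fix implies a speed strictly above 105 km/h,
   the fastest speed observed in a continuous track.
3. **Single outliers**: an interior fix strictly farther than 2.5 km from both
   temporal neighbours when those neighbours are within 100 m of each other.

All thresholds are strict (`>`), matching the wording they derive from. The
order matters in principle (a distance outlier would otherwise trigger the
speed rule); it is fixed as above. The speed rule is a sequential forward
scan — the simplest deterministic reading of "implied a faster speed" — so a
burst of bad fixes is removed one by one against the last good position.
Duplicate timestamps within an individual are rejected as a data error rather
than silently averaged. `run_filters()` is idempotent and reports one count
per rule; the conservation identity
`n_retained = n_input - sum(removed)` is enforced by construction.

Great-circle (haversine) distances are used for the two multi-kilometre rules.
All sub-kilometre geometry — together thresholds, displacement, nest radii —
is computed in a site-centred azimuthal equidistant projection (hand-coded
spherical forward/inverse; no PROJ library is required). At study-area scale
(a few km) the two metrics differ by far less than the GPS noise.

## Pairing fixes and classifying "together"

The two members' fixes are matched one-to-one, greedily by ascending time
gap, with a hard cap of 10 min; unmatched fixes yield no observation.
Distances are evaluated at the matched fix pair.

Three rules label each paired observation:

1. *Candidate*: the distance is strictly below a **dynamic threshold**
   `30 m + 12 m/min × gap`. The allowance term absorbs movement that can
   happen during the time gap between the two fixes. The linear form and the
   12 m/min default are package choices (the rate is a `together_params()`
   field); this is the main place where a different, equally defensible
   functional form could change labels near the boundary.
2. *Bout confirmation*: a maximal run of candidate observations counts as a
   together bout only if at least one distance in it is strictly below the
   fixed 30 m threshold; otherwise the whole run is labelled not-together.
   This removes runs of mid-range distances that merely drift under the
   dynamic threshold at large gaps.
3. *Final-fix rule*: if the last observation of a confirmed bout is strictly
   more than 30 m apart, it is relabelled not-together — the separating
   flight itself is not "together". A final distance of exactly 30 m stays
   together (both comparisons are strict).

Daily proportions divide together slots by recorded slots per local civil day
(UTC−8; under 24-h arctic daylight no activity gap anchors the day, so civil
time is the only defensible convention). Days are indexed relative to clutch
initiation (first-egg day = 0).

## Separations, nest attendance, null pairs

A separation event is every together → not-together transition between
consecutive paired observations. Each member's displacement is the
straight-line distance between its own two fixes bracketing the transition;
the mover is the member with the strictly larger displacement. Exact ties are
recorded as `"tie"` and excluded from mover-sex models (ties have probability
zero under continuous noise; the case is handled for completeness). The
partner counts as stationary when it moved at most 30 m. A 10-min interval
can of course mis-attribute a mover that doubles back unseen; no correction
is attempted.

A member is **at the nest** when its own position is within 15 m of the nest
(inclusive) or when it is together with its partner and the partner is within
15 m; the rule is applied one step only (no transitive propagation). Daily
attendance decomposes exactly into "at nest with mate" plus "at nest alone",
and "alone away" counts slots neither together nor at the nest. Proportions
are over recorded slots, treating missing slots as missing at random.

Random (null) pairs are opposite-sex dyads that did not breed together, with
at least 50% of a day's slots paired and at least one together slot somewhere
in their record (dyads that never met are not an informative baseline). Up to
50 dyads are sampled uniformly without replacement per focal day; when fewer
qualify, all are taken with a warning (take-all avoids duplicate weighting).

## Clutch initiation dates

`estimate_clutch_initiation()` applies a fixed priority cascade: a manual
override from reliable field observations wins; then back-counting for nests
found during laying (`discovery − (eggs − 1)`, one egg per day with the first
egg on day 0); then hatch-date arithmetic (`hatch − (clutch size − 1) −
incubation`, 17 d for incubator-hatched and 19 d for naturally incubated
clutches, both configurable); then flotation ageing
(`discovery − age − (eggs − 1)`); and finally the male's first sustained
nest-visit day used as-is. The egg-count convention deserves a note:
"subtract one day per egg" is read as `− (eggs − 1)` because the literal
`− eggs` would date a one-egg nest to the day before its only egg existed.
Diverging evidence channels (> 3 days) produce a warning naming the method
used. Initiation dates are standardised by subtracting the within-year mean,
and a female's clutches are ranked first/second/third by date.

## Mixed models

Daily proportions are modelled with beta-binomial GLMMs (logit link), binary
responses (together at a slot; female-made separation) with binomial GLMMs,
and separation distances with Gaussian models, all with nest-level random
intercepts and day-relative slopes (unstructured 2×2 covariance) fitted by
Laplace-approximated maximum likelihood via `glmmTMB`. Quadratic terms for
day and season are fitted first and dropped when their Wald p ≥ 0.05 (one
refit, deterministic). Time of day enters slot-level models as
`sin(2πh/24)` and `cos(2πh/24)`.

Fits are accepted when the fixed-effect standard errors and a
population-level prediction SE are finite; `pdHess` alone is deliberately not
the criterion, because data at the binomial boundary push the beta-binomial
dispersion to infinity and flatten the Hessian in that direction without
harming fixed-effect inference. When a structure fails, the model falls back
deterministically: unstructured slope → diagonal slope → random intercept →
no random effects, each step logged. Effect sizes are reported back-
transformed with delta-method standard errors, random effects at zero.

# The synthetic-data generator

The generator's defaults encode the study conditions the analysis targets:

* ~10-min fixes with a between-member schedule offset drawn from a
  light-tailed Weibull (shape 3.5) plus ±0.5 min per-fix jitter, calibrated
  so pairing gaps have median ≈ 2.6 min and ~95% fall below 5 min;
* daily together probabilities 0.80 (days −7..−6), 0.90 (days −5..−1),
  then 0.84 / 0.69 / 0.48 / 0.28 across laying days 0–3 (the two interior
  days interpolate days 0 and 3 linearly on the logit scale) and 0.10
  afterwards;
* ~1.9 separations per day before laying and 4.6 during laying, with the
  female as the scripted mover with probability 0.45 (pre-laying) and 0.52
  (laying);
* log-normal separation flights (median 160 m, log-SD 0.6);
* male nest attendance rising 0.05 → 0.10 over days −3..−1 and 0.20 → 0.66
  across laying days 0–3, then 0.85 (incubation); female attendance peaks
  around laying onset;
* GPS noise of 5 m per coordinate, and optional planted corruptions
  exercising each filter rule.

Movement is a two-state process on a 1.6 km square plot (mirroring a
2.5 km² tundra study plot). While together, both members sit within a few
metres of a shared centroid that performs a correlated random walk (gamma
step lengths, wrapped-normal-style turning) confined to one of six shared
foraging sites, switching sites occasionally. Cross-pair co-visits of these
shared sites are what give random non-breeding dyads their nonzero "together"
baseline (roughly occupancy²/sites ≈ 0.1 before laying) — the null model sees
honest co-location, not planted labels.

Separations are scripted: per pair-day the number of together slots is a
binomial draw of the day's probability (so realised daily fractions are
exactly binomially calibrated around the configured truth), arranged into
bouts with a Poisson number of transitions; every together → apart
transition in the season-long sequence is assigned a mover. The mover flies
a log-normal distance while the partner holds position, giving unambiguous
attribution truth.

Three geometric guards keep the planted truth identifiable at a 10-min fix
interval, and are deliberate idealisations:

* flight lengths are floored at 120 m — a shorter displacement cannot be
  distinguished from joint movement under the dynamic threshold, so a
  scripted "separation" of 40 m would be a contradiction in terms;
* while apart, the mover is kept at least 120 m from its partner, and
  members of a currently-apart pair avoid each other's foraging site when
  relocating;
* while apart, only one member sits on the nest at a time (male priority) —
  two birds on the same scrape would de facto be together.

When the pair is together, the male's attendance draw decides whether the
pair is at the nest (males build and guard the nest), so measured male
attendance tracks its configured schedule exactly, while female attendance is
partly emergent from time spent together.

What the generator does **not** emulate: movement *within* the pairing gap
(both members' true positions are sampled at the slot state, which is exactly
the situation the dynamic threshold exists to absorb in real data — the
threshold is therefore exercised by asynchronous timestamps, not by real
displacement); continuous flight paths; tag failure and download gaps;
within-day attendance bout structure (per-slot attendance is i.i.d. given the
day); and behavioural interactions between pairs. Passing recovery tests on
these tracks therefore demonstrates that the estimators are unbiased under
the stated sampling design, not that field data are free of the ambiguities
the generator sidesteps (short flights, joint flights between sites, and
half-interval tag asynchrony all produce label noise in real data, as the
final-fix rule acknowledges).

With the optional diurnal mode (`diurnal_amplitude > 0`), slot states are
drawn independently with probability `p(day) − A·cos(2πh/24)` (peak at local
midday), trading bout realism for a clean planted time-of-day signal.

# Numerical choices

* Strict inequalities everywhere a rule says "more than" / "smaller than";
  the at-nest radius ("within 15 m") is inclusive.
* The speed filter's boundary is `>` 105 km/h; a leg at exactly the limit is
  kept.
* Greedy gap-ascending pairing breaks ties by input order, making the
  matching deterministic.
* `glmmTMB` is run with its default optimizer and starting values; fits are
  deterministic given the data. Reported agreement with closed forms (OLS,
  contingency-table log odds) is limited by the optimizer's convergence
  tolerance (~1e−5 relative), not by the model definition.
* Every stochastic step — simulation, null-pair sampling, evidence
  generation — derives from a single integer seed; identical configuration
  and seed reproduce byte-identical outputs.

# Problem sizes used by the tests

The test-suite season is 40 pairs × 18 days (−7..10) at 144 slots per day —
around 207,000 fixes — which gives binomial standard errors small enough to
detect a 5-point bias in any daily mean while keeping a full run around a
minute. The Laplace-vs-quadrature check uses 10 nests with deep per-nest
sampling (800 days) because it verifies that the two likelihood computations
target the same value; at small per-nest sizes the difference is dominated by
the Laplace approximation error itself (~2×10⁻³ log-units per nest at 16
observations), which is a property of the approximation, not a defect of
either implementation. The quadratic-drop type-I check uses 500 simulations
of n = 400, where the Wald z test's small-sample liberality (ML variance,
normal reference) is negligible.

# Known limitations

* Mover attribution inherits the 10-min resolution: movements within an
  interval are invisible, and the simulator's scripted movers make the
  planted-truth accuracy an upper bound on what field data allow.
* The dynamic threshold's functional form is a configurable linear rule; if
  an authoritative form differs, `gap_allowance_rate` (and the base) can be
  recalibrated without touching the classifier.
* The null-pair baseline in the simulator is driven by shared-site occupancy
  and falls after laying (males sit on nests), whereas field baselines stay
  near 10% year-round; comparisons of breeding vs. random pairs in the
  post-laying window are therefore conservative in simulation.
* Method 5 for clutch initiation (male visit onset) is used as-is and is the
  coarsest channel; it exists so that field evidence tables round-trip, not
  as a recommended estimator.
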