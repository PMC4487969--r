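---
title: "Hut-trial endpoints, wash-resistance cut-offs and trial simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hut-trial endpoints, wash-resistance cut-offs and trial simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huttrial)
```

## The setting

Experimental huts are the standard Phase-II instrument for evaluating
insecticide-treated nets (ITNs) under field conditions: wild, free-flying
mosquitoes enter verandah-trap huts overnight, a volunteer sleeps under
the test net, and each morning the catch is scored by location (room,
verandah trap, window trap), gonotrophic status (fed/unfed) and survival
at 24 h. Treatments rotate through huts in a Latin square so that hut
position, sleeper attractiveness and individual nets do not confound the
treatment effect. This package implements the full analysis chain for such
trials, calibrated against a 2008 Tanzanian evaluation of a long-lasting
lambda-cyhalothrin treatment kit (ICON Maxx) run in Muheza (36 nights,
*An. funestus* and *An. gambiae*) and Moshi (24 nights, *An. arabiensis*)
with five arms: untreated net, the long-lasting treatment unwashed and
washed 20 times, and a conventionally treated net (CTN) washed to its
cut-off or 20 times.

## Data model

The atomic observation is a hut-night: arm, hut, sleeper, night, period,
species, and twelve counts cross-classifying feeding status x survival x
location (`hut_count_cells()`). Two conventions are baked into the schema:

* **Gonotrophic collapsing.** Field scoring distinguishes unfed,
  blood-fed, semi-gravid and gravid females, but the analysis operates on
  a binary fed/unfed axis; semi-gravid and gravid females (which have
  necessarily fed) count as fed. The schema stores the collapsed axis.
* **Mortality axis.** Immediate and 24-h delayed mortality are pooled into
  one dead/alive-at-24 h axis, matching how trial tables report "total
  dead".
* **Missing cells are errors**, never zeros: a silent zero would mask a
  collection gap.

`aggregate_arms()` reduces records to the arm-level totals `T`, `K`, `B`,
`E` on which every endpoint is defined; "exited" pools verandah and window
traps.

## The endpoints

For treated (`t`) vs untreated control (`u`) arms:
deterrence `100(Tu−Tt)/Tu`; exiting `100E/T`; Abbott-corrected mortality
`100(pt−pu)/(1−pu)`; overall killing effect `100(Kt−Ku)/Tu`; blood-feeding
inhibition `100(1−(Bt/Tt)/(Bu/Tu))`; personal protection `100(Bu−Bt)/Bu`.

Design choices that required a decision:

* **Abbott's correction** is used for "mortality corrected for control".
  The source tables do not print the formula; applied to the published
  counts Abbott's form reproduces 13 of 15 printed cells to the printed
  decimal (the two *An. funestus* deviations of 0.1 are rounding), while
  the plain difference `100(pt−pu)` does not.
* **Truncation at zero** for reporting, with the signed value retained in
  `*_raw` columns. Published tables print "0" where a treated arm caught
  more than the control; discarding the sign entirely would make the
  tables non-invertible for simulation calibration.
* **Rounding is half-up** to one decimal for rendered tables
  (`round_half_up()`); base R's half-to-even would disagree with printed
  values such as 93.8.

### Known inconsistencies in the reference tables

Applied to the published counts, the defining formulas disagree with ten
printed cells, which the test suite therefore excludes from the
reproduction check (all other ~80 cells match exactly):

* the four *An. gambiae* killing-effect cells (printed 30.4/25.3/19/39.2
  vs computed 24.7/20.6/15.5/32.0 — the printed values match a denominator
  of 79, the control *exiting* total, instead of the control catch of 97);
* two *An. funestus* corrected-mortality cells off by 0.1 (rounding);
* three CTN-cut-off-arm cells (*An. funestus* killing effect 34.5 vs 36.5
  and personal protection 49.2 vs 49.4; *An. gambiae* blood-feeding
  inhibition 11.3 vs 11.4);
* the *An. gambiae* CTN-cut-off exiting percentage (98.3 vs 56/57 = 98.2).

The implementation follows the printed formulas, not these cells.

## Wash-resistance cut-off

The "point of insecticide exhaustion" is the smallest wash number at which
the net causes **less than 80 % mortality or less than 95 % knockdown** in
WHO cone bioassays (ten replicates of five susceptible females, 3-min
exposure, knockdown at 60 min, mortality at 24 h) conducted after each
wash. `determine_cutoff()` implements exactly this first-failure rule;
percentages pool replicates. Notes:

* The reference trial describes the CTN "washed three times" as the
  standard reference while also stating mortality first fell below
  threshold *at* four washes; the first-failure definition (returning 4)
  is implemented, as it is the verbatim cut-off rule. Similarly the
  long-lasting treatment's cut-off is reported as 26 washes in one place
  and 27 in another; the rule returns 26 on a series crossing at 26.
* A series that never fails returns `NA_integer_` ("not reached"), not an
  error: strong candidates are expected not to exhaust within 20 washes.
* Knockdown enters the criterion only when it was scored; mortality-only
  series are accepted with a warning.
* An optional percentile bootstrap (`cutoff_bootstrap_ci()`, resampling
  replicates within washes under a fixed seed) quantifies the cut-off's
  sampling noise; resamples that never fail are censored above the largest
  wash tested.

Tunnel tests (`tunnel_summary()`) use the number released as denominator
for penetration, feeding and mortality. Chemistry reduces to the retention
index (`retention_index()`): percent of the initial mg AI/m^2 remaining,
with retained + removed = 100 exactly. The published chemistry is
internally inconsistent at the +/-3 % level for the long-lasting
treatment's 20-wash removal (48.5 % in the text vs 51.4 % from the
concentration table vs 51.5 % quoted elsewhere), so those figures are not
used as tests; the CTN figures (98.5 % removed by 20 washes, 3.8 %
remaining at cut-off) are consistent and are.

## Arm-wise inference

Proportional outcomes (mortality, blood-feeding, exiting) are compared by
logistic regression on the per-hut-night binomial outcomes with arm,
sleeper and hut as fixed effects — equivalent to an individual-mosquito
logistic model with those covariates. Pairwise contrasts are Wald tests
from the single fitted model, unadjusted for multiplicity by default
(trial reports quote raw p-values; Holm adjustment is a flag). When an
arm pair's pooled 2x2 table contains a zero cell the Wald contrast is
unreliable and that pair falls back to Fisher's exact test, flagged in the
output. Night is not a default covariate, matching the trial's stated
adjustment set (sleepers and hut position only); it can be added.

Counts (entries, blood-fed, dead per hut-night) are compared on a
log-linear mean model with the same covariates. The named family for such
analyses is negative-binomial regression; however, with trials of this
size (24-36 nights, i.e. ~50 hut-nights per species) the maximum-likelihood
dispersion is noisy and Wald z contrasts from `glm.nb` rejected a true
null in 9 % of 200 seeded replicates in this package's calibration study.
The contrasts therefore use the moment (Pearson) dispersion estimate with
a t reference on the residual degrees of freedom (quasi-likelihood),
which held 5.5 % measured size under the same nulls; the NB `theta` is
still estimated and reported. An arm with zero-variance counts makes any
dispersion estimate degenerate and triggers a plain-Poisson fallback with
a warning. The unit-of-analysis question (individual mosquito vs
hut-night) is unstated in the reference; hut-night totals with covariates
are used, which for the binomial model is likelihood-identical to the
individual-level model.

**Letter groupings.** Table superscripts follow the convention that arms
sharing a letter do not differ significantly. `letter_grouping()` uses the
insert-and-absorb algorithm, which guarantees the defining iff-property
(share a letter ⇔ p >= alpha); greedy absorption keeps the letter count
small without guaranteeing the minimum. The test suite brute-force
verifies the iff-property on every generated matrix.

## Rotation designs

`generate_rotation()` produces a row-randomised cyclic Latin square (arms
x huts, one row per period), nightly cyclic sleeper rotation, and a net
replicate index cycling every two nights (two to three nets per arm, each
tested two nights per period). One washout night between periods is
recorded as metadata, not as an analysis night. The reference trials ran
longer than one exact rotation (36 nights at 6-night periods with 5 arms =
6 periods); `n_periods` beyond `n_arms` appends extra periods re-using the
square's rows cyclically, and the strict Latin invariants are validated on
the core square. With 5 sleepers and 4-night periods a sleeper cannot
visit every hut within one period, so sleeper coverage is validated over
the whole plan and reported as a warning, not an error.

## The simulator

`simulate_trial()` draws, per hut-night, entries ~ NegBin(mean
`mu (1−d) h s`, size `k`) with log-normal hut/sleeper effects `h`, `s`,
then per mosquito three Bernoulli outcomes (death `m`, feeding `f`,
exiting `e`) via a latent Gaussian copula (correlation `rho`, default 0 =
independent), and bins the results into the twelve cells; exiting
mosquitoes split evenly between verandah and window traps. Everything
derives from one seeded RNG stream, so output is byte-identical per seed.

Defaults mirror the observed structure of the reference control arms:
`mu` is set per study (20.1/night for the Moshi calibration), control
feeding 27 %, exiting 81 %, mortality 3.1 %; `k = 5` reflects the
overdispersion typical of nightly hut catches (the variance of observed
nightly catches is several times the mean; a Poisson model would
understate between-night noise). Independence of the three outcomes is an
explicit simplification — trials publish the joint categories but no
dependence structure — and `rho` exists to probe its consequences.

`params_from_endpoint_table()` inverts the endpoint formulas back to
generative probabilities (using the `*_raw` columns; an endpoint truncated
to 0 with its raw value lost is an explicit inversion-ambiguity error),
and `expected_endpoints()` gives the implied expectations, enabling
end-to-end parameter-recovery studies. Deterrence is deliberately signed,
in (−1,1) rather than [0,1): the reference tables themselves contain arms
that attracted more mosquitoes than the control, and a signed deterrence
is required to invert them.

### What the simulations show — and what they do not

The `analysis/` drivers run the studies at stated sizes: 100 seeded
two-arm trials at the Moshi calibration (24 nights, 4-night periods,
`mu = 20.1`, `k = 5`, effect scales 0.25) for parameter recovery, the same
geometry over 200 seeded null replicates for size (proportions at
`mu = 420`, about 10^4 mosquitoes per arm; counts at `mu = 20`), and 30
trials at 240 nights for the consistency check. Passing these shows the
estimators and tests behave correctly **under the generative model** —
independent outcomes, log-normal multiplicative effects, NB entries. Real
hut data can violate all three (behavioural correlation between feeding
and death, night-by-night weather, trap-dependent scoring); the
calibration results do not certify performance under such violations,
only that the machinery is internally sound.

## Degenerate inputs and numerical conventions

Undefined endpoints (control catch 0, control mortality 100 %, no control
feeding) raise errors rather than returning NaN. Validation failures are
collected into reports (rule, locator, severity) rather than thrown
piecemeal; coverage gaps warn, structural violations fail. Ties in the
cut-off rule cannot occur (strict inequality against the thresholds, per
the verbatim definition). Reported tables round half-up at the last step
only; machine outputs carry full precision.

## Limitations

* Counts only — no individual-mosquito covariates (age, parity).
* Fixed-effects adjustment only (no random hut/sleeper effects), matching
  the reference analysis plan.
* No epidemiological extrapolation from endpoints to transmission.
* The records fixture is a deterministic reconstruction from published
  arm-level totals: its marginals (and hence all endpoint values) are
  exact, but its per-night spread is artificial, so per-night inference on
  it is illustrative, not a reproduction of the original regression
  p-values (which depend on unpublished per-night data).
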