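---
title: "Quantifying resource defense and monopolization from RFID feeder detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying resource defense and monopolization from RFID feeder detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feederdefense)
```

## The problem

Territorial nectarivores such as hummingbirds defend concentrated food
sources, but in the wild the same individuals also range over many sources,
and competitors differ in number, and habitats in visibility. When a
population is marked with passive integrated transponders (PIT tags) and
every feeder carries an RFID antenna logging one reading per second, the
joint use of a whole grid of feeders by all marked individuals becomes
observable. `feederdefense` implements the analysis chain for such data:

1. **Sessionization** — per-second readings are merged into visits;
2. **Space-use indices** — daily and seasonal spatial concentration,
   spatial stability, plus day- and feeder-level control covariates;
3. **Permutation null models** — are individuals more concentrated, and
   feeders more dominated, than random use would produce?
4. **Mixed-model multimodel inference** — how do space use, competition,
   food quality and visibility shape the number of visits by competitors
   (NVC) at a feeder a focal individual may be defending?

Because raw field detection streams of this kind are rarely public, the
package also ships an individual-based simulator that generates detection
streams with known territorial structure, and a generative twin of the
fitted mixed model. All validation in the test suite runs against these
known ground truths.

## Sessionization

Readers scan once per second, so a bird sitting in the antenna produces a
run of readings; brief hops off the perch and occasional missed scans break
the run. Two consecutive readings of the same tag at the same feeder less
than 21 s apart belong to the same visit (`detections_to_visits()`, strict
`<`, so a 21-s gap splits). Choices a user should know about:

* The gap is measured between *consecutive reading timestamps* (end of the
  run so far to the next reading), not start-to-start.
* Duration counts inclusive seconds: a single reading is a 1-s visit.
* A visit spanning midnight belongs to the calendar day of its start.
* Exact duplicate readings are dropped with a warning, so reader chatter
  cannot inflate `n_readings`; the conservation invariant
  (sum of `n_readings` = number of unique input readings) is tested.

Raising the threshold can only merge visits, never split them; this
monotonicity is also tested. Note one subtlety: collapsing a visit to its
first and last reading and re-sessionizing returns the identical visit set
only for visits shorter than the threshold — a 30-s visit's endpoints are
themselves ≥ 21 s apart. The property test is restricted accordingly.

## Space-use indices

For individual $i$, feeder $f$, day $d$, with $v_{ifd}$ visits:

* **Spatial concentration** $C_{ifd} = v_{ifd} / \sum_{f'} v_{if'd}$, the
  share of the day's visits made at $f$. Shares sum to 1 over feeders
  within a bird-day.
* **Seasonal concentration** is the same share over the individual's whole
  followed period (within a year).
* **Spatial stability** is the Pearson correlation between daily and
  seasonal concentration, paired over every (feeder, day) combination where
  the feeder is one the individual visited at least once that season; days
  on which a feeder was skipped contribute daily zeros. Those zeros are
  information — dropping them would make any day look like the seasonal
  pattern. Stability needs at least 3 followed days, and is reported as
  computed (it can in principle be negative; we do not clamp to $[0, 1]$,
  because silently altering a covariate is worse than an occasional
  negative fidelity). A bird using a single feeder all season has a
  zero-variance seasonal vector; its stability is flagged undefined and
  the bird is excluded from modelling.
* **Grid usage** is the mean daily visit total across the individuals that
  used the grid that day (a weather/phenology control).
* **Feeder rank** orders feeders, within year, by the number of distinct
  individuals of the competitor sex detected at least once; rank 1 has the
  most, ties take average ranks, never-visited feeders rank last.

The analysis table (`assemble_analysis_table()`) has one row per (focal,
feeder, day). Focal individuals are adults of the focal sex followed on ≥ 3
distinct days; NVC sums the same-day visits at that feeder by *other*
adults of the competitor sex (all adults count as competitors regardless of
days followed; juveniles never do, as they appear only briefly late in the
season). Feeder-days where the focal is the only individual detected carry
no information about exclusion — an empty feeder more likely reflects low
attractiveness than perfect defense — and are dropped, which also
guarantees $\mathrm{NVC} \ge 1$ so the log response is defined.
`n_competitors` counts the distinct competitor-sex adults at the feeder-day
*excluding* the focal (whether the original analysis included the focal in
this count is ambiguous; excluding it reads "number of individuals detected"
relative to the focal, and only shifts the covariate by a constant 1).

## Permutation null models

Two randomization procedures, each with `n_rep` (default 100) replicates:

* `null_concentration()`: observed statistic = mean over bird-days of the
  concentration at the bird-day's most-visited feeder; each replicate
  reassigns every visit of each bird-day independently and uniformly among
  the feeders that bird visited that day.
* `null_dominance()`: observed = mean over feeder-days of the top
  visitor's count; replicates reassign each feeder-day's visits uniformly
  among that day's visitors.

"Randomly assigning" is implemented as an independent uniform multinomial
over the visited (visitor) set — a permutation of the fixed count vector
would leave the statistic unchanged and make the null vacuous. Totals are
conserved in every replicate. P-values use the add-one convention
$(1 + b)/(n_\mathrm{rep} + 1)$, so an observed value above all 100
replicates reports $P \approx 0.0099$, never zero. Both tests condition on
the *observed* visited set; the type-I calibration study in the test suite
therefore simulates uniform use at high daily rates (Poisson mean 30 over a
shared 4-feeder repertoire, no day-level overdispersion), where the
probability that a used feeder shows zero visits — the one way the
generative process and the conditional null can disagree — is negligible
($\approx e^{-7.5}$ per cell). Under that regime the observed statistic
falls inside the central 95% of its null about 95% of the time.

## The mixed models

The response is $\log(\mathrm{NVC})$ (natural log; the base is a
convention and only rescales coefficients). Ten candidate models share five
control main effects (year, grid usage, number of competitors, feeder rank,
sucrose treatment) and differ in the focal's space-use terms, habitat
visibility terms, and their interactions with spatial concentration
(`build_model_set()` prints the full structure); model 10 carries all 15
terms. Every model has a feeder random intercept and a correlated
individual random intercept and spatial-concentration slope — the random
slope *is* the individual variation in defense. Fitting uses `lme4::lmer`;
numeric covariates stay on their raw scales and factor references are
year 2007 (earliest), low sucrose, closed habitat.

The three-way visibility interaction is parameterized as separate
concentration × lateral-visibility slopes within each openness level
(`spatial_concentration:opennessclosed:lateral_visibility` and
`...open...`), because the scientific expectation differs by habitat:
visibility should aid defense in closed forest, while birds in openings
overlook their feeder from high perches regardless.

Model selection and averaging follow the information-theoretic standard:

* $\mathrm{AICc} = -2\ell + 2K + 2K(K+1)/(n-K-1)$ computed from the
  **maximum-likelihood** fits. $K$ counts fixed effects + 4 random-effect
  (co)variance parameters + the residual variance — a *marginal* AIC, since
  the candidate set compares population-level fixed structures
  (a conditional AIC, with effective degrees of freedom for the random
  effects, answers a different, prediction-oriented question).
* Akaike weights $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$.
* Averaging uses the **REML** coefficients with zero substitution over the
  full set ($\theta_i = 0$ where a term is absent), because a single
  coefficient per term is reported across a set in which some terms appear
  in few models; natural averaging (renormalizing over containing models)
  is available via `average = "natural"`. The unconditional standard error
  is $\sum_i w_i \sqrt{\mathrm{se}_i^2 + (\theta_i - \bar\theta)^2}$ and
  intervals are $\bar\theta \pm 1.96\,\mathrm{SE}$ (normal multiplier,
  which reproduces published bounds from published coefficient/SE pairs).
* Fits that fail to converge or end singular are flagged, dropped from the
  average, and the weights renormalized with a warning. Terms involving a
  factor constant in the data (e.g. year in a single-season run) are
  dropped per model with a message — they are inestimable, and $K$ reflects
  the drop.

Per-individual defense is summarized by `blup_slopes()`: the averaged fixed
concentration slope evaluated at the data means of the interacting numeric
covariates (factors at reference) plus the individual's model-averaged
random-slope BLUP, expressed as the percent NVC reduction when
concentration goes from 0 to 1, $100\,(1 - e^{\mathrm{slope}})$.
`random_slope_support()` reports $\mathrm{AICc}_{\text{no slope}} -
\mathrm{AICc}_{\text{slope}}$ for the full model, the evidence that defense
capacity varies among individuals.

## The simulator

`simulate_population()` / `simulate_visits()` / `simulate_detections()`
generate detection streams with known structure on the 45-feeder grid (two
rows of 12 and three of 7, 100 m spacing, 8 hayfield / 6 fallow / 31 forest
feeders, all open-land feeders plus 14 forest feeders in canopy openings).
Ground-truth parameters per bird: daily rate $\lambda$, fidelity $\kappa$,
defense $\beta$, home feeder, tenure.

* **Allocation.** Each bird draws from a repertoire of its home feeder plus
  the nearest neighbours (default 6 feeders). Long-run weights are
  proportional to feeder attractiveness (habitat multipliers; ×1.5 when a
  feeder holds the 35% sucrose treatment) times $(1 + \kappa)$ at home.
  $\kappa = 0$ is uniform use of the repertoire; $\kappa \to \infty$ puts
  every visit at home. Day-to-day wobble comes from a Dirichlet around
  those weights (`day_concentration`, default 40; `Inf` disables it), and
  the day's visit count is Poisson with mean $\lambda$ scaled by the home
  feeder's multipliers.
* **Defense thinning.** At each feeder-day the top user's *pre-thinning*
  daily concentration $C$ there is computed (using realized, pre-thinning
  counts avoids a circular definition); every other bird's visit is
  retained with probability $e^{-\beta_\mathrm{top} C}$. With all
  $\beta = 0$ no visit is removed.
* **Timing and readings.** Visit durations are log-normal (median 8 s,
  shape 0.6 — strictly positive and right-skewed; no duration distribution
  is available from field reports, so this is a modelling choice). Visits
  are laid into a 05:00–21:00 activity window with at least 25 s between a
  bird's consecutive visits, so generated visits remain distinct under the
  21-s merge rule and the generator's visit count is identifiable. Each
  visit expands to per-second readings with independent dropout (default
  0.05) on interior seconds only: endpoints are never dropped and any
  dropout run long enough to split a visit is repaired, so sessionization
  recovers the generated visits exactly — which is what makes the
  sessionizer testable against ground truth.
* **Scale.** Defaults emulate one breeding season: 103 days from 20 May,
  55 individuals (60% male, 12% juvenile), male tenures of roughly
  38 ± 22 days and female 21 ± 16, and the 2009-style randomized-block
  sucrose schedule (three 3-week blocks from 10 June; 15 of 45 feeders high
  each week; every feeder high exactly once per block).

What the simulator does **not** emulate: spatially explicit flight between
feeders, weather, juvenile influx dynamics, unmarked birds, antenna
efficiency varying among feeders, or within-day behavioural rhythms beyond
the activity window. Passing tests therefore show that the pipeline
recovers the structure this generative model encodes — not that the model
is a complete description of field data.

`simulate_nvc_design()` and `simulate_nvc_table()` are the generative twin
of the mixed model itself: a covariate table at field scale (by default
15,037 rows, 88 individuals, 45 feeders — the scale of the original
male–male analysis) and a log-scale response drawn as fixed linear
predictor + feeder intercept + correlated individual intercept/slope +
residual. The recovery study in the acceptance tests fits the full model to
100 such tables (published coefficient values as truth; variance components
0.04 / 0.09 / 0.25 / −0.03 / 0.49) and verifies absolute bias < 0.05 and
≥ 90% CI coverage for every fixed effect. Problem sizes for the
quicker checks (3,000-row tables, 40 individuals for the random-slope
support study; 5 and 3 replicates under zero and strong slope variance)
were chosen as the smallest designs at which the expected effects are
unambiguous.

## Worked example

```{r example, eval = FALSE}
library(feederdefense)

grid <- make_grid(seed = 1)
schedule <- make_treatment_schedule(2009, seed = 1, grid = grid)
cfg <- sim_config(n_individuals = 30, n_days = 60)
pop <- simulate_population(grid, cfg, seed = 1)

detections <- simulate_detection_stream(pop, grid, schedule, cfg, seed = 2)
visits <- detections_to_visits(detections)
tab <- assemble_analysis_table(visits, pop[c("tag_id", "sex", "age_class")],
                               grid, schedule)

null_concentration(visits, n_rep = 100, seed = 3)
fit <- defense_mma(tab)
summary(fit)
plot(fit)
```

Or in one call writing all intermediate tables and a run log:

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

The run log reconciles row counts exactly: candidate bird-feeder-days =
kept rows + rows dropped for < 3 days followed + singleton feeder-days.

## Known limitations

* Within-day temporal overlap of individuals at a feeder is deliberately
  not analysed; visit counts per day are the unit.
* The permutation nulls use uniform weights over the visited set; no
  distance- or attractiveness-weighted null is offered.
* Stability treats the season's visited feeder set as the universe; adding
  the never-visited feeders would only append constant-zero pairs, which
  changes the Pearson correlation — the visited-only choice is tested and
  documented, not hidden.
* Model averaging assumes the same response scale across models (always
  true here) and normal sampling of coefficients; intervals are Wald-type.
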