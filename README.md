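# feederdefense

Resource defense and monopolization from RFID feeder detections.

`feederdefense` is an R package for behavioural ecologists working with
populations marked with passive integrated transponders (PIT tags) visiting
a grid of feeders equipped with RFID antennas. From per-second detection
streams it quantifies how much individuals concentrate and stabilize their
use of feeders, whether that use departs from random, and how a focal
individual's space use, the number of competitors, food quality and habitat
visibility shape the **number of visits by competitors (NVC)** at a feeder
it may be defending — separating *monopolization* (low NVC) from *defense
capacity* (how strongly the focal's presence reduces NVC).

## The core model

Per-second readings of tag *i* at feeder *f* are merged into visits with a
strict 21-second gap rule. Daily **spatial concentration** is
C(i,f,d) = v(i,f,d) / Σ_f' v(i,f',d); **spatial stability** is the Pearson
correlation between daily and season-level concentration across
(feeder, day) pairs. Two 100-replicate permutation nulls test concentration
(visits reassigned uniformly among a bird-day's visited feeders) and
dominance (a feeder-day's visits reassigned uniformly among its visitors).

The modelling core fits ten candidate linear mixed models for
log(NVC) with a feeder random intercept and a correlated individual random
intercept and concentration slope:

    log(NVC) ~ controls + concentration * (daily visits, stability,
               n competitors, sucrose, openness : lateral visibility)
               + (1 | feeder) + (1 + concentration | individual)

AICc (marginal; maximum-likelihood fits) ranks the models, Akaike weights
w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2) weight them, and REML coefficients are
averaged with zero substitution and unconditional standard errors
SE = Σ w_i √(se_i² + (θ_i − θ̄)²). Per-individual defense combines the
averaged concentration slope with random-slope BLUPs, reported as the
percent NVC reduction 100(1 − e^slope) when concentration goes 0 → 1.

Because field detection datasets of this kind are rarely released, the
package includes an individual-based simulator (grid, randomized-block
sucrose treatment, per-second streams with fidelity- and defense-driven
structure) and a generative twin of the mixed model, used throughout the
tests for parameter recovery and calibration.

## Worked example

```r
library(feederdefense)

grid     <- make_grid(seed = 1)                       # 45-feeder study grid
schedule <- make_treatment_schedule(2009, seed = 1, grid = grid)
cfg      <- sim_config(n_individuals = 30, n_days = 60)
pop      <- simulate_population(grid, cfg, seed = 1)

detections <- simulate_detection_stream(pop, grid, schedule, cfg, seed = 2)
nrow(detections)                                      # 294159 readings
visits <- detections_to_visits(detections)            # 31888 visits
tab <- assemble_analysis_table(visits, pop[c("tag_id", "sex", "age_class")],
                               grid, schedule)        # 1102 bird-feeder-days

null_concentration(visits, n_rep = 100, seed = 3)
#> Permutation null test: mean max daily concentration
#>   observed = 0.5917, null = 0.2775 +/- 0.0015 (100 replicates), P = 0.009901

fit <- defense_mma(tab)
fit
#> Multimodel inference for feeder defense (log NVC)
#>   1102 rows, 14 focal individuals, 23 feeders
#> Model selection (AICc):
#>  model_id  K   logLik    AICc delta weight usable
#>         6 19 -1190.67 2420.05  0.00  0.315   TRUE
#>         4 18 -1191.84 2420.31  0.26  0.276   TRUE
#>         5 18 -1192.31 2421.25  1.19  0.173   TRUE
#>         9 20 -1190.57 2421.92  1.86  0.124   TRUE
#>        10 21 -1189.76 2422.37  2.32  0.099   TRUE
#> Population-level concentration slope -1.245 (NVC reduction 71.2% as concentration 0 -> 1)
```

Reading this output: simulated birds concentrate far more than the
permutation null (0.59 observed vs 0.28 ± 0.002 expected at random,
P ≈ 0.0099, the smallest value 100 replicates can report), and the averaged
mixed model attributes a 71% reduction in competitor visits to a fully
concentrated focal male — the simulated population was generated with
active defense, and the pipeline recovers it. `summary(fit)` prints the
averaged coefficient table with unconditional SEs and 95% CIs;
`blup_slopes(fit)` and `plot(fit)` show the individual-level continuum of
defense; `random_slope_support(tab)` gives the AICc evidence that the
concentration slope varies among individuals.

`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))` runs the whole
chain and writes every intermediate table plus a JSON run log whose row
counts reconcile exactly across the eligibility filters.

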