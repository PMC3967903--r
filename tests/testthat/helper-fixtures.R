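# Fixture builders shared across tests. Everything is generated in code.

# detection records at given offsets (seconds) from a fixed origin
det_at <- function(sec, tag = "T001", feeder = "F01",
                   origin = as.POSIXct("2009-06-01 06:00:00", tz = "UTC")) {
  data.frame(timestamp = origin + sec, tag_id = tag, feeder_id = feeder,
             stringsAsFactors = FALSE)
}

# visit-count table -> synthetic visit rows (one row per visit)
visits_from_counts <- function(counts) {
  # counts: data.frame tag_id, feeder_id, date, n
  v <- counts[rep(seq_len(nrow(counts)), counts$n),
              c("tag_id", "feeder_id", "date")]
  v$date <- as.Date(v$date)
  v$start <- as.POSIXct(paste(v$date, "08:00:00"), tz = "UTC") +
    seq_len(nrow(v)) * 60
  v$duration_s <- 5L
  rownames(v) <- NULL
  v
}

# a small simulated world used by several tests
small_world <- function(seed = 11, n_individuals = 18, n_days = 25) {
  grid <- make_grid(seed = seed)
  cfg <- sim_config(n_individuals = n_individuals, n_days = n_days)
  sch <- make_treatment_schedule(2009, seed = seed, grid = grid)
  pop <- simulate_population(grid, cfg, seed = seed)
  visits <- simulate_visits(pop, grid, sch, cfg, seed = seed + 1)
  list(grid = grid, cfg = cfg, schedule = sch, pop = pop, visits = visits)
}

# population table with explicit behavioural parameters
manual_pop <- function(tag, home, lambda = 30, kappa = 0, beta = 0,
                       sex = "M", age = "adult",
                       first = as.Date("2009-06-01"), n_days = 10) {
  data.frame(tag_id = tag, sex = sex, age_class = age, home_feeder = home,
             lambda = lambda, kappa = kappa, beta = beta,
             first_date = first, last_date = first + n_days - 1,
             stringsAsFactors = FALSE)
}

# a flat single-habitat line of feeders (equal attractiveness everywhere)
flat_grid <- function(n = 4) {
  data.frame(feeder_id = sprintf("G%02d", seq_len(n)),
             x = (seq_len(n) - 1) * 100, y = 0, row = 1L,
             habitat = "forest", openness = "closed",
             lateral_visibility = 5, stringsAsFactors = FALSE)
}

# reference generating parameters for recovery studies: published averaged
# coefficients plus plausible variance components
recovery_truth <- function() {
  ref <- reference_averaged_coefs()
  coefs <- stats::setNames(ref$coef, ref$term)
  coefs["(Intercept)"] <- 1.2
  vc <- c(feeder_intercept = 0.04, individual_intercept = 0.09,
          individual_slope = 0.25, intercept_slope_cov = -0.03,
          residual = 0.49)
  list(coefs = coefs, varcomp = vc)
}
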