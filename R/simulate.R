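#' Simulator configuration
#'
#' Bundles and validates the tunable parameters of the individual-based
#' feeder-visitation simulator. Defaults emulate one breeding season on the
#' 45-feeder grid (20 May to 30 August, 103 days).
#'
#' @param n_individuals Number of tagged birds.
#' @param n_days Number of simulated days.
#' @param start_date First simulated day.
#' @param dropout Probability that a detector misses any interior second of
#'   a visit (the first and last second of a visit are always read, so visit
#'   boundaries stay identifiable). Must lie in `[0, 1)`.
#' @param visit_duration_median,visit_duration_sdlog Median (seconds) and
#'   log-scale shape of the log-normal visit-duration distribution.
#' @param habitat_attract Named positive multipliers on feeder
#'   attractiveness by habitat (hayfield, fallow, forest).
#' @param sucrose_attract Positive multiplier applied to feeders holding the
#'   high-sucrose treatment that week.
#' @param repertoire_size Number of feeders (home feeder plus nearest
#'   neighbours) an individual draws its visits from.
#' @param day_concentration Dirichlet concentration governing day-to-day
#'   wobble of an individual's allocation around its long-run weights;
#'   `Inf` switches the wobble off (fixed multinomial probabilities).
#' @param activity_window Hours of day (start, end) within which visits are
#'   scheduled.
#' @param min_visit_gap Minimum seconds between a bird's consecutive visits;
#'   must exceed the sessionization gap threshold so simulated visits remain
#'   distinct.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 55L, n_days = 103L,
                       start_date = as.Date("2009-05-20"),
                       dropout = 0.05,
                       visit_duration_median = 8, visit_duration_sdlog = 0.6,
                       habitat_attract = c(hayfield = 1.3, fallow = 1.2,
                                           forest = 1.0),
                       sucrose_attract = 1.5,
                       repertoire_size = 6L,
                       day_concentration = 40,
                       activity_window = c(5, 21),
                       min_visit_gap = 25) {
  if (dropout < 0 || dropout >= 1)
    stop("invalid config: dropout must lie in [0, 1)", call. = FALSE)
  if (any(habitat_attract <= 0) || sucrose_attract <= 0)
    stop("invalid config: attractiveness multipliers must be positive",
         call. = FALSE)
  if (!all(c("hayfield", "fallow", "forest") %in% names(habitat_attract)))
    stop("invalid config: habitat_attract must name hayfield, fallow, forest",
         call. = FALSE)
  if (day_concentration <= 0)
    stop("invalid config: day_concentration must be positive (Inf allowed)",
         call. = FALSE)
  stopifnot(n_individuals >= 0, n_days >= 1, visit_duration_median > 0,
            visit_duration_sdlog >= 0, repertoire_size >= 1,
            length(activity_window) == 2,
            activity_window[1] < activity_window[2], min_visit_gap > 21)
  structure(list(
    n_individuals = as.integer(n_individuals), n_days = as.integer(n_days),
    start_date = as.Date(start_date), dropout = dropout,
    visit_duration_median = visit_duration_median,
    visit_duration_sdlog = visit_duration_sdlog,
    habitat_attract = habitat_attract, sucrose_attract = sucrose_attract,
    repertoire_size = as.integer(repertoire_size),
    day_concentration = day_concentration,
    activity_window = activity_window, min_visit_gap = min_visit_gap
  ), class = "sim_config")
}

#' Simulate a tagged population with known behavioural parameters
#'
#' Each individual carries a ground-truth daily visit rate (`lambda`), a
#' feeder-fidelity concentration (`kappa`, 0 = uniform use of its
#' repertoire, large = all visits at the home feeder), a defense strength
#' (`beta`, exclusion of competitors at feeders it dominates) and a tenure
#' (first/last active day). Tenure lengths mirror the field seasons (males
#' followed ~38 +/- 22 days, females ~21 +/- 16; juveniles appear late and
#' stay only a few days).
#'
#' @param grid Feeder grid from [make_grid()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param prop_male,prop_juvenile Sex and age composition.
#' @param lambda_meanlog,lambda_sdlog Log-normal parameters of the daily
#'   visit rate.
#' @param kappa_meanlog,kappa_sdlog Log-normal parameters of feeder
#'   fidelity.
#' @param p_nondefender Probability an adult has `beta = 0` (no defense).
#' @param beta_meanlog,beta_sdlog Log-normal parameters of defense strength
#'   among defenders.
#' @return A data.frame with one row per individual: `tag_id`, `sex`,
#'   `age_class`, `home_feeder`, `lambda`, `kappa`, `beta`, `first_date`,
#'   `last_date`.
#' @export
simulate_population <- function(grid = make_grid(), cfg = sim_config(),
                                seed = 1L,
                                prop_male = 0.6, prop_juvenile = 0.12,
                                lambda_meanlog = log(45), lambda_sdlog = 0.4,
                                kappa_meanlog = log(6), kappa_sdlog = 0.7,
                                p_nondefender = 0.3,
                                beta_meanlog = log(1.5), beta_sdlog = 0.5) {
  n <- cfg$n_individuals
  if (n == 0L)
    return(data.frame(tag_id = character(), sex = character(),
                      age_class = character(), home_feeder = character(),
                      lambda = numeric(), kappa = numeric(), beta = numeric(),
                      first_date = as.Date(character()),
                      last_date = as.Date(character())))
  withr_seed(seed, {
    sex <- ifelse(stats::runif(n) < prop_male, "M", "F")
    age <- ifelse(stats::runif(n) < prop_juvenile, "juvenile", "adult")
    lambda <- stats::rlnorm(n, lambda_meanlog, lambda_sdlog)
    kappa <- stats::rlnorm(n, kappa_meanlog, kappa_sdlog)
    beta <- ifelse(stats::runif(n) < p_nondefender, 0,
                   stats::rlnorm(n, beta_meanlog, beta_sdlog))
    home <- sample(grid$feeder_id, n, replace = TRUE)
    first_day <- integer(n); len <- numeric(n)
    adult <- age == "adult"
    first_day[adult] <- sample.int(max(1L, cfg$n_days - 5L), sum(adult),
                                   replace = TRUE)
    len[adult] <- ifelse(sex[adult] == "M",
                         stats::rnorm(sum(adult), 38, 22),
                         stats::rnorm(sum(adult), 21, 16))
    juv <- !adult
    if (any(juv)) {
      lo <- max(1L, cfg$n_days - 30L)
      first_day[juv] <- sample(seq(lo, cfg$n_days), sum(juv), replace = TRUE)
      len[juv] <- stats::rnorm(sum(juv), 5, 3)
    }
    len <- pmax(3, round(len))
    last_day <- pmin(cfg$n_days, first_day + len - 1L)
    data.frame(
      tag_id = sprintf("T%03d", seq_len(n)), sex = sex, age_class = age,
      home_feeder = home, lambda = lambda, kappa = kappa, beta = beta,
      first_date = cfg$start_date + first_day - 1L,
      last_date = cfg$start_date + last_day - 1L,
      stringsAsFactors = FALSE
    )
  })
}

# repertoire of a bird: its home feeder plus the nearest neighbours
.repertoire <- function(home, grid, size) {
  i <- match(home, grid$feeder_id)
  d <- sqrt((grid$x - grid$x[i])^2 + (grid$y - grid$y[i])^2)
  grid$feeder_id[order(d)][seq_len(min(size, nrow(grid)))]
}

#' Simulate visit-level feeder use
#'
#' For every individual-day within tenure, a visit count is drawn from a
#' Poisson with mean `lambda` scaled by the home feeder's habitat and
#' sucrose multipliers; visits are allocated across the individual's feeder
#' repertoire by a Dirichlet-multinomial whose long-run weights put mass
#' `(1 + kappa)` on the home feeder relative to each other feeder (scaled by
#' feeder attractiveness). Territorial exclusion then thins competitor
#' visits: at each feeder-day, each visit by a bird other than the day's top
#' user is retained with probability `exp(-beta_top * C_top)`, where
#' `beta_top` is the top user's defense strength and `C_top` its realized
#' daily spatial concentration at that feeder (computed before thinning).
#' Retained visits are finally laid out in time within the daily activity
#' window, consecutive visits of a bird separated by at least
#' `cfg$min_visit_gap` seconds.
#'
#' @param pop Population from [simulate_population()].
#' @param grid Feeder grid.
#' @param schedule Treatment schedule (or `NULL` for all-low).
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the seed fully determines the output.
#' @return A data.frame of visits: `tag_id`, `feeder_id`, `date`, `start`
#'   (POSIXct, UTC), `duration_s`.
#' @export
simulate_visits <- function(pop, grid = make_grid(), schedule = NULL,
                            cfg = sim_config(), seed = 1L) {
  empty <- data.frame(tag_id = character(), feeder_id = character(),
                      date = as.Date(character()),
                      start = as.POSIXct(character(), tz = "UTC"),
                      duration_s = integer())
  if (nrow(pop) == 0L) return(empty)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  # high-sucrose lookup: feeder x date
  high <- matrix(FALSE, nrow(grid), length(dates),
                 dimnames = list(grid$feeder_id, as.character(dates)))
  if (!is.null(schedule)) {
    hs <- schedule[schedule$sucrose == "high", , drop = FALSE]
    for (i in seq_len(nrow(hs))) {
      dd <- dates >= hs$week_start[i] & dates <= hs$week_end[i]
      if (any(dd)) high[hs$feeder_id[i], dd] <- TRUE
    }
  }
  hab_a <- cfg$habitat_attract[grid$habitat]
  names(hab_a) <- grid$feeder_id

  withr_seed(seed, {
    alloc <- vector("list", nrow(pop))
    for (b in seq_len(nrow(pop))) {
      bird <- pop[b, ]
      rep_f <- .repertoire(bird$home_feeder, grid, cfg$repertoire_size)
      k <- length(rep_f)
      act <- dates[dates >= bird$first_date & dates <= bird$last_date]
      if (!length(act)) next
      a_base <- hab_a[rep_f]
      is_home <- rep_f == bird$home_feeder
      rows <- vector("list", length(act))
      for (j in seq_along(act)) {
        a <- a_base * ifelse(high[rep_f, as.character(act[j])],
                             cfg$sucrose_attract, 1)
        n_vis <- stats::rpois(1, bird$lambda * a[is_home] /
                                hab_a[bird$home_feeder])
        if (n_vis == 0L) next
        if (is.infinite(bird$kappa)) {
          p <- as.numeric(is_home)
        } else {
          w <- a * (1 + bird$kappa * is_home)
          p <- w / sum(w)
          if (is.finite(cfg$day_concentration)) {
            g <- stats::rgamma(k, shape = cfg$day_concentration * p)
            p <- if (sum(g) > 0) g / sum(g) else p
          }
        }
        cnt <- as.integer(stats::rmultinom(1, n_vis, p))
        nz <- cnt > 0L
        if (!any(nz)) next
        rows[[j]] <- data.frame(tag_id = bird$tag_id, feeder_id = rep_f[nz],
                                date = act[j], n = cnt[nz],
                                stringsAsFactors = FALSE)
      }
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) alloc[[b]] <- do.call(rbind, rows)
    }
    alloc <- alloc[!vapply(alloc, is.null, logical(1))]
    if (!length(alloc)) return(empty)
    counts <- do.call(rbind, alloc)

    # territorial thinning against the top user's pre-thinning concentration
    bd <- .key(counts$tag_id, counts$date)
    counts$day_total <- stats::ave(counts$n, bd, FUN = sum)
    counts$conc <- counts$n / counts$day_total
    fd <- .key(counts$feeder_id, counts$date)
    top_idx <- tapply(seq_len(nrow(counts)), fd,
                      function(i) i[which.max(counts$n[i])])
    top_of <- unlist(top_idx)[match(fd, names(top_idx))]
    retain_p <- exp(-pop$beta[match(counts$tag_id[top_of], pop$tag_id)] *
                      counts$conc[top_of])
    is_top <- seq_len(nrow(counts)) == top_of
    kept <- counts$n
    comp <- !is_top
    kept[comp] <- stats::rbinom(sum(comp), counts$n[comp], retain_p[comp])
    counts$n <- kept
    counts <- counts[counts$n > 0L, , drop = FALSE]
    if (!nrow(counts)) return(empty)

    # expand to visit level and schedule within the activity window
    v <- counts[rep(seq_len(nrow(counts)), counts$n),
                c("tag_id", "feeder_id", "date")]
    g <- .key(v$tag_id, v$date)
    v <- v[order(g, stats::runif(nrow(v))), ]   # interleave feeders randomly
    g <- .key(v$tag_id, v$date)
    dur <- pmax(1L, as.integer(round(stats::rlnorm(
      nrow(v), log(cfg$visit_duration_median), cfg$visit_duration_sdlog))))
    window_s <- diff(cfg$activity_window) * 3600
    busy <- stats::ave(dur + cfg$min_visit_gap, g, FUN = sum)
    free <- pmax(0, window_s - busy)
    e <- stats::rgamma(nrow(v), 1)
    extra <- free * e / stats::ave(e, g, FUN = sum)
    step <- dur + cfg$min_visit_gap + extra
    offset <- stats::ave(step, g, FUN = cumsum) - dur
    v$start <- as.POSIXct(unclass(v$date) * 86400, origin = "1970-01-01",
                          tz = "UTC") +
      cfg$activity_window[1] * 3600 + round(offset)
    v$duration_s <- dur
    rownames(v) <- NULL
    v[order(v$tag_id, v$start), ]
  })
}

#' Expand visits into per-second detection readings
#'
#' Each visit of duration `d` seconds becomes readings at seconds
#' `0, ..., d - 1` from its start; interior seconds are dropped
#' independently with probability `dropout`, but the first and last second
#' are always kept and any dropout run long enough to split the visit under
#' the 21-s merge rule is repaired, so sessionization recovers the generated
#' visits exactly.
#'
#' @param visits Visit table from [simulate_visits()].
#' @param dropout Per-second miss probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param gap_guard Readings are re-inserted so that no internal gap reaches
#'   this many seconds (default 21, the sessionization threshold).
#' @return A detection data.frame: `timestamp` (POSIXct, UTC), `tag_id`,
#'   `feeder_id`, sorted by timestamp.
#' @export
simulate_detections <- function(visits, dropout = 0.05, seed = 1L,
                                gap_guard = 21) {
  if (dropout < 0 || dropout >= 1)
    stop("invalid config: dropout must lie in [0, 1)", call. = FALSE)
  if (nrow(visits) == 0L)
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      tag_id = character(), feeder_id = character()))
  withr_seed(seed, {
    idx <- rep(seq_len(nrow(visits)), visits$duration_s)
    sec <- sequence(visits$duration_s) - 1L
    ts <- as.numeric(visits$start)[idx] + sec
    first <- sec == 0L
    last <- sec == visits$duration_s[idx] - 1L
    keep <- first | last | stats::runif(length(sec)) >= dropout
    idx <- idx[keep]; ts <- ts[keep]
    # repair dropout runs that would break a visit in two
    repeat {
      gap_after <- c(diff(ts), 0)
      bad <- which(gap_after >= gap_guard & idx == c(idx[-1], -1L))
      if (!length(bad)) break
      mid <- floor((ts[bad] + ts[bad + 1]) / 2)
      ts <- c(ts, mid); idx <- c(idx, idx[bad])
      o <- order(idx, ts); ts <- ts[o]; idx <- idx[o]
    }
    out <- data.frame(
      timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
      tag_id = visits$tag_id[idx], feeder_id = visits$feeder_id[idx],
      stringsAsFactors = FALSE)
    out <- out[order(out$timestamp, out$tag_id, out$feeder_id), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full detection stream
#'
#' Convenience wrapper chaining [simulate_visits()] and
#' [simulate_detections()].
#'
#' @inheritParams simulate_visits
#' @return A detection data.frame (see [simulate_detections()]).
#' @export
simulate_detection_stream <- function(pop, grid = make_grid(),
                                      schedule = NULL, cfg = sim_config(),
                                      seed = 1L) {
  v <- simulate_visits(pop, grid, schedule, cfg, seed = seed)
  simulate_detections(v, dropout = cfg$dropout, seed = seed + 1L)
}
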