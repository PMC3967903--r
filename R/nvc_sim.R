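# Generative counterpart of the NVC mixed model, used for parameter
# recovery and coverage studies where no field data can be re-used.

#' Simulate an analysis-table design (covariates only)
#'
#' Draws a bird-feeder-day covariate table with the structure and rough
#' scales of the field analysis table: individuals carry a season-level
#' spatial stability, bird-days carry a daily visit total and a handful of
#' visited feeders with Dirichlet-distributed concentration shares, days
#' carry a grid-usage index, and feeders carry openness, lateral visibility
#' and a season rank. No response column is attached; see
#' [simulate_nvc_table()].
#'
#' @param n_rows Approximate number of rows (default mirrors the field
#'   sample of 15,037 bird-feeder-days).
#' @param n_individuals,n_feeders Numbers of focal individuals and feeders.
#' @param years Study years; sucrose manipulation runs in the last one.
#' @param seed Integer seed.
#' @return A data.frame with columns `tag_id`, `feeder_id`, `date`, `year`,
#'   `spatial_concentration`, `daily_visits`, `spatial_stability`,
#'   `n_competitors`, `grid_usage`, `feeder_rank`, `sucrose`, `openness`,
#'   `lateral_visibility`.
#' @export
simulate_nvc_design <- function(n_rows = 15037L, n_individuals = 88L,
                                n_feeders = 45L, years = 2007:2009,
                                seed = 1L) {
  withr_seed(seed, {
    feeders <- sprintf("F%02d", seq_len(n_feeders))
    open <- stats::runif(n_feeders) < 0.6
    lv <- ifelse(open, stats::runif(n_feeders, 10, 30),
                 stats::runif(n_feeders, 1, 15))
    rank <- sample.int(n_feeders)
    tags <- sprintf("T%03d", seq_len(n_individuals))
    stab <- stats::runif(n_individuals, 0.15, 0.95)
    yr <- sample(years, n_individuals, replace = TRUE)
    rows <- vector("list", 4 * n_rows %/% 10 + n_individuals)
    total <- 0L; r <- 0L
    while (total < n_rows) {
      r <- r + 1L
      b <- (r - 1L) %% n_individuals + 1L
      day <- sample.int(100, 1)
      k <- min(n_feeders, 1L + stats::rpois(1, 3.5))
      sh <- stats::rgamma(k, 0.8); sh <- sh / sum(sh)
      f <- sample.int(n_feeders, k)
      rows[[r]] <- data.frame(
        tag_id = tags[b], feeder_id = feeders[f],
        date = as.Date(sprintf("%d-06-01", yr[b])) + day,
        year = yr[b], spatial_concentration = sh,
        daily_visits = stats::rpois(1, 60) + 1L,
        spatial_stability = stab[b],
        n_competitors = 1L + stats::rpois(k, 3),
        grid_usage = NA_real_,
        feeder_rank = rank[f], sucrose = "low",
        openness = ifelse(open[f], "open", "closed"),
        lateral_visibility = lv[f], stringsAsFactors = FALSE)
      total <- total + k
    }
    d <- do.call(rbind, rows[seq_len(r)])
    d <- d[seq_len(min(nrow(d), n_rows)), ]
    gu <- stats::rnorm(length(unique(d$date)), 50, 12)
    gu <- pmax(5, gu)
    d$grid_usage <- gu[match(d$date, unique(d$date))]
    manip <- d$year == max(years)
    d$sucrose[manip & stats::runif(nrow(d)) < 1 / 3] <- "high"
    rownames(d) <- NULL
    d
  })
}

#' Simulate responses from the mixed model's generative form
#'
#' Attaches a log-scale response to a covariate design: fixed-effect linear
#' predictor plus a feeder random intercept, an individual random intercept,
#' an individual random slope on spatial concentration (intercept and slope
#' correlated), and residual noise. This is the generative twin of the
#' fitted model, used to verify that the inference machinery recovers known
#' coefficients.
#'
#' @param coefs Named numeric vector of fixed-effect coefficients; names
#'   must match the full-model design-matrix columns for `design` (see
#'   [model_formula()] applied to model 10), e.g. `"(Intercept)"`,
#'   `"year2008"`, `"spatial_concentration:spatial_stability"`.
#' @param variance_components Named numeric vector with entries
#'   `feeder_intercept`, `individual_intercept`, `individual_slope`
#'   (variances), `intercept_slope_cov` (covariance) and `residual`
#'   (variance). The implied individual-level covariance matrix must be
#'   positive semi-definite.
#' @param design Covariate table, e.g. from [simulate_nvc_design()].
#' @param seed Integer seed.
#' @return `design` with two added columns: `log_nvc` (the simulated
#'   log-scale response) and `nvc = exp(log_nvc)`, ready for [fit_lmm()].
#' @export
simulate_nvc_table <- function(coefs, variance_components, design,
                               seed = 1L) {
  vc_names <- c("feeder_intercept", "individual_intercept",
                "individual_slope", "intercept_slope_cov", "residual")
  miss <- setdiff(vc_names, names(variance_components))
  if (length(miss))
    stop("invalid config: variance_components missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  vc <- variance_components
  if (any(vc[c("feeder_intercept", "individual_intercept",
               "individual_slope", "residual")] < 0))
    stop("invalid config: variances must be non-negative", call. = FALSE)
  Sigma <- matrix(c(vc[["individual_intercept"]], vc[["intercept_slope_cov"]],
                    vc[["intercept_slope_cov"]], vc[["individual_slope"]]), 2)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("invalid config: individual random-effect covariance is not ",
         "positive semi-definite", call. = FALSE)
  design <- .prepare_nvc_data(design)
  form <- model_formula(build_model_set()[[10]], random = FALSE,
                        response = NULL)
  X <- stats::model.matrix(form, design)
  miss <- setdiff(colnames(X), names(coefs))
  if (length(miss))
    stop("coefs missing term(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  beta <- coefs[colnames(X)]
  withr_seed(seed, {
    tags <- levels(design$tag_id); feeders <- levels(design$feeder_id)
    b_f <- stats::rnorm(length(feeders), 0, sqrt(vc[["feeder_intercept"]]))
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
    b_i <- matrix(stats::rnorm(2 * length(tags)), ncol = 2) %*% t(L)
    ti <- as.integer(design$tag_id); fi <- as.integer(design$feeder_id)
    y <- as.numeric(X %*% beta) + b_f[fi] + b_i[ti, 1] +
      b_i[ti, 2] * design$spatial_concentration +
      stats::rnorm(nrow(design), 0, sqrt(vc[["residual"]]))
    design$log_nvc <- y
    design$nvc <- exp(y)
  })
  design
}
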