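#' Multimodel inference for feeder defense
#'
#' Fits the 10-model candidate set of linear mixed models for the
#' log-transformed number of visits by competitors (NVC), performs AICc
#' model selection on the maximum-likelihood fits, and averages the
#' restricted-maximum-likelihood coefficients across the set with
#' unconditional standard errors. Per-individual defense slopes combine the
#' averaged fixed effect of spatial concentration (other numeric covariates
#' at their means, factors at reference) with model-averaged BLUPs of the
#' individual random slope.
#'
#' Rows with missing covariates (e.g. focal individuals whose spatial
#' stability is undefined) are dropped with a message. Fits that do not
#' converge or are singular are excluded from the average and the Akaike
#' weights renormalized, with a warning.
#'
#' @param data Analysis table from [assemble_analysis_table()] or
#'   [simulate_nvc_table()]; must contain `nvc >= 1` and the model
#'   covariates.
#' @param specs Candidate set (default [build_model_set()]).
#' @param average `"zero"` for zero-substitution averaging over the full
#'   set (default) or `"natural"` to renormalize over containing models.
#' @return An object of class `defense_mma` with components `selection`
#'   (model-selection table: model_id, K, logLik, AICc, delta, weight),
#'   `averaged` (term, coef, se, ci_lower, ci_upper), `fits_reml`,
#'   `fits_ml`, `blups` (per-individual slope table, see [blup_slopes()]),
#'   `data_means`, `n`, `n_individuals`, `n_feeders`.
#' @seealso [blup_slopes()], [random_slope_support()]
#' @export
defense_mma <- function(data, specs = build_model_set(),
                        average = c("zero", "natural")) {
  average <- match.arg(average)
  data <- .prepare_nvc_data(data)
  needed <- c("nvc", "spatial_concentration", "spatial_stability",
              "daily_visits", "n_competitors", "grid_usage", "feeder_rank",
              "lateral_visibility")
  .assert_cols(data, needed, "analysis table")
  ok <- stats::complete.cases(data[needed])
  if (any(!ok)) {
    message(sum(!ok), " row(s) with missing covariates dropped")
    data <- droplevels(data[ok, , drop = FALSE])
  }
  if (!nrow(data)) stop("no complete rows to fit", call. = FALSE)

  fits_ml <- lapply(specs, fit_lmm, data = data, method = "ML")
  fits_reml <- lapply(specs, fit_lmm, data = data, method = "REML")
  usable <- vapply(fits_ml, function(f) f$converged, logical(1)) &
    vapply(fits_reml, function(f) f$converged && !f$singular, logical(1))
  if (!all(usable))
    warning("model(s) ", paste(which(!usable), collapse = ", "),
            " flagged (non-convergence or singular fit); ",
            "excluded from averaging")
  if (!any(usable)) stop("no usable fits", call. = FALSE)

  aiccs <- vapply(fits_ml, aicc, numeric(1))
  w_all <- akaike_weights(aiccs[usable])
  weights <- numeric(length(specs)); weights[usable] <- w_all
  averaged <- model_average(fits_reml[usable], w_all, method = average)

  selection <- data.frame(
    model_id = vapply(specs, `[[`, 0L, "model_id"),
    K = vapply(fits_ml, `[[`, 0L, "K"),
    logLik = vapply(fits_ml, `[[`, 0, "loglik"),
    AICc = aiccs, delta = aiccs - min(aiccs[usable]),
    weight = weights, usable = usable)
  selection <- selection[order(selection$AICc), ]
  rownames(selection) <- NULL

  num_means <- vapply(
    c("daily_visits", "n_competitors", "spatial_stability", "grid_usage",
      "feeder_rank", "lateral_visibility"),
    function(v) mean(data[[v]]), numeric(1))

  obj <- structure(list(
    selection = selection, averaged = averaged, average_method = average,
    fits_reml = fits_reml, fits_ml = fits_ml, weights = weights,
    usable = usable, data_means = num_means, n = nrow(data),
    n_individuals = nlevels(data$tag_id), n_feeders = nlevels(data$feeder_id),
    call = match.call()), class = "defense_mma")
  obj$blups <- blup_slopes(obj)
  obj
}

# averaged fixed part of the concentration slope: other numeric covariates
# at their data means, factors at reference (closed habitat, low sucrose)
.fixed_conc_slope <- function(object) {
  cf <- stats::setNames(object$averaged$coef, object$averaged$term)
  m <- object$data_means
  pick <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  pick("spatial_concentration") +
    pick("spatial_concentration:daily_visits") * m[["daily_visits"]] +
    pick("n_competitors:spatial_concentration") * m[["n_competitors"]] +
    pick("spatial_concentration:spatial_stability") *
      m[["spatial_stability"]] +
    pick("spatial_concentration:opennessclosed:lateral_visibility") *
      m[["lateral_visibility"]]
}

#' Per-individual defense slopes and predicted NVC reductions
#'
#' Combines the model-averaged fixed effect of spatial concentration
#' (other numeric covariates at their means, factors at reference) with
#' each individual's model-averaged random-slope BLUP, and expresses the
#' total slope as the percent reduction in NVC when an individual's spatial
#' concentration goes from 0 to 1: `100 * (1 - exp(slope))`.
#'
#' @param object A `defense_mma` fit.
#' @return A data.frame `tag_id`, `blup_intercept`, `blup_slope`,
#'   `total_slope`, `reduction_pct`, with attribute `population` holding
#'   the population-level slope and reduction.
#' @export
blup_slopes <- function(object) {
  stopifnot(inherits(object, "defense_mma"))
  w <- object$weights[object$usable]
  fits <- object$fits_reml[object$usable]
  re <- lapply(fits, function(f) f$blups$tag_id)
  tags <- rownames(re[[1]])
  bi <- rowSums(mapply(function(r, wi) wi * r[tags, "(Intercept)"], re, w))
  bs <- rowSums(mapply(function(r, wi)
    wi * r[tags, "spatial_concentration"], re, w))
  fixed <- .fixed_conc_slope(object)
  total <- fixed + bs
  out <- data.frame(tag_id = tags, blup_intercept = bi, blup_slope = bs,
                    total_slope = total,
                    reduction_pct = 100 * (1 - exp(total)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "population") <- c(slope = unname(fixed),
                               reduction_pct = 100 * (1 - exp(fixed)))
  out
}

#' @export
print.defense_mma <- function(x, ...) {
  cat("Multimodel inference for feeder defense (log NVC)\n")
  cat(sprintf("  %d rows, %d focal individuals, %d feeders\n",
              x$n, x$n_individuals, x$n_feeders))
  cat("Model selection (AICc):\n")
  sel <- x$selection
  sel$logLik <- round(sel$logLik, 2); sel$AICc <- round(sel$AICc, 2)
  sel$delta <- round(sel$delta, 2); sel$weight <- round(sel$weight, 3)
  print.data.frame(utils::head(sel, 5), row.names = FALSE)
  pop <- attr(x$blups, "population")
  cat(sprintf(paste0("Population-level concentration slope %.3f ",
                     "(NVC reduction %.1f%% as concentration 0 -> 1)\n"),
              pop[["slope"]], pop[["reduction_pct"]]))
  invisible(x)
}

#' @export
summary.defense_mma <- function(object, ...) {
  structure(list(selection = object$selection, averaged = object$averaged,
                 blups = object$blups, n = object$n,
                 n_individuals = object$n_individuals,
                 n_feeders = object$n_feeders,
                 average_method = object$average_method),
            class = "summary.defense_mma")
}

#' @export
print.summary.defense_mma <- function(x, ...) {
  cat(sprintf("Multimodel inference: %d rows, %d individuals, %d feeders\n",
              x$n, x$n_individuals, x$n_feeders))
  cat("\nModel selection:\n")
  sel <- x$selection
  for (cl in c("logLik", "AICc", "delta")) sel[[cl]] <- round(sel[[cl]], 2)
  sel$weight <- round(sel$weight, 3)
  print.data.frame(sel, row.names = FALSE)
  cat(sprintf("\nModel-averaged coefficients (%s-substitution):\n",
              x$average_method))
  print(x$averaged)
  pop <- attr(x$blups, "population")
  cat(sprintf(paste0("\nPopulation-level concentration slope: %.3f ",
                     "(%.1f%% NVC reduction)\n"),
              pop[["slope"]], pop[["reduction_pct"]]))
  cat(sprintf("Individual total slopes: %.3f to %.3f (median %.3f)\n",
              min(x$blups$total_slope), max(x$blups$total_slope),
              stats::median(x$blups$total_slope)))
  invisible(x)
}

#' @export
coef.defense_mma <- function(object, ...) {
  stats::setNames(object$averaged$coef, object$averaged$term)
}

#' Predict log NVC from the averaged coefficients
#'
#' Population-level prediction: the full-model design matrix for `newdata`
#' multiplied by the model-averaged coefficients. `type = "response"`
#' back-transforms to the NVC scale.
#'
#' @param object A `defense_mma` fit.
#' @param newdata Covariate data.frame (defaults to refitting data means
#'   is not supported; supply newdata).
#' @param type `"link"` (log NVC, default) or `"response"` (NVC).
#' @param ... Unused.
#' @export
predict.defense_mma <- function(object, newdata,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  nd <- .prepare_nvc_data(newdata)
  form <- model_formula(build_model_set()[[10]], random = FALSE,
                        response = NULL)
  X <- stats::model.matrix(form, nd)
  cf <- coef(object)
  missing_terms <- setdiff(colnames(X), names(cf))
  if (length(missing_terms))
    stop("averaged coefficients lack term(s): ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  eta <- as.numeric(X %*% cf[colnames(X)])
  if (type == "response") exp(eta) else eta
}

#' @export
residuals.defense_mma <- function(object, ...) {
  best <- object$selection$model_id[object$selection$usable][1]
  stats::residuals(object$fits_reml[[best]]$fit, ...)
}

#' Simulate responses from the best-supported model
#'
#' Delegates to [lme4::simulate.merMod()] on the REML fit of the
#' lowest-AICc usable model.
#'
#' @param object A `defense_mma` fit.
#' @param nsim,seed,... Passed to the merMod simulate method.
#' @export
simulate.defense_mma <- function(object, nsim = 1, seed = NULL, ...) {
  best <- object$selection$model_id[object$selection$usable][1]
  stats::simulate(object$fits_reml[[best]]$fit, nsim = nsim, seed = seed,
                  ...)
}

#' Plot per-individual defense
#'
#' Scatter of each focal individual's predicted NVC reduction (spatial
#' concentration 0 to 1) against its baseline NVC at concentration 0
#' (covariates at their means, factors at reference), from the
#' model-averaged BLUPs.
#'
#' @param x A `defense_mma` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.defense_mma <- function(x, ...) {
  b <- x$blups
  cf <- stats::setNames(x$averaged$coef, x$averaged$term)
  m <- x$data_means
  base <- cf[["(Intercept)"]] +
    ifelse("grid_usage" %in% names(cf), cf[["grid_usage"]], 0) *
      m[["grid_usage"]] +
    cf[["n_competitors"]] * m[["n_competitors"]] +
    cf[["feeder_rank"]] * m[["feeder_rank"]] +
    cf[["daily_visits"]] * m[["daily_visits"]] +
    cf[["spatial_stability"]] * m[["spatial_stability"]] +
    cf[["lateral_visibility"]] * m[["lateral_visibility"]]
  nvc0 <- exp(base + b$blup_intercept)
  graphics::plot(nvc0, b$reduction_pct,
                 xlab = "predicted NVC at spatial concentration 0",
                 ylab = "predicted NVC reduction (%)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
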