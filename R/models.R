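# Candidate model set, mixed-model fitting, AICc multimodel inference.

# canonical fixed-effect term labels, in model-10 order
.nvc_terms <- c(
  "year", "grid_usage", "n_competitors", "feeder_rank", "sucrose",
  "spatial_concentration", "daily_visits", "spatial_stability",
  "openness", "lateral_visibility",
  "spatial_concentration:daily_visits",
  "spatial_concentration:n_competitors",
  "spatial_concentration:spatial_stability",
  "spatial_concentration:openness:lateral_visibility",
  "spatial_concentration:sucrose"
)

# inclusion matrix: which of the 10 candidate models carries each term
.nvc_inclusion <- list(
  year                                                 = 1:10,
  grid_usage                                           = 1:10,
  n_competitors                                        = 1:10,
  feeder_rank                                          = 1:10,
  sucrose                                              = 1:10,
  spatial_concentration                                = 3:10,
  daily_visits                                         = c(3, 5:10),
  spatial_stability                                    = c(3, 4, 6:10),
  openness                                             = c(2:6, 8:10),
  lateral_visibility                                   = c(2:6, 8:10),
  `spatial_concentration:daily_visits`                 = 5:10,
  `spatial_concentration:n_competitors`                = c(4, 5, 7:10),
  `spatial_concentration:spatial_stability`            = c(4, 6:10),
  `spatial_concentration:openness:lateral_visibility`  = c(4, 5, 6, 9, 10),
  `spatial_concentration:sucrose`                      = 10
)

#' Build the 10-model candidate set
#'
#' Returns the fixed-effect structures of the ten competing linear mixed
#' models. All models share five control main effects (year, grid usage,
#' number of competitors, feeder rank, sucrose); models 3-10 add the focal
#' individual's space-use covariates, habitat visibility and their
#' interactions with spatial concentration in the combinations of the
#' published candidate set; model 10 carries every term. The random
#' structure (feeder intercept; correlated individual intercept and
#' spatial-concentration slope) is common to all models.
#'
#' @return A list of 10 objects of class `model_spec`, each with
#'   `model_id` and `fixed_terms`.
#' @export
build_model_set <- function() {
  lapply(1:10, function(m) {
    terms <- .nvc_terms[vapply(.nvc_terms,
                               function(t) m %in% .nvc_inclusion[[t]],
                               logical(1))]
    structure(list(model_id = m, fixed_terms = terms), class = "model_spec")
  })
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d: log(nvc) ~ %s\n", x$model_id,
              paste(x$fixed_terms, collapse = " + ")))
  invisible(x)
}

#' Model formula for a candidate specification
#'
#' @param spec A `model_spec` from [build_model_set()].
#' @param random Include the random-effect structure (feeder intercept plus
#'   correlated individual intercept and concentration slope)?
#' @param random_slope If `random`, include the individual concentration
#'   slope (set `FALSE` for the intercept-only comparison structure).
#' @param response Left-hand side, as a character string.
#' @return A formula.
#' @export
model_formula <- function(spec, random = TRUE, random_slope = TRUE,
                          response = "log(nvc)") {
  rhs <- paste(spec$fixed_terms, collapse = " + ")
  if (random) {
    ind <- if (random_slope) "(1 + spatial_concentration | tag_id)"
           else "(1 | tag_id)"
    rhs <- paste(rhs, "(1 | feeder_id)", ind, sep = " + ")
  }
  stats::as.formula(paste(if (is.null(response)) "" else response, "~", rhs),
                    env = globalenv())
}

# drop fixed terms that cannot be estimated from this table: any term
# involving a factor observed at fewer than 2 levels (e.g. a single-season
# table has one year, or no sucrose manipulation)
.drop_inestimable <- function(spec, data) {
  ok <- vapply(spec$fixed_terms, function(tm) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(vars, function(v) {
      x <- data[[v]]
      !is.factor(x) || nlevels(droplevels(x)) >= 2
    }, logical(1)))
  }, logical(1))
  if (!all(ok)) {
    message("term(s) constant in the data dropped from model ",
            spec$model_id, ": ",
            paste(spec$fixed_terms[!ok], collapse = ", "))
    spec$fixed_terms <- spec$fixed_terms[ok]
  }
  spec
}

# coerce analysis-table columns to the factor codings used throughout:
# year reference 2007 (or earliest present), sucrose reference low,
# openness reference closed
.prepare_nvc_data <- function(data) {
  .assert_cols(data, c("tag_id", "feeder_id"), "analysis table")
  if (!is.factor(data$year))
    data$year <- factor(data$year, levels = sort(unique(data$year)))
  data$sucrose <- factor(data$sucrose, levels = c("low", "high"))
  data$openness <- factor(data$openness, levels = c("closed", "open"))
  data$tag_id <- factor(data$tag_id)
  data$feeder_id <- factor(data$feeder_id)
  data
}

#' Fit one candidate linear mixed model
#'
#' Fits `log(nvc)` on the specification's fixed terms with a feeder random
#' intercept and correlated individual random intercept and
#' spatial-concentration slope, via [lme4::lmer()]. Numeric covariates enter
#' on their raw scales; year, sucrose and openness are coded with references
#' 2007 (earliest year), low and closed. Fits that fail to converge or have
#' a singular random-effect covariance are returned flagged, not errored.
#'
#' @param spec A `model_spec`.
#' @param data Analysis table with an `nvc` column (>= 1).
#' @param method `"ML"` (for AICc) or `"REML"` (for coefficient averaging).
#' @param random_slope Include the individual random slope (default TRUE).
#' @return An object of class `lmm_fit`: model_id, method, coefficients,
#'   se, vcov, loglik, K (fixed effects + variance/covariance parameters +
#'   residual variance), n, blups (per-group random-effect modes),
#'   converged, singular, and the underlying `merMod` as `fit`.
#' @export
fit_lmm <- function(spec, data, method = c("REML", "ML"),
                    random_slope = TRUE) {
  method <- match.arg(method)
  data <- .prepare_nvc_data(data)
  if (!nrow(data)) stop("analysis table is empty", call. = FALSE)
  if (any(data$nvc <= 0)) stop("nvc must be positive for the log response",
                               call. = FALSE)
  spec <- .drop_inestimable(spec, data)
  form <- model_formula(spec, random = TRUE, random_slope = random_slope)
  fit <- suppressMessages(lme4::lmer(
    form, data = data, REML = (method == "REML"),
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  conv <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  K <- length(beta) + length(fit@theta) + 1L
  structure(list(
    model_id = spec$model_id, method = method, formula = form,
    coefficients = beta, se = sqrt(diag(vc)), vcov = vc,
    loglik = as.numeric(stats::logLik(fit)), K = K, n = nrow(data),
    blups = lme4::ranef(fit), converged = conv,
    singular = lme4::isSingular(fit), fit = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model %d (%s), n = %d, logLik = %.2f, K = %d%s\n",
              x$model_id, x$method, x$n, x$loglik, x$K,
              if (!x$converged) " [NOT CONVERGED]"
              else if (x$singular) " [singular]" else ""))
  print(round(x$coefficients, 5))
  invisible(x)
}

.aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("AICc undefined: n <= K + 1", call. = FALSE)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1)/(n - K - 1)`, where K counts fixed
#' effects plus random-effect variance/covariance parameters plus the
#' residual variance. The fit must be by maximum likelihood.
#'
#' @param fit An `lmm_fit`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (fit$method != "ML")
    warning("AICc computed from a REML log-likelihood; refit with ML")
  .aicc(fit$loglik, fit$K, fit$n)
}

#' Akaike weights
#'
#' Normalized model likelihoods `exp(-delta_i/2) / sum_j exp(-delta_j/2)`
#' with `delta_i = AICc_i - min(AICc)`. Invariant to a common shift, so raw
#' AICc values and AICc differences give identical weights.
#'
#' @param aicc_values Numeric vector of AICc values (or differences).
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1, all(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-averaged coefficients with unconditional standard errors
#'
#' Averages fixed-effect coefficients across the candidate set. Under
#' zero-substitution (default) a term absent from a model contributes a
#' coefficient of 0 (with zero sampling variance) to the average over the
#' full set; under natural averaging the weights are renormalized over the
#' models containing the term. The unconditional standard error is
#' `sum_i w_i * sqrt(se_i^2 + (theta_i - theta_bar)^2)`, and the confidence
#' interval is `theta_bar -/+ 1.96 * SE`.
#'
#' @param fits List of `lmm_fit` objects (REML fits of the candidate set).
#' @param weights Akaike weights aligned with `fits`, summing to 1.
#' @param method `"zero"` (zero-substitution) or `"natural"`.
#' @return A data.frame of class `averaged_coefs`: `term`, `coef`, `se`,
#'   `ci_lower`, `ci_upper`.
#' @export
model_average <- function(fits, weights, method = c("zero", "natural")) {
  method <- match.arg(method)
  stopifnot(length(fits) == length(weights),
            abs(sum(weights) - 1) < 1e-8)
  coef_list <- lapply(fits, `[[`, "coefficients")
  se_list <- lapply(fits, `[[`, "se")
  terms <- unique(unlist(lapply(coef_list, names)))
  # keep model-10 (fullest) ordering where available
  fullest <- coef_list[[which.max(lengths(coef_list))]]
  terms <- c(intersect(names(fullest), terms), setdiff(terms, names(fullest)))
  avg <- function(term) {
    th <- vapply(coef_list, function(b) if (term %in% names(b)) b[[term]]
                 else 0, numeric(1))
    se <- vapply(se_list, function(s) if (term %in% names(s)) s[[term]]
                 else 0, numeric(1))
    has <- vapply(coef_list, function(b) term %in% names(b), logical(1))
    w <- weights
    if (method == "natural") {
      w <- ifelse(has, w, 0)
      w <- w / sum(w)
    }
    tb <- sum(w * th)
    c(coef = tb, se = sum(w * sqrt(se^2 + (th - tb)^2)))
  }
  res <- t(vapply(terms, avg, numeric(2)))
  out <- data.frame(term = terms, coef = res[, "coef"], se = res[, "se"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$ci_lower <- out$coef - 1.96 * out$se
  out$ci_upper <- out$coef + 1.96 * out$se
  class(out) <- c("averaged_coefs", "data.frame")
  out
}

#' @export
print.averaged_coefs <- function(x, digits = 5, ...) {
  y <- x
  for (cl in c("coef", "se", "ci_lower", "ci_upper"))
    y[[cl]] <- round(y[[cl]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Confidence-interval bounds from coefficient/SE pairs
#'
#' Normal-theory bounds `coef -/+ z * se`, the arithmetic used for the
#' averaged-coefficient tables.
#'
#' @param coef,se Numeric vectors.
#' @param z Critical value (default 1.96).
#' @return A two-column matrix `ci_lower`, `ci_upper`.
#' @export
ci_bounds <- function(coef, se, z = 1.96) {
  cbind(ci_lower = coef - z * se, ci_upper = coef + z * se)
}

#' Evidence for the individual random concentration slope
#'
#' Fits the full (model 10) structure by maximum likelihood with and
#' without the individual random slope on spatial concentration and returns
#' `AICc(no slope) - AICc(slope)`; positive values favour treating the
#' slope as individual-specific.
#'
#' @param data Analysis table.
#' @param spec Fixed-effect specification (default: the full model).
#' @return Named list with both AICc values and `delta_aicc`.
#' @export
random_slope_support <- function(data, spec = build_model_set()[[10]]) {
  with_slope <- fit_lmm(spec, data, method = "ML", random_slope = TRUE)
  no_slope <- fit_lmm(spec, data, method = "ML", random_slope = FALSE)
  if (!with_slope$converged || !no_slope$converged)
    warning("a fit did not converge; delta AICc may be unreliable")
  a1 <- aicc(with_slope); a0 <- aicc(no_slope)
  list(aicc_slope = a1, aicc_no_slope = a0, delta_aicc = a0 - a1)
}
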