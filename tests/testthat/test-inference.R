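test_that("the candidate set reproduces the published inclusion structure", {
  specs <- build_model_set()
  expect_length(specs, 10L)
  controls <- c("year", "grid_usage", "n_competitors", "feeder_rank",
                "sucrose")
  for (s in specs) expect_true(all(controls %in% s$fixed_terms))
  expect_false("spatial_concentration" %in% specs[[1]]$fixed_terms)
  expect_false(any(grepl("spatial_concentration",
                         unlist(specs[1:2], use.names = FALSE))))
  expect_length(specs[[10]]$fixed_terms, 15L)
  three_way <- "spatial_concentration:openness:lateral_visibility"
  has3 <- vapply(specs, function(s) three_way %in% s$fixed_terms,
                 logical(1))
  expect_equal(which(has3), c(4L, 5L, 6L, 9L, 10L))
  only10 <- vapply(specs, function(s)
    "spatial_concentration:sucrose" %in% s$fixed_terms, logical(1))
  expect_equal(which(only10), 10L)
})

test_that("AICc matches hand arithmetic and penalizes parameters", {
  fake <- function(ll, K, n) structure(
    list(loglik = ll, K = K, n = n, method = "ML"), class = "lmm_fit")
  expect_equal(aicc(fake(-50, 5, 50)), 100 + 10 + 60 / 44)
  # correction vanishes as n grows
  expect_equal(aicc(fake(-50, 5, 1e9)), 110, tolerance = 1e-6)
  # same likelihood, one more parameter: strictly worse
  expect_gt(aicc(fake(-50, 6, 50)), aicc(fake(-50, 5, 50)))
  expect_error(aicc(fake(-50, 49, 50)), "undefined")
  expect_warning(aicc(structure(list(loglik = -50, K = 5, n = 50,
                                     method = "REML"),
                                class = "lmm_fit")), "REML")
})

test_that("Akaike weights normalize model likelihoods", {
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(0, 2)),
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))))
  w <- akaike_weights(c(123.4, 120.1, 140.0, 121.0))
  expect_equal(sum(w), 1)
  expect_equal(which.max(w), 2L)
  # invariance to a common shift (AICc values vs differences)
  expect_equal(akaike_weights(c(0, 2) + 500), akaike_weights(c(0, 2)))
})

test_that("model averaging follows the stated formulas", {
  fake_fit <- function(coefs, ses) structure(
    list(coefficients = coefs, se = ses), class = "lmm_fit")
  f1 <- fake_fit(c(a = 1), c(a = 0))
  f2 <- fake_fit(c(b = 3), c(b = 0))   # term "a" absent here
  avg <- model_average(list(f1, f2), c(0.5, 0.5))
  a <- avg[avg$term == "a", ]
  expect_equal(a$coef, 0.5)
  expect_equal(a$se, 0.5)   # spread-only unconditional SE
  expect_equal(a$ci_lower, 0.5 - 1.96 * 0.5)

  # identical models: average equals the common fit
  g <- fake_fit(c(a = 2, b = -1), c(a = 0.3, b = 0.1))
  avg2 <- model_average(list(g, g), c(0.4, 0.6))
  expect_equal(avg2$coef, c(2, -1))
  expect_equal(avg2$se, c(0.3, 0.1))

  # natural averaging renormalizes over containing models
  nat <- model_average(list(f1, f2), c(0.5, 0.5), method = "natural")
  expect_equal(nat$coef[nat$term == "a"], 1)
  expect_equal(nat$se[nat$term == "a"], 0)
})

test_that("averaging is shrinkage-bounded and inflates the SE", {
  set.seed(10)
  fits <- lapply(1:4, function(i) structure(
    list(coefficients = c(x = rnorm(1)), se = c(x = runif(1, 0.1, 0.5))),
    class = "lmm_fit"))
  w <- akaike_weights(runif(4, 0, 6))
  avg <- model_average(fits, w)
  ths <- vapply(fits, function(f) f$coefficients[["x"]], numeric(1))
  ses <- vapply(fits, function(f) f$se[["x"]], numeric(1))
  expect_lte(abs(avg$coef), max(abs(ths)))
  expect_gte(avg$se, sum(w * ses) - 1e-12)
})

test_that("mixed-model fixed effects match an OLS oracle without random variance", {
  des <- simulate_nvc_design(n_rows = 1500, n_individuals = 25, seed = 12)
  truth <- recovery_truth()
  vc0 <- c(feeder_intercept = 0, individual_intercept = 0,
           individual_slope = 0, intercept_slope_cov = 0, residual = 0.25)
  tab <- simulate_nvc_table(truth$coefs, vc0, des, seed = 13)
  spec <- build_model_set()[[10]]
  fit <- fit_lmm(spec, tab, method = "ML")
  form <- model_formula(spec, random = FALSE)
  ols <- lm(form, data = feederdefense:::.prepare_nvc_data(tab))
  expect_equal(unname(fit$coefficients[names(coef(ols))]),
               unname(coef(ols)), tolerance = 1e-4)
})

test_that("row order does not affect the fit", {
  des <- simulate_nvc_design(n_rows = 800, n_individuals = 15, seed = 14)
  truth <- recovery_truth()
  tab <- simulate_nvc_table(truth$coefs, truth$varcomp, des, seed = 15)
  spec <- build_model_set()[[6]]
  f1 <- fit_lmm(spec, tab, method = "REML")
  f2 <- fit_lmm(spec, tab[sample.int(nrow(tab)), ], method = "REML")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("confidence bounds are plain coef -/+ 1.96 se arithmetic", {
  b <- ci_bounds(c(1, -2), c(0.5, 0.1))
  expect_equal(b[, "ci_lower"], c(1 - 0.98, -2 - 0.196))
  expect_equal(b[, "ci_upper"], c(1 + 0.98, -2 + 0.196))
})

test_that("defense_mma averages, ranks models and exposes methods", {
  des <- simulate_nvc_design(n_rows = 2500, n_individuals = 30, seed = 16)
  truth <- recovery_truth()
  tab <- simulate_nvc_table(truth$coefs, truth$varcomp, des, seed = 17)
  fit <- defense_mma(tab)
  expect_s3_class(fit, "defense_mma")
  expect_equal(sum(fit$selection$weight), 1, tolerance = 1e-8)
  expect_equal(fit$selection$delta[1], 0)
  expect_equal(fit$selection$weight[1], max(fit$selection$weight))
  expect_equal(nrow(fit$blups), 30L)
  # reduction transform: 100 * (1 - exp(slope))
  expect_equal(fit$blups$reduction_pct,
               100 * (1 - exp(fit$blups$total_slope)))
  cf <- coef(fit)
  expect_true("spatial_concentration:spatial_stability" %in% names(cf))
  # predictions respond to the averaged coefficients
  nd <- tab[1:5, ]
  pr <- predict(fit, nd)
  expect_length(pr, 5L)
  expect_equal(exp(pr), predict(fit, nd, type = "response"))
  expect_output(print(fit), "Model selection")
  expect_output(print(summary(fit)), "Model-averaged")
  expect_length(residuals(fit), fit$n)
})

test_that("blup slope of zero leaves an individual at the population level", {
  des <- simulate_nvc_design(n_rows = 1200, n_individuals = 20, seed = 18)
  truth <- recovery_truth()
  tab <- simulate_nvc_table(truth$coefs, truth$varcomp, des, seed = 19)
  fit <- defense_mma(tab)
  b <- blup_slopes(fit)
  pop <- attr(b, "population")
  expect_equal(b$total_slope - b$blup_slope,
               rep(unname(pop["slope"]), nrow(b)))
  expect_equal(unname(pop["reduction_pct"]),
               100 * (1 - exp(unname(pop["slope"]))))
  # slope of -1 corresponds to a 63.2% reduction
  expect_equal(100 * (1 - exp(-1)), 63.2, tolerance = 1e-3)
})

test_that("random-slope support is deterministic for identical data", {
  des <- simulate_nvc_design(n_rows = 1000, n_individuals = 15, seed = 20)
  truth <- recovery_truth()
  tab <- simulate_nvc_table(truth$coefs, truth$varcomp, des, seed = 21)
  r1 <- random_slope_support(tab)
  r2 <- random_slope_support(tab)
  expect_equal(r1$delta_aicc, r2$delta_aicc)
  expect_equal(r1$delta_aicc, r1$aicc_no_slope - r1$aicc_slope)
})
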