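test_that("the three-step initializer lands near the truth on a clean curve", {
  p <- thermo_parameters(-2, 0.15, 0.005, time_unit = "day")
  cv <- noiseless_curve(p)
  init <- estimate_initial_parameters(cv)
  # heuristic accuracy: within 50% is enough to seed the optimizer
  expect_lt(abs(init$delta_G / -2 - 1), 0.5)
  expect_lt(abs(init$k_S / 0.15 - 1), 0.5)
  expect_lt(abs(init$k_off / 0.005 - 1), 0.5)
  fit <- fit_release_model(cv, init = init)
  expect_true(fit$converged)
  expect_lt(abs(fit$delta_G / -2 - 1), 1e-3)
  expect_lt(abs(fit$k_S / 0.15 - 1), 1e-3)
  expect_lt(abs(fit$k_off / 0.005 - 1), 1e-3)
})

test_that("a pure single-exponential curve reads as an all-burst profile", {
  cv <- release_curve((1:15) * 4, -expm1(-0.1 * (1:15) * 4), time_unit = "hour")
  init <- suppressWarnings(estimate_initial_parameters(cv))
  # burst estimate is most of the load -> strongly positive delta_G
  expect_gt(init$delta_G, 0)
})

test_that("minimal 4-point curves yield defined estimates", {
  p <- thermo_parameters(1, 0.3, 0.02, time_unit = "day")
  tt <- c(2, 8, 40, 90)
  cv <- release_curve(tt, cumulative_release(p, tt), time_unit = "day")
  init <- suppressWarnings(estimate_initial_parameters(cv))
  expect_true(all(is.finite(c(init$delta_G, init$k_S, init$k_off))))
  expect_error(estimate_initial_parameters(
    release_curve(c(1, 2, 3), c(0.1, 0.2, 0.3))), "4 points")
})

test_that("noiseless curves from the four category triples refit exactly", {
  for (nm in names(fig_triples)) {
    p <- triple_params(nm)
    fit <- suppressWarnings(fit_release_model(noiseless_curve(p)))
    expect_true(fit$converged)
    expect_lt(abs(fit$k_S / p$k_S - 1), 1e-3)
    expect_lt(abs(fit$k_off / p$k_off - 1), 1e-3)
    expect_lt(abs(fit$delta_G / p$delta_G - 1), 1e-3)
  }
})

test_that("refinement never worsens the initializer's SSE and the full model
           never loses to its single-exponential restriction", {
  p <- triple_params("III")
  cv <- generate_release_curve(p, n_points = 18, horizon = 100,
                               spacing = "log", noise_sd = 0.02, seed = 11)
  init <- suppressWarnings(estimate_initial_parameters(cv))
  sse_init <- sum((cumulative_release(as_rate_parameters(init), cv$times) -
                     cv$released)^2)
  fit <- fit_release_model(cv, init = init)
  expect_lte(fit$sse, sse_init + 1e-12)
  fit1 <- fit_release_model(cv, variant = "single_exponential")
  expect_lte(fit$sse, fit1$sse + 1e-12)
})

test_that("the single-exponential variant recovers k_S to machine tolerance", {
  tt <- (1:12) * 5
  cv <- release_curve(tt, -expm1(-0.192 * tt), time_unit = "minute")
  fit <- fit_release_model(cv, variant = "single_exponential")
  expect_equal(fit$k_S, 0.192, tolerance = 1e-10)
  expect_true(is.na(fit$k_off) && is.na(fit$delta_G))
})

test_that("too-short curves are rejected with a clear message", {
  cv <- release_curve(c(1, 5, 9), c(0.2, 0.5, 0.7))
  expect_error(fit_release_model(cv), "at least 4")
})

test_that("variant selection keeps the simpler model when it suffices", {
  tt <- seq(2, 60, length.out = 14)
  single <- release_curve(tt, -expm1(-0.1 * tt), time_unit = "hour")
  sel <- select_model_variant(single)
  expect_identical(sel$variant, "single_exponential")

  biphasic <- noiseless_curve(triple_params("IV"))
  sel <- suppressWarnings(select_model_variant(biphasic))
  expect_identical(sel$variant, "full")

  short <- release_curve(c(5, 10, 15, 20), c(0.1, 0.2, 0.3, 0.4))
  expect_warning(sel <- select_model_variant(short), "power")
  expect_identical(sel$variant, "single_exponential")
})

test_that("classification reproduces the four canonical category labels", {
  for (nm in names(fig_triples)) {
    expect_identical(classify_release_profile(triple_params(nm), horizon = 100),
                     nm)
  }
})

test_that("classification thresholds behave at the axes", {
  # burst axis flips at delta_G = 0 (free fraction 0.5)
  expect_identical(classify_release_profile(
    thermo_parameters(0.01, 0.2, 0.001, time_unit = "day"), 100), "I")
  expect_identical(classify_release_profile(
    thermo_parameters(-0.01, 0.2, 0.001, time_unit = "day"), 100), "II")
  # sustained axis flips at k_off * horizon = 1
  expect_identical(classify_release_profile(
    thermo_parameters(2, 0.2, 0.011, time_unit = "day"), 100), "III")
  expect_identical(classify_release_profile(
    thermo_parameters(2, 0.2, 0.009, time_unit = "day"), 100), "I")
  # a single-exponential fit is all burst by construction
  tt <- (1:10) * 5
  fit <- fit_release_model(release_curve(tt, -expm1(-0.05 * tt)),
                           variant = "single_exponential")
  expect_message(cat_lab <- classify_release_profile(fit, 100), "category I")
  expect_identical(cat_lab, "I")
})

test_that("mismatched time units are refused, not silently mixed", {
  p <- thermo_parameters(1, 0.3, 0.02, time_unit = "day")
  cv <- noiseless_curve(p)
  init_wrong <- thermo_parameters(1, 0.3, 0.02, time_unit = "hour")
  expect_error(fit_release_model(cv, init = init_wrong), "time unit")
})
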