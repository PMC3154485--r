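test_that("eigenvalues solve the characteristic quadratic in known cases", {
  e <- release_eigenvalues(rate_parameters(2, 0, 0.5))
  expect_equal(e$lambda1, 2)
  expect_equal(e$lambda2, 0.5)
  expect_false(e$repeated)

  e <- release_eigenvalues(rate_parameters(1, 1, 1))
  expect_equal(e$lambda1, (3 + sqrt(5)) / 2)
  expect_equal(e$lambda2, (3 - sqrt(5)) / 2)

  # a literature parameter row, checked through the symmetric functions
  e <- release_eigenvalues(rate_parameters(0.494, 0.0172, 0.0136,
                                           time_unit = "minute"))
  expect_equal(e$lambda1 + e$lambda2, 0.494 + 0.0172 + 0.0136,
               tolerance = 1e-10)
  expect_equal(e$lambda1 * e$lambda2, 0.494 * 0.0136, tolerance = 1e-10)
})

test_that("eigenvalue symmetric functions hold across random parameter draws", {
  for (p in random_rate_draws(40)) {
    e <- release_eigenvalues(p)
    s <- p$k_S + p$k_on + p$k_off
    expect_gte(e$lambda1, e$lambda2)
    expect_gte(e$lambda2, 0)
    expect_equal(e$lambda1 + e$lambda2, s, tolerance = 1e-10 * s)
    expect_equal(e$lambda1 * e$lambda2, p$k_S * p$k_off,
                 tolerance = 1e-10 * max(p$k_S * p$k_off, 1e-300))
  }
})

test_that("a confluent root is flagged and handled continuously", {
  # k_on = 0 with k_S = k_off collapses the discriminant exactly
  p <- rate_parameters(0.3, 0, 0.3)
  e <- release_eigenvalues(p)
  expect_true(e$repeated)
  tr <- state_fractions(p, c(0, 1, 5, 10))
  expect_true(all(is.finite(tr$released)))
  # continuity: a nearby non-degenerate parameter set gives nearly the same curve
  p2 <- rate_parameters(0.3, 0, 0.3 * (1 + 1e-5))
  expect_equal(cumulative_release(p, c(1, 5, 10)),
               cumulative_release(p2, c(1, 5, 10)), tolerance = 1e-4)
})

test_that("the trajectory starts at binding equilibrium and conserves drug", {
  p <- rate_parameters(0.15, 0.03, 0.0199, time_unit = "day")
  tr <- state_fractions(p, c(0, 0.5, 2, 10, 50))
  expect_equal(tr$free[1], 0.0199 / 0.0499)
  expect_equal(tr$bound[1], 0.03 / 0.0499)
  expect_equal(tr$released[1], 0)
  for (q in random_rate_draws(25)) {
    tr <- state_fractions(q, c(0, 0.1, 1, 4, 20, 100))
    expect_lt(max(abs(tr$free + tr$bound + tr$released - 1)), 1e-10)
    expect_true(all(tr$free >= -1e-12 & tr$free <= 1 + 1e-12))
    expect_true(all(diff(tr$released) >= -1e-12))
  }
})

test_that("with no association the free pool decays as a single exponential", {
  p <- rate_parameters(0.1, 0, 0)
  tr <- state_fractions(p, c(0, 3, 10))
  expect_equal(tr$bound, rep(0, 3))
  expect_equal(tr$free, exp(-0.1 * c(0, 3, 10)))
  expect_equal(cumulative_release(p, 10), 1 - exp(-1), tolerance = 1e-12)
})

test_that("cumulative release is 0 at t=0, monotone, and saturates at 1", {
  for (p in random_rate_draws(25)) {
    e <- release_eigenvalues(p)
    t_long <- if (e$lambda2 > 0) 60 / e$lambda2 else 60 / e$lambda1
    times <- c(0, 10^seq(-3, log10(t_long), length.out = 40))
    rel <- cumulative_release(p, times)
    expect_equal(rel[1], 0)
    expect_true(all(diff(rel) >= -1e-14))
    expect_true(all(rel <= 1 + 1e-11))
    # widely separated modes can carry large opposite-sign prefactors, so
    # the saturated sum is exact only to ~1e3 ulp in the worst draws
    expect_equal(rel[length(rel)], 1, tolerance = 1e-11)
  }
  # with well-conditioned mode weights the saturation identity is exact
  p <- rate_parameters(0.2, 0.05, 0.1)
  e <- release_eigenvalues(p)
  expect_equal(cumulative_release(p, 55 / e$lambda2), 1, tolerance = 1e-15)
})

test_that("the two biexponential prefactors sum to exactly one", {
  for (p in random_rate_draws(30)) {
    if (release_eigenvalues(p)$repeated || p$k_on + p$k_off == 0) next
    a <- nanorelease:::.release_prefactors(p)
    expect_equal(unname(sum(a)), 1, tolerance = 1e-12)
  }
})

test_that("Case 1 is the pure transport exponential", {
  expect_equal(cumulative_release_case1(0.1, 0), 0)
  expect_equal(cumulative_release_case1(0.1, log(2) / 0.1), 0.5)
  # fast telmisartan-type release: essentially complete within 80 minutes
  expect_gt(cumulative_release_case1(0.192, 80), 0.999)
})

test_that("the full solution reduces to Case 1 as k_on/k_off -> 0", {
  times <- c(0.5, 2, 10, 40)
  p <- rate_parameters(0.1, k_on = 1e-9, k_off = 0.05)
  expect_equal(cumulative_release(p, times),
               cumulative_release_case1(0.1, times), tolerance = 1e-7)
})

test_that("Case 2 matches the full solution when transport is fast, and
           otherwise over-predicts release", {
  # k_S = 1000 (k_on + k_off): the decoupling approximation is excellent
  p_fast <- rate_parameters(1000 * 0.06, k_on = 0.04, k_off = 0.02)
  times <- 10^seq(-4, 2.5, length.out = 60)
  expect_lt(max(abs(cumulative_release_case2(p_fast, times) -
                    cumulative_release(p_fast, times))), 1e-3)
  # k_S = 2 k_off: decoupling ignores the transport bottleneck -> upper bound
  p_slow <- rate_parameters(0.04, k_on = 0.03, k_off = 0.02)
  d <- cumulative_release_case2(p_slow, times) -
    cumulative_release(p_slow, times)
  expect_true(all(d >= -1e-12))
  expect_gt(max(d), 0.01)   # the gap is material, not round-off
  # pointwise domination holds generically
  for (p in random_rate_draws(20)) {
    tt <- 10^seq(-2, 2, length.out = 25)
    expect_true(all(cumulative_release_case2(p, tt) -
                      cumulative_release(p, tt) >= -1e-10))
  }
})

test_that("Case 2 endpoints behave (0 at start, 1 in the limit)", {
  p <- rate_parameters(5, 0.3, 0.1)
  expect_equal(cumulative_release_case2(p, 0), 0)
  expect_equal(cumulative_release_case2(p, 1e4), 1, tolerance = 1e-12)
})
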