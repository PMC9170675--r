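test_that("kernel density estimate is normalized and recovers a known density", {
  draws <- sim_normal_draws(0, 1, 20000, seed = 101)
  d <- estimate_posterior_density(draws, grid_size = 1024L)

  expect_lt(abs(trap(d$theta, d$density) - 1), 1e-6)
  expect_true(all(d$density >= 0))
  # the argmax wanders at the kernel mode-noise scale, sd ~ 0.07 at this n
  # (the density is flat at its peak); 0.3 is a ~4-sd bound
  expect_lt(abs(d$theta[which.max(d$density)]), 0.3)
  at0 <- approx(d$theta, d$density, xout = 0)$y
  expect_lt(abs(at0 - dnorm(0)), 0.02)
  # sup-norm consistency against the true density on [-3, 3]; pointwise noise
  # sd ~ 0.007 plus smoothing bias ~ 0.003 at the peak put the sup-norm near
  # 0.01-0.02, so 0.03 is the reliable bound at this n
  grid <- seq(-3, 3, length.out = 301)
  est <- approx(d$theta, d$density, xout = grid)$y
  expect_lt(max(abs(est - dnorm(grid))), 0.03)
})

test_that("density grid spans min - 3bw to max + 3bw and honours a bandwidth override", {
  draws <- sim_normal_draws(5, 2, 5000, seed = 7)
  d <- estimate_posterior_density(draws, bandwidth = 0.5)
  expect_equal(attr(d, "bandwidth"), 0.5)
  expect_equal(min(d$theta), min(draws) - 1.5)
  expect_equal(max(d$theta), max(draws) + 1.5)
})

test_that("degenerate or invalid draw vectors are rejected", {
  expect_error(suppressWarnings(estimate_posterior_density(c(0, 0, 0, 0))),
               class = "evtest_error_degenerate_sample")
  expect_error(estimate_posterior_density(1), class = "evtest_error_invalid_input")
  expect_error(estimate_posterior_density(c(1, NA, 3)),
               class = "evtest_error_invalid_input")
  expect_error(suppressWarnings(estimate_posterior_density(rnorm(100), grid_size = 10)),
               class = "evtest_error_invalid_input")
  expect_error(suppressWarnings(estimate_posterior_density(rnorm(100), bandwidth = -1)),
               class = "evtest_error_invalid_input")
  expect_warning(estimate_posterior_density(rnorm(100)),
                 class = "evtest_warning_few_draws")
})

test_that("reference families evaluate to their closed-form densities", {
  grid <- seq(-2, 2, by = 0.5)
  expect_equal(evaluate_reference(ref_flat(), grid), rep(1, length(grid)))
  expect_equal(evaluate_reference(ref_cauchy(0, 1), 0), 1 / pi)
  expect_equal(evaluate_reference(ref_half_cauchy(0, 1), -0.5), 0)
  expect_equal(evaluate_reference(ref_half_cauchy(0, 1), 0.5),
               2 * dcauchy(0.5))
  expect_equal(evaluate_reference(ref_normal(1, 2), 1), dnorm(0, sd = 2))
  expect_equal(evaluate_reference(ref_student_t(3), 0.7), dt(0.7, 3))
  # half-Cauchy integrates to 1 on the positive axis
  xs <- seq(0, 200, length.out = 20001)
  expect_lt(abs(trap(xs, evaluate_reference(ref_half_cauchy(0, 1), xs)) - 0.9968),
            1e-3)
})

test_that("invalid references are rejected", {
  expect_error(ref_cauchy(0, -1), class = "evtest_error_invalid_reference")
  expect_error(ref_normal(0, 0), class = "evtest_error_invalid_reference")
  expect_error(evaluate_reference(ref_custom(function(x) -x), c(1, 2)),
               class = "evtest_error_invalid_reference")
  expect_error(evaluate_reference("flat", 1:3),
               class = "evtest_error_invalid_reference")
})

test_that("surprise function is the pointwise density/reference ratio", {
  draws <- sim_normal_draws(0, 1, 5000, seed = 11)
  d <- estimate_posterior_density(draws)

  s_flat <- build_surprise(d, ref_flat())
  expect_identical(s_flat$surprise, d$density)  # flat-reference identity, exact

  s_cauchy <- build_surprise(d, ref_cauchy(0, 1))
  expect_equal(s_cauchy$surprise,
               s_cauchy$density / dcauchy(s_cauchy$theta), tolerance = 1e-12)
  # s >= 1 exactly where the posterior density exceeds the reference
  expect_identical(s_cauchy$surprise >= 1,
                   s_cauchy$density >= s_cauchy$reference)
})

test_that("a reference that misses the posterior support is a support mismatch", {
  draws <- sim_normal_draws(0, 1, 5000, seed = 13)  # half of the mass below 0
  d <- estimate_posterior_density(draws)
  expect_error(build_surprise(d, ref_half_cauchy(0, 1)),
               class = "evtest_error_support_mismatch")
  # a few stragglers below the support are tolerated (mass < 1e-3)
  pos <- sim_normal_draws(4, 1, 5000, seed = 14)
  d2 <- estimate_posterior_density(pos)
  expect_s3_class(build_surprise(d2, ref_half_cauchy(0, 1)), "fbst_surprise")
})
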