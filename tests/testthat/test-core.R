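make_surprise <- function(draws, ref = ref_flat(), ...) {
  build_surprise(estimate_posterior_density(draws, ...), ref)
}

test_that("surprise at the null is interpolated on the grid", {
  draws <- sim_normal_draws(0, 1, 20000, seed = 21)
  s <- make_surprise(draws)
  # null at the mode: s* is the curve maximum up to interpolation error
  s_star <- supremum_surprise(s, fbst_hypothesis(s$theta[which.max(s$surprise)]))
  expect_gt(s_star, max(s$surprise) * 0.999)
  # flat reference, standard normal posterior: s*(0) is the normal peak height
  expect_lt(abs(supremum_surprise(s, fbst_hypothesis(0)) - dnorm(0)), 0.02)
  expect_error(supremum_surprise(s, fbst_hypothesis(10)),
               class = "evtest_error_null_outside_support")
})

test_that("tangential region handles empty, full and disconnected cases", {
  draws <- sim_normal_draws(0, 1, 10000, seed = 22)
  s <- make_surprise(draws)

  r_empty <- tangential_region(s, max(s$surprise) + 1)
  expect_equal(nrow(r_empty), 0L)
  expect_equal(attr(r_empty, "total_mass"), 0)
  expect_equal(integrate_posterior_mass(s, r_empty), 0)

  r_full <- tangential_region(s, 0)
  expect_equal(nrow(r_full), 1L)
  expect_lt(abs(attr(r_full, "total_mass") - 1), 1e-6)
  expect_lt(abs(integrate_posterior_mass(s, r_full) - 1), 1e-6)

  # bimodal mixture: a level between trough and peaks gives two intervals
  mix <- sim_mixture_draws(c(0.5, 0.5), c(-3, 3), c(0.5, 0.5), 20000, seed = 23)
  sm <- make_surprise(mix)
  trough <- approx(sm$theta, sm$surprise, xout = 0)$y
  peak <- max(sm$surprise)
  r2 <- tangential_region(sm, (trough + peak) / 2)
  expect_equal(nrow(r2), 2L)
  expect_true(all(r2$upper[-nrow(r2)] < r2$lower[-1]))  # disjoint, sorted
  expect_equal(attr(r2, "total_mass"), sum(r2$mass))
})

test_that("posterior mass integrates correctly over explicit intervals", {
  draws <- sim_normal_draws(0, 1, 20000, seed = 24)
  d <- estimate_posterior_density(draws)
  central <- tibble::tibble(lower = -1.96, upper = 1.96, mass = NA_real_)
  expect_lt(abs(integrate_posterior_mass(d, central) - 0.95), 0.02)
  expect_error(
    integrate_posterior_mass(d, tibble::tibble(lower = -50, upper = 0)),
    class = "evtest_error_invalid_input")
})

test_that("draw-fraction e-value matches its boundary cases and the normal oracle", {
  draws <- sim_normal_draws(0, 1, 20000, seed = 25)
  s <- make_surprise(draws)
  expect_equal(e_value_montecarlo(draws, s, 0), 1)
  expect_equal(e_value_montecarlo(draws, s, max(s$surprise) + 1), 0)
  s_star <- supremum_surprise(s, fbst_hypothesis(1.96))
  expect_lt(abs(e_value_montecarlo(draws, s, s_star) -
                closed_form_normal_ev(0, 1, 1.96)), 0.01)
})

test_that("chi-square standardization reproduces the worked two-parameter case", {
  out <- standardized_e_value(0.8597, dim_theta = 2, dim_null = 1)
  expect_lt(abs(out$sev - 0.047), 0.001)
  expect_equal(out$sev_bar + out$sev, 1)

  # h = 0: F_k o F_k^{-1} is the identity
  for (x in c(0.001, 0.25, 0.5, 0.9, 0.999)) {
    expect_equal(standardized_e_value(x, dim_theta = 3, dim_null = 0)$sev_bar,
                 x, tolerance = 1e-12)
  }
  # exact boundary mapping
  expect_identical(standardized_e_value(0, dim_theta = 2, dim_null = 1),
                   list(sev_bar = 0, sev = 1))
  expect_identical(standardized_e_value(1, dim_theta = 2, dim_null = 1),
                   list(sev_bar = 1, sev = 0))
  expect_error(standardized_e_value(1.2, dim_theta = 2, dim_null = 1),
               class = "evtest_error_invalid_input")
  # strictly increasing in the e-value for fixed k > h
  xs <- seq(0.01, 0.99, by = 0.01)
  sb <- vapply(xs, function(x)
    standardized_e_value(x, dim_theta = 4, dim_null = 2)$sev_bar, numeric(1))
  expect_true(all(diff(sb) > 0))
})

test_that("asymptotic p-value analogues follow their chi-square forms", {
  expect_equal(asymptotic_ev0(0.3, 0.3, k = 1), 1)
  expect_lt(abs(asymptotic_ev0(0, 1.96, k = 1) - 0.05), 1e-3)
  dists <- seq(0, 5, by = 0.5)
  ev0s <- vapply(dists, function(d) asymptotic_ev0(0, d, k = 1), numeric(1))
  expect_true(all(diff(ev0s) < 0))  # monotone toward 0
  expect_lt(asymptotic_ev0(0, 100, k = 1), 1e-12)

  hyp11 <- fbst_hypothesis(0, 2, 1)
  expect_equal(asymptotic_pv0(0, hyp11), 1)
  expect_lt(abs(asymptotic_pv0(3.8416, hyp11) - 0.05), 1e-3)
  expect_lt(abs(asymptotic_pv0(5.9915, fbst_hypothesis(0, 3, 1)) - 0.05), 1e-3)
  expect_error(asymptotic_pv0(-1, hyp11), class = "evtest_error_invalid_input")
})

test_that("hypothesis dimensions are validated", {
  expect_error(fbst_hypothesis(0, 1, 1), class = "evtest_error_invalid_input")
  expect_error(fbst_hypothesis(0, 2, -1), class = "evtest_error_invalid_input")
  expect_error(fbst_hypothesis(NaN), class = "evtest_error_invalid_input")
  h <- fbst_hypothesis(0.5, 9, 8)
  expect_equal(h$dim_theta - h$dim_null, 1L)
})

test_that("full pipeline matches the closed-form normal e-value", {
  draws <- sim_normal_draws(1.96, 1, 20000, seed = 26)
  fit <- fbst_test(draws, null_value = 0)
  expect_lt(abs(fit$e_against - 0.95), 0.02)
  expect_equal(fit$e_against + fit$e_favor, 1)          # complementarity, exact
  expect_equal(fit$sev + fit$sev_bar, 1)
  expect_lt(abs(fit$e_against - fit$e_against_mc), 0.01) # estimator agreement
  vals <- unlist(tidy(fit)[c("e_against", "e_favor", "sev", "sev_bar", "ev0")])
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("e-value at a null on the posterior mode is small", {
  draws <- sim_normal_draws(0, 1, 20000, seed = 27)
  fit <- fbst_test(draws, null_value = 0)
  # the e-value at the mode fluctuates at the scale of the kernel-density
  # mode-location noise (sd ~ 0.05 at n = 20000); 0.25 is a ~4-sd bound
  expect_lt(fit$e_against, 0.25)
})

test_that("e-value grows with the distance of the null from the mode", {
  draws <- sim_normal_draws(0, 1, 20000, seed = 28)
  evs <- vapply(seq(0, 3, by = 0.5), function(t0)
    fbst_test(draws, null_value = t0)$e_against, numeric(1))
  expect_true(all(diff(evs) >= -1e-9))
})

test_that("scaling the reference function leaves the e-value invariant", {
  draws <- sim_normal_draws(0.5, 1, 10000, seed = 29)
  base <- function(x) dcauchy(x, 0, 1)
  f1 <- fbst_test(draws, null_value = 0, reference = ref_custom(base))
  f2 <- fbst_test(draws, null_value = 0,
                  reference = ref_custom(function(x) 7.3 * base(x)))
  expect_lt(abs(f1$e_against - f2$e_against), 1e-12)
})

test_that("a null far outside the draw range yields overwhelming evidence", {
  draws <- sim_normal_draws(-1, 0.05, 10000, seed = 30)
  fit <- fbst_test(draws, null_value = 0, dim_theta = 2, dim_null = 1)
  expect_gt(fit$e_against, 0.999)
  expect_lt(fit$sev, 0.001)
})

test_that("the worked standardization example flows through the result object", {
  res <- fbst_result(0.8597, fbst_hypothesis(0, 2, 1))
  expect_equal(res$e_favor, 0.1403, tolerance = 1e-12)
  expect_lt(abs(res$sev - 0.047), 0.001)
})

test_that("pv0 is attached only when the likelihood statistic is supplied", {
  draws <- sim_normal_draws(1, 0.5, 5000, seed = 31)
  f0 <- fbst_test(draws, null_value = 0, dim_theta = 2, dim_null = 1)
  expect_null(f0$pv0)
  f1 <- fbst_test(draws, null_value = 0, dim_theta = 2, dim_null = 1,
                  neg2_log_relative_likelihood = 3.8416)
  expect_lt(abs(f1$pv0 - 0.05), 1e-3)
})

test_that("data-frame method selects the draws column tidily", {
  df <- tibble::tibble(
    step = 1:5000,
    delta = as.numeric(sim_normal_draws(1, 0.5, 5000, seed = 32)))
  fit <- fbst_test(df, column = delta, null_value = 0)
  expect_equal(fit$parameter, "delta")
  expect_equal(fit$n_draws, 5000L)
  expect_equal(glance(fit)$reference, "flat")
  fit2 <- fbst_test(df, column = "delta", null_value = 0)
  expect_equal(fit$e_against, fit2$e_against)
})
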