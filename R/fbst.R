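#' Full Bayesian Significance Test from posterior draws
#'
#' Runs the complete FBST pipeline on posterior draws of a scalar parameter:
#' estimate the posterior density by a Gaussian kernel density estimator,
#' form the surprise function against the reference, evaluate the surprise
#' s* at the null value, locate the tangential set (all values with surprise
#' strictly above s*), and integrate the posterior over it to obtain the
#' e-value against H0. The standardized e-value, its complement, the
#' asymptotic Bayesian p-value ev0 and (when the caller supplies the
#' likelihood-ratio statistic) the frequentist p-value pv0 are filled in, and
#' a Monte-Carlo cross-check of the e-value is recorded.
#'
#' The data-frame method selects one column of draws with tidyselect
#' semantics, so results chain naturally with the pipe.
#'
#' @param x A data frame of posterior draws, or a numeric vector.
#' @param column For the data-frame method: the column holding the draws
#'   (unquoted name, string, or index). Defaults to the first column.
#' @param null_value The sharp null value theta0.
#' @param dim_theta Dimension k of the full parameter space of the model the
#'   draws came from.
#' @param dim_null Dimension h of the null set (`0 <= h < k`).
#' @param reference An [`fbst_reference`][reference]; default flat, under
#'   which the surprise function is the posterior density itself.
#' @param grid_size,bandwidth Passed to [estimate_posterior_density()].
#' @param neg2_log_relative_likelihood Optional non-negative scalar
#'   -2 lambda(m0) for the frequentist p-value pv0 ([asymptotic_pv0()]);
#'   omitted from the result when `NULL`.
#' @param standardize_distance Logical; if `TRUE`, the squared distance in
#'   ev0 is divided by the posterior variance of the draws (a standardized
#'   reading of the asymptotic distance). Default `FALSE` (raw distance).
#' @param ... Passed between methods.
#'
#' @return An object of class `fbst` with fields `e_against` (evidence
#'   against H0), `e_favor = 1 - e_against`, `s_star`, `sev` and `sev_bar`,
#'   `ev0`, optionally `pv0`, `e_against_mc` (draw-based cross-check),
#'   the hypothesis, reference label, and the grid objects used. Supports
#'   [print()], [summary()], [tidy()], [glance()], [autoplot()].
#' @examples
#' draws <- sim_normal_draws(1, 0.5, n = 5000, seed = 1)
#' fit <- fbst_test(draws, null_value = 0, dim_theta = 1, dim_null = 0)
#' fit$e_against
#' tidy(fit)
#' @export
fbst_test <- function(x, ...) UseMethod("fbst_test")

#' @rdname fbst_test
#' @export
fbst_test.data.frame <- function(x, column = 1, null_value = 0,
                                 dim_theta = 1L, dim_null = 0L,
                                 reference = ref_flat(),
                                 grid_size = 4096L, bandwidth = "silverman",
                                 neg2_log_relative_likelihood = NULL,
                                 standardize_distance = FALSE, ...) {
  loc <- tidyselect::eval_select(enquo(column), data = x)
  if (length(loc) != 1L) {
    stop_evtest("`column` must select exactly one column of draws.",
                "evtest_error_invalid_input")
  }
  draws <- x[[loc]]
  attr(draws, "parameter") <- names(loc)
  fbst_test(draws, null_value = null_value,
            dim_theta = dim_theta, dim_null = dim_null,
            reference = reference, grid_size = grid_size,
            bandwidth = bandwidth,
            neg2_log_relative_likelihood = neg2_log_relative_likelihood,
            standardize_distance = standardize_distance, ...)
}

#' @rdname fbst_test
#' @export
fbst_test.numeric <- function(x, null_value = 0, dim_theta = 1L, dim_null = 0L,
                              reference = ref_flat(),
                              grid_size = 4096L, bandwidth = "silverman",
                              neg2_log_relative_likelihood = NULL,
                              standardize_distance = FALSE, ...) {
  hyp <- fbst_hypothesis(null_value, dim_theta, dim_null)
  dens <- estimate_posterior_density(x, grid_size = grid_size,
                                     bandwidth = bandwidth)
  surp <- build_surprise(dens, reference)
  rng <- range(surp$theta)
  s_star <- if (hyp$theta0 >= rng[1] && hyp$theta0 <= rng[2]) {
    supremum_surprise(surp, hyp)
  } else {
    # the quadrature grid does not reach theta0; the kernel density itself is
    # defined on all of R, so evaluate the Gaussian kernel sum there exactly
    # (on the grid's normalization scale) instead of refusing the test
    bw <- attr(surp, "bandwidth")
    r0 <- evaluate_reference(reference, hyp$theta0)
    if (r0 == 0) {
      stop_evtest(
        "Reference function is zero at the null value; the surprise at the null is undefined.",
        "evtest_error_support_mismatch")
    }
    mean(dnorm(hyp$theta0, mean = x, sd = bw)) /
      attr(surp, "norm_const") / r0
  }
  region <- tangential_region(surp, s_star)
  e_against <- integrate_posterior_mass(surp, region)
  e_mc <- e_value_montecarlo(x, surp, s_star)
  sev <- standardized_e_value(e_against, hyp)
  mode_idx <- which.max(surp$density)
  post_mode <- surp$theta[mode_idx]
  ev0 <- asymptotic_ev0(post_mode, hyp$theta0, k = hyp$dim_theta,
                        scale = if (isTRUE(standardize_distance)) sd(x) else NULL)
  pv0 <- if (is.null(neg2_log_relative_likelihood)) NULL else
    asymptotic_pv0(neg2_log_relative_likelihood, hyp)
  structure(
    list(
      e_against = e_against,
      e_favor = 1 - e_against,
      s_star = s_star,
      sev_bar = sev$sev_bar,
      sev = sev$sev,
      ev0 = ev0,
      pv0 = pv0,
      e_against_mc = e_mc,
      posterior_mode = post_mode,
      hypothesis = hyp,
      reference = attr(surp, "ref"),
      method = "quadrature",
      distance_standardized = isTRUE(standardize_distance),
      n_draws = length(x),
      bandwidth = attr(dens, "bandwidth"),
      grid_size = as.integer(grid_size),
      parameter = attr(dens, "parameter"),
      density = dens,
      surprise = surp,
      region = region
    ),
    class = "fbst")
}

#' Assemble an FBST result from precomputed components
#'
#' Low-level constructor used by [fbst_test()] and useful when the e-value
#' has been obtained elsewhere (e.g. from a different quadrature) and only
#' the standardization and reporting layers are needed. `e_favor`,
#' `sev`/`sev_bar` are derived, never supplied, so the complementarity
#' identities hold by construction.
#'
#' @param e_against e-value against H0, in \[0, 1\].
#' @param hyp An [fbst_hypothesis()].
#' @param s_star Surprise at the null (optional, `NA` if unknown).
#' @param reference_label Text label of the reference function.
#' @param ev0,pv0 Optional asymptotic p-values.
#' @param method `"quadrature"` or `"montecarlo"`.
#'
#' @return An object of class `fbst` (without grid objects; [autoplot()]
#'   requires a full [fbst_test()] result).
#' @export
fbst_result <- function(e_against, hyp, s_star = NA_real_,
                        reference_label = "flat", ev0 = NULL, pv0 = NULL,
                        method = c("quadrature", "montecarlo")) {
  hyp <- as_fbst_hypothesis(hyp)
  method <- match.arg(method)
  sev <- standardized_e_value(e_against, hyp)
  structure(
    list(
      e_against = e_against,
      e_favor = 1 - e_against,
      s_star = s_star,
      sev_bar = sev$sev_bar,
      sev = sev$sev,
      ev0 = ev0,
      pv0 = pv0,
      e_against_mc = NULL,
      posterior_mode = NA_real_,
      hypothesis = hyp,
      reference = ref_custom(function(theta) rep(1, length(theta)),
                             label = reference_label),
      method = method,
      distance_standardized = FALSE,
      n_draws = NA_integer_,
      bandwidth = NA_real_,
      grid_size = NA_integer_,
      parameter = "theta",
      density = NULL,
      surprise = NULL,
      region = NULL
    ),
    class = "fbst")
}

#' @export
print.fbst <- function(x, ...) {
  cat(fbst_report(x), sep = "\n")
  invisible(x)
}

#' @export
summary.fbst <- function(object, ...) {
  cat(fbst_report(object), sep = "\n")
  invisible(object)
}

#' Tidy an FBST result
#'
#' @param x An [`fbst`][fbst_test] object.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble of the evidence measures;
#'   `glance()` returns a one-row tibble of the test configuration.
#' @export
#' @exportS3Method generics::tidy
tidy.fbst <- function(x, ...) {
  tibble(
    e_against = x$e_against,
    e_favor = x$e_favor,
    s_star = x$s_star,
    sev = x$sev,
    sev_bar = x$sev_bar,
    ev0 = x$ev0 %||% NA_real_,
    pv0 = x$pv0 %||% NA_real_,
    e_against_mc = x$e_against_mc %||% NA_real_
  )
}

#' @rdname tidy.fbst
#' @export
#' @exportS3Method generics::glance
glance.fbst <- function(x, ...) {
  tibble(
    parameter = x$parameter,
    null_value = x$hypothesis$theta0,
    dim_theta = x$hypothesis$dim_theta,
    dim_null = x$hypothesis$dim_null,
    reference = x$reference$label,
    method = x$method,
    n_draws = x$n_draws,
    bandwidth = x$bandwidth,
    grid_size = x$grid_size
  )
}
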