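#' Specify a sharp null hypothesis
#'
#' A sharp (precise) null hypothesis restricts the parameter to a
#' lower-dimensional subset of the parameter space, here a single point
#' `theta0`. The dimensions enter the chi-square standardization of the
#' e-value: `dim_theta` (k) is the dimension of the full parameter space of
#' the model the draws came from, and `dim_null` (h) is the dimension of the
#' null set. For a two-sample t-test on the effect size, for example, the
#' model has parameters (delta, sigma) so k = 2, and under H0 only sigma is
#' free, so h = 1.
#'
#' @param theta0 Numeric scalar, the null value of the tested parameter.
#' @param dim_theta Positive integer k, dimension of the parameter space.
#' @param dim_null Non-negative integer h, dimension of the null set;
#'   must satisfy `0 <= h < k` so the chi-square degrees of freedom
#'   `k - h` are at least 1.
#'
#' @return An object of class `fbst_hypothesis`.
#' @examples
#' fbst_hypothesis(0, dim_theta = 2, dim_null = 1)
#' @export
fbst_hypothesis <- function(theta0, dim_theta = 1L, dim_null = 0L) {
  if (!is.numeric(theta0) || length(theta0) != 1L || !is.finite(theta0)) {
    stop_evtest("`theta0` must be a single finite number.",
                "evtest_error_invalid_input")
  }
  k <- as.integer(dim_theta)
  h <- as.integer(dim_null)
  if (is.na(k) || k < 1L) {
    stop_evtest("`dim_theta` must be a positive integer.",
                "evtest_error_invalid_input")
  }
  if (is.na(h) || h < 0L || h >= k) {
    stop_evtest(
      sprintf(
        "`dim_null` must satisfy 0 <= dim_null < dim_theta (k - h >= 1); got k = %d, h = %d.",
        k, h),
      "evtest_error_invalid_input")
  }
  structure(
    list(theta0 = as.numeric(theta0), dim_theta = k, dim_null = h),
    class = "fbst_hypothesis")
}

#' @export
print.fbst_hypothesis <- function(x, ...) {
  cat(sprintf("Sharp null hypothesis H0: theta = %g  (k = %d, h = %d)\n",
              x$theta0, x$dim_theta, x$dim_null))
  invisible(x)
}

as_fbst_hypothesis <- function(x) {
  if (inherits(x, "fbst_hypothesis")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(fbst_hypothesis(x))
  stop_evtest("Supply a single null value or an `fbst_hypothesis` object.",
              "evtest_error_invalid_input")
}

# Validate a draws vector; warns (KDE reliability) below 1000 draws.
check_draws <- function(draws, name = "draws") {
  if (!is.numeric(draws)) {
    stop_evtest(sprintf("`%s` must be a numeric vector.", name),
                "evtest_error_invalid_input")
  }
  if (length(draws) < 2L) {
    stop_evtest(sprintf("`%s` must contain at least 2 draws.", name),
                "evtest_error_invalid_input")
  }
  if (!all(is.finite(draws))) {
    stop_evtest(sprintf("`%s` contains non-finite values (NA/NaN/Inf).", name),
                "evtest_error_invalid_input")
  }
  if (length(draws) < 1000L) {
    warn(sprintf(
      "Only %d posterior draws supplied; kernel density estimates are unreliable below ~1000 draws.",
      length(draws)), class = "evtest_warning_few_draws")
  }
  invisible(draws)
}
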