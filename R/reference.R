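#' Reference functions for the surprise function
#'
#' The surprise function is the ratio s(theta) = p(theta | x) / r(theta) of
#' the posterior density to a reference function r. Two canonical choices are
#' the flat reference r(theta) = 1, under which the surprise function *is*
#' the posterior density, and the model prior, under which s(theta) >= 1
#' marks parameter values corroborated by the data.
#'
#' `ref_flat()` returns 1 everywhere. `ref_normal()`, `ref_cauchy()` and
#' `ref_student_t()` are the usual location-scale densities. `ref_half_cauchy()`
#' is the Cauchy density folded onto `[location, Inf)` (twice the Cauchy
#' density above the location, 0 below), the conventional prior for
#' directional effect-size alternatives. `ref_custom()` wraps any
#' non-negative vectorized density function.
#'
#' @param location,scale,mean,sd,df Distribution parameters; scales must be
#'   positive.
#' @param fn For `ref_custom()`, a vectorized function of one argument
#'   returning non-negative densities.
#' @param label Display label for a custom reference.
#'
#' @return An object of class `fbst_reference`.
#' @examples
#' ref_cauchy(0, sqrt(2) / 2)      # "medium" Cauchy prior on an effect size
#' ref_flat()
#' @name reference
NULL

new_reference <- function(family, params, density, label) {
  structure(
    list(family = family, params = params, density = density, label = label),
    class = "fbst_reference")
}

check_scale <- function(scale, what = "scale") {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop_evtest(sprintf("Reference `%s` must be a positive finite number.", what),
                "evtest_error_invalid_reference")
  }
  as.numeric(scale)
}

#' @rdname reference
#' @export
ref_flat <- function() {
  new_reference("flat", list(),
                function(theta) rep(1, length(theta)), "flat")
}

#' @rdname reference
#' @export
ref_normal <- function(mean = 0, sd = 1) {
  sd <- check_scale(sd, "sd")
  new_reference("normal", list(mean = mean, sd = sd),
                function(theta) dnorm(theta, mean, sd),
                sprintf("normal(%g, %g)", mean, sd))
}

#' @rdname reference
#' @export
ref_cauchy <- function(location = 0, scale = 1) {
  scale <- check_scale(scale)
  new_reference("cauchy", list(location = location, scale = scale),
                function(theta) dcauchy(theta, location, scale),
                sprintf("cauchy(%g, %g)", location, scale))
}

#' @rdname reference
#' @export
ref_half_cauchy <- function(location = 0, scale = 1) {
  scale <- check_scale(scale)
  new_reference("half_cauchy", list(location = location, scale = scale),
                function(theta) {
                  ifelse(theta < location, 0,
                         2 * dcauchy(theta, location, scale))
                },
                sprintf("half_cauchy(%g, %g)", location, scale))
}

#' @rdname reference
#' @export
ref_student_t <- function(df, location = 0, scale = 1) {
  scale <- check_scale(scale)
  if (!is.numeric(df) || df <= 0) {
    stop_evtest("Reference `df` must be positive.",
                "evtest_error_invalid_reference")
  }
  new_reference("student_t", list(df = df, location = location, scale = scale),
                function(theta) dt((theta - location) / scale, df) / scale,
                sprintf("student_t(df = %g, %g, %g)", df, location, scale))
}

#' @rdname reference
#' @export
ref_custom <- function(fn, label = "custom") {
  if (!is.function(fn)) {
    stop_evtest("`fn` must be a function.", "evtest_error_invalid_reference")
  }
  new_reference("custom", list(), fn, label)
}

#' @export
print.fbst_reference <- function(x, ...) {
  cat("FBST reference function:", x$label, "\n")
  invisible(x)
}

#' Evaluate a reference function on a grid
#'
#' @param ref An [`fbst_reference`][reference] object.
#' @param grid Numeric vector of finite evaluation points.
#'
#' @return Numeric vector of non-negative reference values, one per grid
#'   point. A custom reference returning negative values is an error.
#' @examples
#' evaluate_reference(ref_cauchy(0, 1), 0)   # 1/pi
#' @export
evaluate_reference <- function(ref, grid) {
  if (!inherits(ref, "fbst_reference")) {
    stop_evtest("`ref` must be an `fbst_reference` (see `ref_flat()` etc.).",
                "evtest_error_invalid_reference")
  }
  if (!is.numeric(grid) || !all(is.finite(grid))) {
    stop_evtest("`grid` must be finite numeric.", "evtest_error_invalid_input")
  }
  r <- as.numeric(ref$density(grid))
  if (length(r) != length(grid) || anyNA(r)) {
    stop_evtest("Reference function returned NA or wrong length.",
                "evtest_error_invalid_reference")
  }
  if (any(r < 0)) {
    stop_evtest("Reference function returned negative values; a reference must be non-negative.",
                "evtest_error_invalid_reference")
  }
  r
}
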