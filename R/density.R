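#' Estimate the posterior density from draws
#'
#' Gaussian kernel density estimate of the posterior, evaluated on an equally
#' spaced grid spanning `[min(draws) - 3*bw, max(draws) + 3*bw]` and
#' renormalized so that its trapezoidal integral over the grid is exactly 1.
#' The Gaussian kernel is motivated by the Bernstein-von Mises asymptotic
#' normality of posteriors; the bandwidth defaults to Silverman's
#' rule-of-thumb ([stats::bw.nrd0()]).
#'
#' @param draws Numeric vector of posterior draws (at least 2, all finite;
#'   fewer than 1000 draws triggers a quality warning).
#' @param grid_size Number of grid points, at least 64. Default 4096.
#' @param bandwidth Either `"silverman"` or a positive numeric bandwidth in
#'   parameter units.
#'
#' @return An object of class `fbst_density`: a tibble with columns `theta`
#'   and `density`, plus attributes `bandwidth` and `parameter`.
#' @examples
#' d <- estimate_posterior_density(rnorm(2000))
#' sum(diff(d$theta) * (head(d$density, -1) + tail(d$density, -1)) / 2) # ~1
#' @export
estimate_posterior_density <- function(draws, grid_size = 4096L,
                                       bandwidth = "silverman") {
  check_draws(draws)
  name <- attr(draws, "parameter") %||% "theta"
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 64L) {
    stop_evtest("`grid_size` must be an integer >= 64.",
                "evtest_error_invalid_input")
  }
  if (var(draws) == 0) {
    stop_evtest("Draws have zero variance; the posterior sample is degenerate.",
                "evtest_error_degenerate_sample")
  }
  bw <- if (identical(bandwidth, "silverman")) {
    bw.nrd0(draws)
  } else {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
        !is.finite(bandwidth) || bandwidth <= 0) {
      stop_evtest("`bandwidth` must be \"silverman\" or a positive number.",
                  "evtest_error_invalid_input")
    }
    as.numeric(bandwidth)
  }
  kde <- density(draws, bw = bw, kernel = "gaussian", n = grid_size,
                 from = min(draws) - 3 * bw, to = max(draws) + 3 * bw)
  dens <- pmax(kde$y, 0)
  norm_const <- trapezoid(kde$x, dens)
  dens <- dens / norm_const
  structure(
    tibble(theta = kde$x, density = dens),
    bandwidth = bw, parameter = name, norm_const = norm_const,
    class = c("fbst_density", class(tibble())))
}

# Trapezoidal integral of y over x (x strictly increasing).
trapezoid <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the surprise function on the density grid
#'
#' Forms s(theta) = p(theta | x) / r(theta) pointwise on the grid of a
#' posterior density estimate. With a flat reference the surprise function
#' equals the density estimate exactly. Grid points where the reference is 0
#' while the density is positive are excluded from the evaluable range; if
#' the posterior mass on such points exceeds 1e-3 the reference does not
#' cover the posterior's support and an error is raised.
#'
#' @param density An [`fbst_density`][estimate_posterior_density] object.
#' @param ref An [`fbst_reference`][reference] object.
#'
#' @return An object of class `fbst_surprise`: a tibble with columns `theta`,
#'   `density`, `reference` and `surprise`, restricted to the evaluable
#'   range, with the reference object attached as attribute `ref`.
#' @examples
#' d <- estimate_posterior_density(rnorm(2000))
#' s <- build_surprise(d, ref_flat())
#' all(s$surprise == s$density)
#' @export
build_surprise <- function(density, ref = ref_flat()) {
  if (!inherits(density, "fbst_density")) {
    stop_evtest("`density` must come from `estimate_posterior_density()`.",
                "evtest_error_invalid_input")
  }
  r <- evaluate_reference(ref, density$theta)
  bad <- r == 0 & density$density > 0
  if (any(bad)) {
    lost <- trapezoid(density$theta, ifelse(bad, density$density, 0))
    if (lost > 1e-3) {
      stop_evtest(
        sprintf(paste0(
          "Reference function is zero on a region carrying posterior mass %.4g",
          " (> 0.001); the reference does not cover the posterior support."), lost),
        "evtest_error_support_mismatch")
    }
  }
  s <- numeric(length(r))
  pos <- r > 0
  s[pos] <- density$density[pos] / r[pos]
  # where both density and reference vanish the ratio is defined as 0
  keep <- !bad
  out <- tibble(theta = density$theta[keep],
                density = density$density[keep],
                reference = r[keep],
                surprise = s[keep])
  structure(out,
            bandwidth = attr(density, "bandwidth"),
            parameter = attr(density, "parameter"),
            norm_const = attr(density, "norm_const"),
            ref = ref,
            class = c("fbst_surprise", class(tibble())))
}
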