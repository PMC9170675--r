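#' Surprise at the null value
#'
#' Evaluates the supremum s* of the surprise function over the null set. For
#' a point null H0: theta = theta0 this is s(theta0), obtained by linear
#' interpolation between the two bracketing grid points.
#'
#' @param surprise An [`fbst_surprise`][build_surprise] object.
#' @param hyp An [fbst_hypothesis()] or a single null value.
#'
#' @return Non-negative scalar s*.
#' @export
supremum_surprise <- function(surprise, hyp) {
  hyp <- as_fbst_hypothesis(hyp)
  rng <- range(surprise$theta)
  if (hyp$theta0 < rng[1] || hyp$theta0 > rng[2]) {
    stop_evtest(
      sprintf("Null value %g lies outside the evaluable posterior range [%.4g, %.4g].",
              hyp$theta0, rng[1], rng[2]),
      "evtest_error_null_outside_support")
  }
  approx(surprise$theta, surprise$surprise, xout = hyp$theta0)$y
}

#' Tangential set of a sharp null
#'
#' The tangential set collects all parameter values whose surprise strictly
#' exceeds s*, the surprise at the null value: the values more consistent
#' with the data than the null. On a grid it is a union of maximal intervals
#' where `surprise > s_star`; interval endpoints are refined by linear
#' interpolation of the surprise function across each crossing. Grid points
#' tied exactly at s* are excluded (the defining inequality is strict).
#'
#' @param surprise An [`fbst_surprise`][build_surprise] object.
#' @param s_star Non-negative scalar, the surprise at the null.
#'
#' @return A tibble of class `fbst_region` with columns `lower`, `upper` and
#'   `mass` (posterior mass of each interval), and attribute `total_mass`.
#'   Zero rows (an empty region) is valid.
#' @export
tangential_region <- function(surprise, s_star) {
  if (!is.numeric(s_star) || length(s_star) != 1L || !is.finite(s_star) ||
      s_star < 0) {
    stop_evtest("`s_star` must be a single non-negative number.",
                "evtest_error_invalid_input")
  }
  x <- surprise$theta
  s <- surprise$surprise
  d <- surprise$density
  above <- s > s_star
  empty <- structure(
    tibble(lower = numeric(0), upper = numeric(0), mass = numeric(0)),
    total_mass = 0, class = c("fbst_region", class(tibble())))
  if (!any(above)) return(empty)

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- which(runs$values)
  lowers <- uppers <- masses <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i1 <- starts[idx[j]]
    i2 <- ends[idx[j]]
    lo <- if (i1 == 1L) x[1] else cross_point(x, s, i1 - 1L, i1, s_star)
    hi <- if (i2 == length(x)) x[length(x)] else cross_point(x, s, i2, i2 + 1L, s_star)
    lowers[j] <- lo
    uppers[j] <- hi
    masses[j] <- interval_mass(x, d, lo, hi)
  }
  out <- tibble(lower = lowers, upper = uppers, mass = masses)
  structure(out, total_mass = sum(masses),
            class = c("fbst_region", class(tibble())))
}

# abscissa where the linear interpolant of s between grid indices i and j
# crosses the level s_star
cross_point <- function(x, s, i, j, s_star) {
  if (s[j] == s[i]) return(x[j])
  x[i] + (s_star - s[i]) / (s[j] - s[i]) * (x[j] - x[i])
}

# trapezoidal posterior mass over [a, b], with density linearly interpolated
# at the (possibly off-grid) endpoints
interval_mass <- function(x, d, a, b) {
  if (b <= a) return(0)
  inner <- x > a & x < b
  xs <- c(a, x[inner], b)
  ds <- c(approx(x, d, xout = a)$y, d[inner], approx(x, d, xout = b)$y)
  trapezoid(xs, ds)
}

#' Posterior mass of a region
#'
#' Trapezoidal integral of the normalized posterior density estimate over a
#' union of disjoint intervals. With the full grid as the region the result
#' is 1 up to the normalization tolerance; an empty region has mass 0.
#'
#' @param density An [`fbst_density`][estimate_posterior_density] or
#'   [`fbst_surprise`][build_surprise] object (anything carrying `theta` and
#'   `density` columns).
#' @param region An [`fbst_region`][tangential_region] tibble, or any data
#'   frame with `lower` and `upper` columns.
#'
#' @return Scalar in \[0, 1\].
#' @export
integrate_posterior_mass <- function(density, region) {
  if (nrow(region) == 0L) return(0)
  rng <- range(density$theta)
  if (any(region$lower < rng[1] - 1e-9) || any(region$upper > rng[2] + 1e-9)) {
    stop_evtest("Region intervals fall outside the density grid range.",
                "evtest_error_invalid_input")
  }
  m <- sum(purrr::map2_dbl(region$lower, region$upper,
                           ~ interval_mass(density$theta, density$density, .x, .y)))
  min(max(m, 0), 1)
}

#' Monte-Carlo e-value estimate from the draws themselves
#'
#' Linear search over the posterior draws: the fraction of draws whose
#' (linearly interpolated) surprise value strictly exceeds s* estimates the
#' posterior mass of the tangential set, i.e. the e-value against H0. This
#' is the draw-based cross-check of the quadrature e-value; the two agree to
#' Monte-Carlo error.
#'
#' @param draws Numeric vector of posterior draws (clipped to the grid range).
#' @param surprise An [`fbst_surprise`][build_surprise] object.
#' @param s_star Non-negative scalar.
#'
#' @return Scalar in \[0, 1\].
#' @export
e_value_montecarlo <- function(draws, surprise, s_star) {
  rng <- range(surprise$theta)
  xs <- pmin(pmax(draws, rng[1]), rng[2])
  s_at <- approx(surprise$theta, surprise$surprise, xout = xs)$y
  mean(s_at > s_star)
}

#' Standardized e-value
#'
#' Maps the e-value against H0 through the asymptotic chi-square relation:
#' `sev_bar = F_{k-h}(F_k^{-1}(ev_against))` with F_d the chi-square CDF with
#' d degrees of freedom, and `sev = 1 - sev_bar`. `sev` is the probability of
#' obtaining as much or more evidence against H0, the FBST's analogue of a
#' p-value. With `h = 0` the map is the identity. Boundary inputs map
#' exactly: 0 to (0, 1) and 1 to (1, 0).
#'
#' @param ev_against e-value against H0, in \[0, 1\].
#' @param hyp An [fbst_hypothesis()], or `k`/`h` given separately.
#' @param dim_theta,dim_null Used when `hyp` is missing.
#'
#' @return Named list with elements `sev_bar` and `sev`.
#' @examples
#' standardized_e_value(0.8597, dim_theta = 2, dim_null = 1)$sev  # ~0.047
#' @export
standardized_e_value <- function(ev_against, hyp = NULL,
                                 dim_theta = 1L, dim_null = 0L) {
  if (!is.numeric(ev_against) || length(ev_against) != 1L ||
      is.na(ev_against) || ev_against < 0 || ev_against > 1) {
    stop_evtest("`ev_against` must be a single number in [0, 1].",
                "evtest_error_invalid_input")
  }
  hyp <- if (is.null(hyp)) fbst_hypothesis(0, dim_theta, dim_null)
         else as_fbst_hypothesis(hyp)
  k <- hyp$dim_theta
  h <- hyp$dim_null
  if (ev_against == 0) return(list(sev_bar = 0, sev = 1))
  if (ev_against == 1) return(list(sev_bar = 1, sev = 0))
  eps <- 1e-15  # keep the quantile function off the boundaries
  p <- min(max(ev_against, eps), 1 - eps)
  sev_bar <- pchisq(qchisq(p, df = k), df = k - h)
  list(sev_bar = sev_bar, sev = 1 - sev_bar)
}

#' Asymptotic Bayesian p-value ev0
#'
#' Large-sample approximation of the e-value in favor of H0 based on the
#' asymptotic normality of the posterior: `ev0 = 1 - F_k(d0)` with
#' `d0 = (m0 - M0)^2`, the squared Euclidean distance between the null value
#' m0 and the posterior mode M0, and F_k the chi-square CDF with k degrees of
#' freedom.
#'
#' @param posterior_mode Posterior mode M0 (argmax of the density estimate).
#' @param null_mode Null value m0 (the posterior maximizer over the null set;
#'   for a point null, theta0 itself).
#' @param k Dimension of the parameter space, a positive integer.
#' @param scale Optional positive scalar: when supplied, the distance is
#'   divided by `scale^2` (i.e. computed on the standardized parameter).
#'   The default (`NULL`) uses the raw squared distance.
#'
#' @return Scalar in \[0, 1\].
#' @export
asymptotic_ev0 <- function(posterior_mode, null_mode, k = 1L, scale = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) {
    stop_evtest("`k` must be a positive integer.", "evtest_error_invalid_input")
  }
  d0 <- (null_mode - posterior_mode)^2
  if (!is.null(scale)) {
    d0 <- d0 / check_scale(scale)^2
  }
  1 - pchisq(d0, df = k)
}

#' Asymptotic frequentist p-value pv0
#'
#' Wilks-type p-value associated with the e-value: the upper tail of the
#' chi-square distribution with k - h degrees of freedom evaluated at
#' -2 * lambda(m0), where lambda is the log relative-likelihood at the null.
#' The likelihood lives with the caller (this package only sees posterior
#' draws), so the statistic must be supplied.
#'
#' @param neg2_log_relative_likelihood Non-negative scalar, -2 lambda(m0).
#' @param hyp An [fbst_hypothesis()] carrying k and h.
#'
#' @return Scalar in \[0, 1\].
#' @export
asymptotic_pv0 <- function(neg2_log_relative_likelihood, hyp) {
  stat <- neg2_log_relative_likelihood
  if (!is.numeric(stat) || length(stat) != 1L || is.na(stat) || stat < 0) {
    stop_evtest("`neg2_log_relative_likelihood` must be a single non-negative number.",
                "evtest_error_invalid_input")
  }
  hyp <- as_fbst_hypothesis(hyp)
  1 - pchisq(stat, df = hyp$dim_theta - hyp$dim_null)
}
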