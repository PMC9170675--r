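#' Visualize an FBST result
#'
#' Draws the surprise function with the posterior mass split into the
#' tangential set (evidence against H0, blue by default) and its complement
#' (in favor of H0, red by default). The shaded ribbons are the posterior
#' density, so their areas are exactly the two e-values; with a flat
#' reference the density and the surprise curve coincide. A point marks
#' (theta0, s*). With a non-flat reference a horizontal line at s = 1
#' separates corroborated from non-corroborated parameter values and the
#' y-axis is labeled as surprise. Optional one-sided boundaries restrict the
#' shading to one side, for hypotheses whose directionality lives in the
#' posterior draws.
#'
#' @param object,x An [`fbst`][fbst_test] object from [fbst_test()] (a bare
#'   [fbst_result()] has no grids and cannot be plotted).
#' @param left_boundary,right_boundary Optional numeric: shade only at
#'   `theta >= left_boundary` / `theta <= right_boundary`. Must lie inside
#'   the grid range; when both are given, left < right.
#' @param col_against,col_favor Fill colors of the two regions.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @examples
#' fit <- fbst_test(sim_normal_draws(1, 0.5, 4000, seed = 8), null_value = 0)
#' autoplot(fit)
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fbst <- function(object, left_boundary = NULL, right_boundary = NULL,
                          col_against = "#3366CC", col_favor = "#CC3333", ...) {
  if (is.null(object$surprise)) {
    stop_evtest("This result carries no surprise grid; run `fbst_test()` to plot.",
                "evtest_error_invalid_input")
  }
  grid <- plot_grid_data(object, left_boundary, right_boundary)
  hyp <- object$hypothesis
  flat <- identical(object$reference$family, "flat")
  lab <- sprintf("e-value against H0 = %.4f,  sev(H0) = %.4f",
                 object$e_against, object$sev)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 0, ymax = .data$against_height, fill = "against H0"),
      alpha = 0.6) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 0, ymax = .data$favor_height, fill = "in favor of H0"),
      alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$surprise), linewidth = 0.6) +
    ggplot2::annotate("point", x = hyp$theta0, y = object$s_star,
                      color = col_against, size = 2.5) +
    ggplot2::scale_fill_manual(
      name = NULL, values = c("against H0" = col_against,
                              "in favor of H0" = col_favor)) +
    ggplot2::labs(
      x = object$parameter %||% "theta",
      y = if (flat) "posterior density" else "surprise s(theta)",
      title = "Full Bayesian Significance Test",
      subtitle = lab) +
    ggplot2::theme_minimal()
  if (!flat) {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                                 color = "grey40")
  }
  p
}

#' @rdname autoplot.fbst
#' @export
plot.fbst <- function(x, ...) print(autoplot(x, ...))

# Ribbon heights for the two shaded regions. Heights are the posterior
# density (so shaded areas integrate to the e-values); membership in the
# tangential set is surprise > s*, with optional one-sided boundaries
# masking the shading.
plot_grid_data <- function(object, left_boundary = NULL, right_boundary = NULL) {
  surp <- object$surprise
  rng <- range(surp$theta)
  for (b in c(left_boundary, right_boundary)) {
    if (!is.null(b) && (b < rng[1] || b > rng[2])) {
      stop_evtest(
        sprintf("Boundary %g lies outside the grid range [%.4g, %.4g].",
                b, rng[1], rng[2]),
        "evtest_error_invalid_boundary")
    }
  }
  if (!is.null(left_boundary) && !is.null(right_boundary) &&
      left_boundary >= right_boundary) {
    stop_evtest("`left_boundary` must be smaller than `right_boundary`.",
                "evtest_error_invalid_boundary")
  }
  visible <- rep(TRUE, nrow(surp))
  if (!is.null(left_boundary)) visible <- visible & surp$theta >= left_boundary
  if (!is.null(right_boundary)) visible <- visible & surp$theta <= right_boundary
  in_tangential <- surp$surprise > object$s_star
  dplyr::mutate(
    as_tibble(surp),
    in_tangential = in_tangential,
    against_height = ifelse(in_tangential & visible, .data$density, 0),
    favor_height = ifelse(!in_tangential & visible, .data$density, 0))
}

#' Write an FBST plot to a file
#'
#' Renders [autoplot.fbst()] and writes it to `path`; the graphics format is
#' chosen from the file extension (png, pdf, or svg).
#'
#' @inheritParams autoplot.fbst
#' @param result An [`fbst`][fbst_test] object.
#' @param path Output file path ending in .png, .pdf or .svg.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
plot_fbst <- function(result, path, left_boundary = NULL, right_boundary = NULL,
                      width = 7, height = 4.5, ...) {
  p <- autoplot(result, left_boundary = left_boundary,
                right_boundary = right_boundary, ...)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf", "svg")) {
    stop_evtest("Plot path must end in .png, .pdf or .svg.",
                "evtest_error_invalid_input")
  }
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
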