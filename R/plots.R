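#' Plot methods
#'
#' `autoplot()` methods (ggplot2) for the package's result types:
#'
#' * `gs_split`: per-window splitting probabilities with binomial
#'   error bars for simulated estimates.
#' * `gs_locus`: the source locus curve with the window positions.
#' * `gs_recovery`: the locus curves of each observed flux with the
#'   recovered source at their common intersection.
#' * `gs_region`: the cloud of perturbed recoveries with its convex hull.
#' * `gs_distance_map`: the distance-to-source field over the flux
#'   simplex with the inadmissible region masked.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gradsense-plots
NULL

#' @rdname gradsense-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.gs_split <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$window), y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(x = "window", y = "splitting probability",
                  title = sprintf("Splitting probabilities (%s)",
                                  attr(object, "provenance"))) +
    ggplot2::theme_minimal()
  if (any(is.finite(df$se)))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$p - 3 * .data$se, ymax = .data$p + 3 * .data$se),
      width = 0.15)
  p
}

#' @export
autoplot.gs_locus <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(data = tibble::as_tibble(w),
                        ggplot2::aes(.data$x, .data$y), shape = 3, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Source locus, P2 = %.3g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_recovery <- function(object, ...) {
  w <- object$windows
  obs <- object$observed
  N <- nrow(w)
  # contour the forward map: one flux-level curve per window
  pos <- object$position
  span <- 1.5 * max(sqrt(sum((pos - c(mean(w$x), mean(w$y)))^2)),
                    pairwise_min_sep(w))
  xs <- seq(mean(w$x) - span, mean(w$x) + span, length.out = 71)
  ys <- seq(mean(w$y) - span, mean(w$y) + span, length.out = 71)
  grid <- tidyr::expand_grid(x = xs, y = ys)
  geometry <- ws_geometry(w)
  ok <- in_domain(geometry, grid$x, grid$y)
  P <- matrix(NA_real_, nrow(grid), N)
  for (k in which(ok)) {
    P[k, ] <- tryCatch(window_system(w, c(grid$x[k], grid$y[k]))$p,
                       error = function(e) rep(NA_real_, N))
  }
  curves <- purrr::map_dfr(seq_len(N), function(i) {
    dplyr::mutate(grid, level = P[, i] - obs[i],
                  curve = sprintf("window %d", i))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$x, .data$y, z = .data$level,
                                       colour = .data$curve)) +
    ggplot2::geom_contour(breaks = 0, na.rm = TRUE) +
    ggplot2::geom_point(data = tibble::as_tibble(w),
                        ggplot2::aes(.data$x, .data$y),
                        inherit.aes = FALSE, shape = 3, size = 3) +
    ggplot2::annotate("point", x = object$position[1], y = object$position[2],
                      shape = 8, size = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Flux-ratio loci and recovered source",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_region <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$ok)
  hull <- attr(object, "hull")
  centre <- attr(object, "centre")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(data = tibble::as_tibble(object)[hull, ],
                          fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::annotate("point", x = centre[1], y = centre[2], shape = 8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Recovered-source uncertainty under flux perturbation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_distance_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$p1, .data$p3, fill = log10(.data$distance))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey70") +
    ggplot2::labs(x = "P1", y = "P3", fill = "log10 distance",
                  title = "Distance to the source across the flux simplex") +
    ggplot2::theme_minimal()
}

#' @export
tidy.gs_split <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.gs_split <- function(x, ...) {
  tibble(n_windows = nrow(x), provenance = attr(x, "provenance"),
         total = sum(x$p), n = attr(x, "n"))
}
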