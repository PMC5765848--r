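#' Source locus curves for two windows
#'
#' With only two windows, an observed splitting probability does not
#' determine the source: every source position on a one-dimensional curve
#' produces the same flux split. For windows centred at `x1`, `x2` on the
#' obstacle boundary, the Neumann-Green's function evaluated at a boundary
#' window centre reduces to `-(1/pi) ln |x_i - x0|`, so the level set
#' `P_2 = alpha` is the set of sources with a fixed distance ratio
#' `|x1 - x0| / |x2 - x0| = lambda`, `lambda = exp((2 alpha - 1) ln(d/eps))`
#' - a circle of Apollonius with respect to the two window centres
#' (their perpendicular bisector when `alpha = 1/2`), intersected with the
#' domain.
#'
#' `source_locus()` returns both the implicit function
#' `F(x0) = P_2(x0) - alpha` and a traced polyline of the curve.
#' `recover_two_windows()` is the inversion view of the same object: it
#' attaches the direction indicator (which window receives the larger
#' flux) to the locus of an observed probability.
#'
#' @param windows A two-window [window set][window_set].
#' @param alpha Observed splitting probability of window 2, in `(0, 1)`
#'   (excluding the degenerate endpoints).
#' @param n Number of polyline points to trace.
#' @param span Half-length of the traced bisector segment when
#'   `alpha = 1/2`, in units of the window separation.
#' @return An object of class `gs_locus`: a list with `alpha`, `lambda`,
#'   the implicit function `F` (vectorised over an `n x 2` matrix of
#'   source positions), a `points` tibble tracing the curve inside the
#'   domain, and the generating `windows`. `recover_two_windows()` adds a
#'   `toward` element, the index of the higher-flux window.
#' @examples
#' w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
#' locus <- source_locus(w, alpha = 0.45)
#' head(locus$points)
#' @export
source_locus <- function(windows, alpha, n = 361, span = 50) {
  assert_window_set(windows, n = 2L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort("`alpha` must lie strictly inside (0, 1); the endpoints are degenerate.")
  geometry <- ws_geometry(windows)
  eps <- ws_eps(windows)
  x1 <- c(windows$x[1], windows$y[1])
  x2 <- c(windows$x[2], windows$y[2])
  d <- sqrt(sum((x1 - x2)^2))
  lambda <- exp((2 * alpha - 1) * (log(d) - log(eps)))

  Ffun <- function(x0) {
    x0 <- as_points(x0, "x0")
    vapply(seq_len(nrow(x0)), function(i) {
      splitting_closed_form(windows, x0[i, ])$p[2] - alpha
    }, numeric(1))
  }

  pts <- trace_apollonius(x1, x2, lambda, geometry, n, span * d)
  structure(list(alpha = alpha, lambda = lambda, F = Ffun,
                 points = pts, windows = windows),
            class = "gs_locus")
}

## points of {x : |x - x1| = lambda |x - x2|} inside the domain
trace_apollonius <- function(x1, x2, lambda, geometry, n, span) {
  if (abs(lambda - 1) < 1e-12) {
    mid <- (x1 + x2) / 2
    u <- (x2 - x1) / sqrt(sum((x2 - x1)^2))
    nrm <- c(-u[2], u[1])                     # bisector direction
    t <- seq(-span, span, length.out = n)
    pts <- cbind(mid[1] + t * nrm[1], mid[2] + t * nrm[2])
  } else {
    l2 <- lambda^2
    centre <- (x1 - l2 * x2) / (1 - l2)
    radius <- lambda * sqrt(sum((x1 - x2)^2)) / abs(1 - l2)
    t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    pts <- cbind(centre[1] + radius * cos(t), centre[2] + radius * sin(t))
  }
  keep <- in_domain(geometry, pts[, 1], pts[, 2])
  tibble(x = pts[keep, 1], y = pts[keep, 2])
}

#' @export
print.gs_locus <- function(x, ...) {
  cat(sprintf(
    "# Source locus for P2 = %.4g: distance ratio |x1 - x0| / |x2 - x0| = %.6g (%d traced points)\n",
    x$alpha, x$lambda, nrow(x$points)))
  if (!is.null(x$toward))
    cat(sprintf("# higher flux at window %d: source lies on that side\n", x$toward))
  invisible(x)
}

#' @rdname source_locus
#' @export
recover_two_windows <- function(windows, alpha, n = 361) {
  locus <- source_locus(windows, alpha, n = n)
  locus$toward <- if (alpha > 0.5) 2L else 1L
  locus
}
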