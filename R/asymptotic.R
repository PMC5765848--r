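#' Matched-asymptotic splitting probabilities
#'
#' Steady-state splitting probabilities of Brownian particles emitted at a
#' point source and absorbed by small boundary windows, in the
#' narrow-escape limit where every window is small compared to the window
#' separations. The outer solution is the domain's Neumann-Green's
#' function; matching it to the logarithmic inner solutions at each window
#' yields an `(N+1) x (N+1)` linear system for the window flux
#' coefficients `A_1..A_N` and a constant `C`:
#' off-diagonal entries `ln(|x_i - x_j| / eps)`, a border of ones, zero
#' diagonal, and right-hand side `(-G(x_1, x0), ..., -G(x_N, x0), 1/pi)`.
#' The probabilities are `P_i = pi * A_i` and sum to one because planar
#' Brownian motion is recurrent.
#'
#' For two windows the system reduces to the closed form
#' `P_i = 1/2 + (pi/2) * (G(x_i, x0) - G(x_j, x0)) / ln(d / eps)`,
#' so the window with the larger Green's-function value - the window
#' nearer the source - receives the larger flux.
#'
#' `splitting_asymptotic()` works for any `N >= 1`;
#' `splitting_closed_form()` is the two-window closed form (identical to
#' the linear solve to machine precision); `window_system()` exposes the
#' raw coefficients and diagnostics.
#'
#' @param windows A [window set][window_set] on a half-plane or
#'   exterior-disk geometry.
#' @param source Source position `c(x, y)`, strictly inside the domain.
#' @param matching Inner matching-constant convention: `"log_eps"`
#'   (default) uses `ln(eps)` as in the leading-order theory;
#'   `"capacity"` replaces `eps` by the logarithmic capacity `eps / 4` of
#'   an absorbing slit of arclength `eps` in every logarithm, which
#'   removes the dominant finite-`eps` error of the leading-order
#'   formulas (the remaining error is algebraically small in `eps`).
#' @return `splitting_asymptotic()` and `splitting_closed_form()` return a
#'   tibble of class `gs_split` with columns `window`, `x`, `y`, `p` and
#'   attributes `provenance = "analytic"`, `source` and (for the solver
#'   path) the `gs_system` solution. `window_system()` returns a
#'   `gs_system` list with fields `A`, `C`, `p`, `kappa` and, for three
#'   windows, the determinant `delta123`.
#' @examples
#' w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
#' splitting_closed_form(w, source = c(1, 2))
#' splitting_asymptotic(w, source = c(1, 2))
#' @name splitting
NULL

new_split <- function(windows, p, se, n, provenance, source, extra = list()) {
  tb <- tibble(window = windows$window, x = windows$x, y = windows$y,
               p = p, se = se)
  attrs <- c(list(provenance = provenance, source = source,
                  eps = ws_eps(windows), geometry = ws_geometry(windows),
                  n = n), extra)
  for (nm in names(attrs)) attr(tb, nm) <- attrs[[nm]]
  class(tb) <- c("gs_split", class(tb))
  tb
}

#' @export
print.gs_split <- function(x, ...) {
  cat(sprintf("# Splitting probabilities (%s), source at (%.4g, %.4g)\n",
              attr(x, "provenance"), attr(x, "source")[1], attr(x, "source")[2]))
  NextMethod()
}

#' @rdname splitting
#' @export
splitting_closed_form <- function(windows, source,
                                  matching = c("log_eps", "capacity")) {
  assert_window_set(windows, n = 2L)
  assert_source(windows, source)
  geometry <- ws_geometry(windows)
  eps <- matching_eps(windows, matching)
  xs <- cbind(windows$x, windows$y)
  d <- dist2d(xs[1, , drop = FALSE], xs[2, , drop = FALSE])
  G <- green_at(geometry, xs, source)
  L <- log(d) - log(eps)
  p1 <- 1 / 2 + (pi / 2) * (G[1] - G[2]) / L
  new_split(windows, c(p1, 1 - p1), se = NA_real_, n = NA_integer_,
            provenance = "analytic", source = source)
}

#' @rdname splitting
#' @export
window_system <- function(windows, source,
                          matching = c("log_eps", "capacity")) {
  assert_window_set(windows)
  assert_source(windows, source)
  geometry <- ws_geometry(windows)
  eps <- matching_eps(windows, matching)
  N <- nrow(windows)
  xs <- cbind(windows$x, windows$y)
  M <- matrix(0, N + 1L, N + 1L)
  if (N > 1L) {
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      M[i, j] <- M[j, i] <- log(dist2d(xs[i, , drop = FALSE],
                                       xs[j, , drop = FALSE]) / eps)
    }
  }
  M[N + 1L, seq_len(N)] <- 1
  M[seq_len(N), N + 1L] <- 1
  G <- green_at(geometry, xs, source)
  B <- c(-G, 1 / pi)
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    abort("degenerate window configuration: the matching system is ill-conditioned.")
  sol <- solve(M, B)
  A <- sol[seq_len(N)]
  out <- list(A = A, C = sol[N + 1L], p = pi * A, G = G, kappa = kap,
              windows = windows, source = source)
  if (N == 3L) out$delta123 <- three_window_determinant(windows)
  structure(out, class = "gs_system")
}

#' @export
print.gs_system <- function(x, ...) {
  cat(sprintf("# Matched-asymptotic window system: N = %d, C = %.6g, cond = %.3g\n",
              length(x$A), x$C, x$kappa))
  print(tibble(window = seq_along(x$A), A = x$A, p = x$p))
  invisible(x)
}

#' @rdname splitting
#' @export
splitting_asymptotic <- function(windows, source,
                                 matching = c("log_eps", "capacity")) {
  sys <- window_system(windows, source, matching = matching)
  new_split(windows, sys$p, se = NA_real_, n = NA_integer_,
            provenance = "analytic", source = source,
            extra = list(system = sys))
}

log_sep <- function(windows, i, j, eps = ws_eps(windows)) {
  xs <- cbind(windows$x, windows$y)
  log(dist2d(xs[i, , drop = FALSE], xs[j, , drop = FALSE]) / eps)
}

## matching-constant convention: "log_eps" uses ln(eps) as printed in the
## leading-order theory; "capacity" uses the logarithmic capacity eps/4 of
## an absorbing slit of arclength eps, which is accurate to O(eps/d)
matching_eps <- function(windows, matching = c("log_eps", "capacity")) {
  matching <- match.arg(matching)
  eps <- ws_eps(windows)
  if (matching == "capacity") eps / 4 else eps
}

three_window_determinant <- function(windows) {
  L12 <- log_sep(windows, 1, 2)
  L13 <- log_sep(windows, 1, 3)
  L23 <- log_sep(windows, 2, 3)
  (L12 + L13 - L23)^2 - 4 * L12 * L13
}

#' Explicit three-window solution
#'
#' Closed-form solution of the three-window matching system obtained by
#' eliminating `A_1` and `C`: with `L_ij = ln(d_ij / eps)`,
#' `m = L_12 + L_13 - L_23` and determinant
#' `delta_123 = m^2 - 4 L_12 L_13`, the coefficients are
#' `A_2 = (m b_3 - 2 L_13 b_2) / delta_123`,
#' `A_3 = (m b_2 - 2 L_12 b_3) / delta_123` with
#' `b_i = G(x_i, x0) - G(x_1, x0) + L_1i / pi`, and
#' `A_1 = 1/pi - A_2 - A_3`. Agrees with the generic linear solve to
#' numerical round-off and is the forward map inverted by
#' [recover_source()].
#'
#' @inheritParams splitting
#' @return A `gs_system` object (see [window_system()]).
#' @examples
#' w <- windows_on_line(c(-1, 0, 1), eps = 0.1)
#' three_window_explicit(w, source = c(2, 8))
#' @export
three_window_explicit <- function(windows, source,
                                  matching = c("log_eps", "capacity")) {
  assert_window_set(windows, n = 3L)
  assert_source(windows, source)
  geometry <- ws_geometry(windows)
  eps <- matching_eps(windows, matching)
  xs <- cbind(windows$x, windows$y)
  G <- green_at(geometry, xs, source)
  L12 <- log_sep(windows, 1, 2, eps); L13 <- log_sep(windows, 1, 3, eps)
  L23 <- log_sep(windows, 2, 3, eps)
  m <- L12 + L13 - L23
  delta <- m^2 - 4 * L12 * L13
  if (abs(delta) < 1e-10)
    abort("ill-conditioned three-window configuration: determinant ~ 0.")
  b2 <- G[2] - G[1] + L12 / pi
  b3 <- G[3] - G[1] + L13 / pi
  A2 <- (m * b3 - 2 * L13 * b2) / delta
  A3 <- (m * b2 - 2 * L12 * b3) / delta
  A1 <- 1 / pi - A2 - A3
  A <- c(A1, A2, A3)
  structure(list(A = A, C = NA_real_, p = pi * A, G = G,
                 kappa = NA_real_, delta123 = delta,
                 windows = windows, source = source),
            class = "gs_system")
}

#' Directional sensitivity and detection threshold
#'
#' Measures of how well a pair of absorbing windows can sense the
#' direction of a distant source from the difference of its two fluxes.
#'
#' `sensitivity_ratio()` is the exact two-window flux difference
#' `|P_1 - P_2|` for windows a distance `d` apart on the half-plane
#' boundary and a source at distance `L` and angle `theta` from the
#' boundary normal through the window midpoint:
#' `ratio = | (1 / (2 ln(d/eps))) * ln( (d^2/4 + L^2 - L d sin(theta)) /
#' (d^2/4 + L^2 + L d sin(theta)) ) |`.
#' For `L >> d` it decays as `d |sin(theta)| / (L ln(d/eps))`.
#'
#' `detection_threshold()` is the maximum of the flux difference over
#' window placements on a disk of radius `R`, attained for the two windows
#' diametrically aligned with the source:
#' `f = ln( (L + R) / (L - R) ) / ln(2R / eps)`, which decays as
#' `2R / (L ln(2R/eps))` for large `L`
#' (`detection_threshold_asymptotic()`). For two independent particle
#' classes the joint sensitivity is the product `f^2`
#' (`detection_threshold_two_class()`), decaying as `1 / L^2`.
#'
#' @param theta Source angle(s) in radians, measured from the boundary
#'   normal (the x-axis); `theta = 0` is the symmetric position.
#' @param L Source distance(s) from the window midpoint / disk centre.
#' @param d Window separation on the half-plane boundary.
#' @param eps Window arclength (`0 < eps < d`).
#' @param R Disk radius (`eps < 2R < 2L`).
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' sensitivity_ratio(pi / 2, L = 10, d = 1, eps = 0.1)
#' detection_threshold(L = 10, R = 1, eps = 0.1)
#' detection_threshold_asymptotic(L = 10, R = 1, eps = 0.1)
#' @name sensitivity
NULL

#' @rdname sensitivity
#' @export
sensitivity_ratio <- function(theta, L, d = 1, eps = 0.1) {
  if (any(d <= 0) || any(L <= 0)) abort("`d` and `L` must be positive.")
  if (any(eps <= 0) || any(eps >= d))
    abort("`eps` must lie in (0, d): windows must be small compared to their separation.")
  num <- d^2 / 4 + L^2 - L * d * sin(theta)
  den <- d^2 / 4 + L^2 + L * d * sin(theta)
  abs(0.5 * log(num / den) / log(d / eps))
}

#' @rdname sensitivity
#' @export
detection_threshold <- function(L, R = 1, eps = 0.1) {
  if (any(L <= R)) abort("the source must lie outside the disk: L > R.")
  if (any(eps <= 0) || any(eps >= 2 * R)) abort("`eps` must lie in (0, 2R).")
  abs(log((L + R) / (L - R))) / log(2 * R / eps)
}

#' @rdname sensitivity
#' @export
detection_threshold_asymptotic <- function(L, R = 1, eps = 0.1) {
  if (any(L <= R)) abort("the source must lie outside the disk: L > R.")
  2 * R / (L * log(2 * R / eps))
}

#' @rdname sensitivity
#' @export
detection_threshold_two_class <- function(L, R = 1, eps = 0.1) {
  detection_threshold(L, R, eps)^2
}
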