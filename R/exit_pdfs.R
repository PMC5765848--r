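#' Exit densities on artificial boundaries
#'
#' First-hitting (harmonic-measure) densities of Brownian motion on the
#' artificial absorbing boundaries used by the hybrid simulator: the
#' boundary flux of the absorbing Green's function, normalized to one.
#' In recurrent planar diffusion absorption on the artificial boundary is
#' certain, so each density integrates to one over its boundary.
#'
#' * `exit_pdf_full_space()`: circle of radius `Re` seen from a source at
#'   radius `r` beyond `Re`; a Poisson-kernel form in the angle difference
#'   `dtheta`, equal to a wrapped-Cauchy density with concentration
#'   `q = Re / r`.
#' * `exit_pdf_half_space()`: half-circle of radius `Re` in the half-plane.
#'   Angles are measured from the boundary axis, so both the exit angle
#'   `theta` and the source angle `theta_src` lie in `[0, pi]`; the density
#'   is the full-space kernel symmetrized by the mirror image of the
#'   source (`K(theta - theta_src) + K(theta + theta_src)`).
#' * `exit_pdf_semistrip()`: cross-section `x2 in (0, a)` of a semi-strip
#'   of width `a`, hit from a source at distance `y1 > 0` down the strip at
#'   cross-coordinate `y2`; derived from the semi-strip Green's function
#'   with `omega = pi / a`.
#'
#' @param r Source radius (greater than `Re`).
#' @param dtheta Angle between exit point and source (any real; the
#'   density is `2*pi`-periodic).
#' @param theta Exit angle in `[0, pi]`, measured from the boundary axis.
#' @param theta_src Source angle in `[0, pi]`, same convention.
#' @param Re Radius of the artificial absorbing (half-)circle.
#' @param x2 Exit coordinate across the strip, in `(0, a)`.
#' @param y1 Source distance from the absorbing cross-section (`y1 > 0`).
#' @param y2 Source cross-strip coordinate, in `(0, a)`.
#' @param a Strip width.
#' @return Numeric vector of density values (per unit angle for the circle
#'   densities, per unit length for the strip).
#' @examples
#' exit_pdf_full_space(2, 0, Re = 1)            # 3 / (2*pi)
#' integrate(function(t) exit_pdf_full_space(2, t), 0, 2 * pi)
#' exit_pdf_half_space(3, pi / 2, pi / 2, Re = 1)
#' exit_pdf_semistrip(0.3, 0.5, 0.6, a = 1)
#' @name exit_densities
NULL

## full-space Poisson kernel in the angle difference, rho = r / Re > 1
poisson_kernel_ratio <- function(dtheta, rho) {
  (rho^2 - 1) / (rho^2 - 2 * rho * cos(dtheta) + 1) / (2 * pi)
}

#' @rdname exit_densities
#' @export
exit_pdf_full_space <- function(r, dtheta, Re = 1) {
  if (any(r <= Re)) abort("the source must lie outside the circle: r > Re.")
  poisson_kernel_ratio(dtheta, r / Re)
}

#' @rdname exit_densities
#' @export
exit_pdf_half_space <- function(r, theta, theta_src, Re = 1) {
  if (any(r <= Re)) abort("the source must lie outside the half-circle: r > Re.")
  if (any(theta < 0 | theta > pi) || any(theta_src < 0 | theta_src > pi))
    abort("angles must lie in [0, pi] (measured from the boundary axis).")
  rho <- r / Re
  poisson_kernel_ratio(theta - theta_src, rho) +
    poisson_kernel_ratio(theta + theta_src, rho)
}

#' @rdname exit_densities
#' @export
exit_pdf_semistrip <- function(x2, y1, y2, a = 1) {
  if (any(y1 <= 0)) abort("`y1` must be positive (source inside the semi-strip).")
  if (any(x2 <= 0 | x2 >= a) || any(y2 <= 0 | y2 >= a))
    abort("cross-strip coordinates must lie strictly inside (0, a).")
  w <- pi / a
  sinh(w * y1) / (2 * a) *
    (1 / (cosh(w * y1) - cos(w * (x2 + y2))) +
     1 / (cosh(w * y1) - cos(w * (x2 - y2))))
}

#' Exit-distribution objects and exact sampling
#'
#' `exit_pdf()` bundles one of the three exit densities with its boundary
#' support into an object that [sample_exit_point()] can draw from.
#' All three samplers are exact and rejection-free: the full-space density
#' is a wrapped-Cauchy law with concentration `q = Re / r`, sampled through
#' its closed-form inverse CDF, and the half-space and strip densities are
#' method-of-images symmetrizations of the same law, sampled by drawing the
#' underlying wrapped-Cauchy deviate and folding it across the reflecting
#' boundary (the fold maps the image term onto the physical support, so the
#' folded draw has exactly the target density).
#'
#' Sampling uses R's random number generator: `set.seed()` makes draws
#' reproducible.
#'
#' @param type Boundary type: `"full_space"`, `"half_space"` or
#'   `"semi_strip"`.
#' @param r,theta_src,Re,y1,y2,a Parameters of the corresponding density;
#'   see [exit_densities].
#' @param pdf An object created by `exit_pdf()`.
#' @param n Number of samples.
#' @return `exit_pdf()` returns a `gs_exit_pdf` object with fields `type`,
#'   the parameters, `density` (a function of the boundary coordinate) and
#'   `support`. `sample_exit_point()` returns `n` boundary coordinates
#'   (angles, or cross-strip positions for the strip).
#' @examples
#' pdf <- exit_pdf("full_space", r = 2, Re = 1)
#' set.seed(1)
#' hist(sample_exit_point(pdf, 1e4), breaks = 50)
#' @export
exit_pdf <- function(type = c("full_space", "half_space", "semi_strip"),
                     r = NULL, theta_src = NULL, Re = 1,
                     y1 = NULL, y2 = NULL, a = 1) {
  type <- match.arg(type)
  obj <- switch(type,
    full_space = {
      if (is.null(r) || r <= Re) abort("full-space exit pdf needs r > Re.")
      ts <- if (is.null(theta_src)) 0 else theta_src
      list(type = type, r = r, Re = Re, theta_src = ts,
           density = function(theta) exit_pdf_full_space(r, theta - ts, Re),
           support = c(0, 2 * pi))
    },
    half_space = {
      if (is.null(r) || r <= Re) abort("half-space exit pdf needs r > Re.")
      if (is.null(theta_src) || theta_src < 0 || theta_src > pi)
        abort("half-space exit pdf needs theta_src in [0, pi].")
      list(type = type, r = r, Re = Re, theta_src = theta_src,
           density = function(theta) exit_pdf_half_space(r, theta, theta_src, Re),
           support = c(0, pi))
    },
    semi_strip = {
      if (is.null(y1) || y1 <= 0) abort("semi-strip exit pdf needs y1 > 0.")
      if (is.null(y2) || y2 <= 0 || y2 >= a)
        abort("semi-strip exit pdf needs y2 in (0, a).")
      list(type = type, y1 = y1, y2 = y2, a = a,
           density = function(x2) exit_pdf_semistrip(x2, y1, y2, a),
           support = c(0, a))
    })
  structure(obj, class = "gs_exit_pdf")
}

## wrapped-Cauchy deviates on (-pi, pi] via the closed-form inverse CDF
rwrapped_cauchy <- function(n, q) {
  2 * atan(((1 - q) / (1 + q)) * tan(pi * (runif(n) - 0.5)))
}

## fold a coordinate into [0, half] given period 2 * half (reflection at 0 and half)
fold_reflect <- function(u, half) {
  u <- u %% (2 * half)
  ifelse(u > half, 2 * half - u, u)
}

#' @rdname exit_pdf
#' @export
sample_exit_point <- function(pdf, n = 1) {
  if (!inherits(pdf, "gs_exit_pdf")) abort("`pdf` must be built with `exit_pdf()`.")
  switch(pdf$type,
    full_space = {
      d <- rwrapped_cauchy(n, pdf$Re / pdf$r)
      (pdf$theta_src + d) %% (2 * pi)
    },
    half_space = {
      d <- rwrapped_cauchy(n, pdf$Re / pdf$r)
      fold_reflect(pdf$theta_src + d, pi)
    },
    semi_strip = {
      w <- pi / pdf$a
      d <- rwrapped_cauchy(n, exp(-w * pdf$y1))
      fold_reflect(pdf$y2 + d / w, pdf$a)
    })
}
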