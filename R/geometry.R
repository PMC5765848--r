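#' Domain geometries
#'
#' Constructors for the three unbounded planar domains supported by the
#' package. A geometry carries the obstacle description and dispatches the
#' correct Neumann-Green's functions, exit densities and reflection rules.
#'
#' * `half_plane()`: the domain `side * x > 0`, bounded by the vertical line
#'   `x = 0` on which absorbing windows are placed (intervals of the
#'   boundary coordinate `z`).
#' * `exterior_disk()`: free space outside a reflecting disk of radius `R`
#'   centred at the origin; windows are arcs of the circle `|x| = R`.
#' * `disk_in_strip()`: the same obstacle disk inside an infinite strip with
#'   reflecting walls at `y = -a` and `y = +a` (half-width `a > R`).
#'
#' All lengths are nondimensional; the analytic formulas scale the
#' diffusivity and injection rate to one, while the simulator keeps `D` as
#' an explicit parameter.
#'
#' @param side Which half-plane is the domain: `+1` for `x > 0` (default),
#'   `-1` for `x < 0`.
#' @param R Obstacle disk radius (`R > 0`).
#' @param a Strip half-width; the walls sit at `y = +/- a` and `a > R` is
#'   required so the disk fits inside the strip.
#'
#' @return An object of class `gs_geometry`: a list with a `type` tag
#'   (`"half_plane"`, `"exterior_disk"` or `"disk_in_strip"`) and the
#'   geometric parameters.
#' @examples
#' half_plane()
#' exterior_disk(R = 1)
#' disk_in_strip(R = 1, a = 2)
#' @name geometries
NULL

new_geometry <- function(type, ...) {
  structure(list(type = type, ...), class = "gs_geometry")
}

#' @rdname geometries
#' @export
half_plane <- function(side = 1) {
  side <- sign(side)
  if (side == 0) abort("`side` must be +1 or -1.")
  new_geometry("half_plane", side = side)
}

#' @rdname geometries
#' @export
exterior_disk <- function(R = 1) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    abort("`R` must be a single positive number.")
  new_geometry("exterior_disk", R = R)
}

#' @rdname geometries
#' @export
disk_in_strip <- function(R = 1, a = 2) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) abort("`R` must be positive.")
  if (!is.numeric(a) || length(a) != 1L || a <= R)
    abort("strip half-width `a` must exceed the disk radius `R`.")
  new_geometry("disk_in_strip", R = R, a = a)
}

#' @export
print.gs_geometry <- function(x, ...) {
  desc <- switch(x$type,
    half_plane    = sprintf("half-plane (domain %sx > 0, boundary line x = 0)",
                            if (x$side < 0) "-" else ""),
    exterior_disk = sprintf("free space outside a disk of radius R = %g", x$R),
    disk_in_strip = sprintf("disk of radius R = %g in a strip with walls at y = +/-%g",
                            x$R, x$a))
  cat("<gs_geometry> ", desc, "\n", sep = "")
  invisible(x)
}

is_geometry <- function(x) inherits(x, "gs_geometry")

## obstacle extent: radius of the smallest origin-centred circle containing
## all reflecting structure relevant to window placement
obstacle_extent <- function(windows) {
  geometry <- ws_geometry(windows)
  eps <- ws_eps(windows)
  switch(geometry$type,
    half_plane = max(abs(windows$y)) + eps / 2,
    exterior_disk = ,
    disk_in_strip = geometry$R)
}

## is a point inside the domain (strictly off the obstacle)?
in_domain <- function(geometry, x, y) {
  switch(geometry$type,
    half_plane    = geometry$side * x > 0,
    exterior_disk = x^2 + y^2 > geometry$R^2,
    disk_in_strip = x^2 + y^2 > geometry$R^2 & abs(y) < geometry$a)
}

#' Window sets on an obstacle boundary
#'
#' A window set is an ordered collection of small absorbing windows, all of
#' the same arclength `eps`, centred at points on the obstacle boundary of a
#' geometry. It is represented as a tibble with one row per window
#' (columns `window`, `x`, `y`) carrying the window size and geometry as
#' attributes, so it pipes directly into [splitting_asymptotic()],
#' [splitting_simulate()], [recover_source()] and friends.
#'
#' `windows_on_line()` places windows on the half-plane boundary at
#' boundary coordinates `z` (centres `(0, z)`); `windows_on_disk()` places
#' them at angles `theta` on the obstacle circle (centres
#' `R * (cos theta, sin theta)`).
#'
#' The matched-asymptotic formulas hold in the well-separated regime where
#' every pairwise centre distance greatly exceeds `eps`; a warning is
#' emitted when any separation drops below `5 * eps`, and separations at or
#' below `eps` are an error.
#'
#' @param z Numeric vector of boundary coordinates (half-plane).
#' @param theta Numeric vector of window-centre angles in radians
#'   (disk geometries).
#' @param eps Common window arclength (`eps > 0`). The window at centre `c`
#'   occupies the boundary interval of length `eps` centred at `c`.
#' @param geometry A [gs_geometry][geometries] object of the matching type.
#' @return A tibble of class `gs_windows` with columns `window`, `x`, `y`
#'   and attributes `eps` and `geometry`.
#' @examples
#' windows_on_line(c(-0.5, 0.5), eps = 0.1)
#' windows_on_disk(c(0, pi / 2), eps = 0.1, geometry = exterior_disk(R = 1))
#' @name window_set
NULL

new_window_set <- function(x, y, eps, geometry) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    abort("`eps` must be a single positive window size.")
  tb <- tibble(window = seq_along(x), x = as.numeric(x), y = as.numeric(y))
  out <- structure(tb, eps = eps, geometry = geometry,
                   class = c("gs_windows", class(tb)))
  check_separation(out)
  out
}

#' @rdname window_set
#' @export
windows_on_line <- function(z, eps = 0.1, geometry = half_plane()) {
  stopifnot(is_geometry(geometry))
  if (geometry$type != "half_plane")
    abort("`windows_on_line()` requires a half-plane geometry.")
  new_window_set(rep(0, length(z)), z, eps, geometry)
}

#' @rdname window_set
#' @export
windows_on_disk <- function(theta, eps = 0.1, geometry = exterior_disk()) {
  stopifnot(is_geometry(geometry))
  if (!geometry$type %in% c("exterior_disk", "disk_in_strip"))
    abort("`windows_on_disk()` requires a disk geometry.")
  R <- geometry$R
  if (eps >= pi * R)
    abort("window arclength `eps` must be smaller than half the disk perimeter.")
  new_window_set(R * cos(theta), R * sin(theta), eps, geometry)
}

ws_eps <- function(windows) attr(windows, "eps", exact = TRUE)
ws_geometry <- function(windows) attr(windows, "geometry", exact = TRUE)

is_window_set <- function(x) inherits(x, "gs_windows")

assert_window_set <- function(windows, n = NULL) {
  if (!is_window_set(windows))
    abort("`windows` must be a window set built with `windows_on_line()` or `windows_on_disk()`.")
  if (!is.null(n) && nrow(windows) != n)
    abort(sprintf("exactly %d windows are required here (got %d).", n, nrow(windows)))
  invisible(windows)
}

pairwise_min_sep <- function(windows) {
  if (nrow(windows) < 2L) return(Inf)
  d <- as.matrix(stats::dist(cbind(windows$x, windows$y)))
  min(d[upper.tri(d)])
}

check_separation <- function(windows) {
  eps <- ws_eps(windows)
  sep <- pairwise_min_sep(windows)
  if (sep <= eps)
    abort("window separation must exceed the window size `eps` (narrow-escape regime).")
  if (sep < 5 * eps)
    warn(sprintf(
      "window separation %.3g is below 5*eps = %.3g; the asymptotic formulas degrade in this regime.",
      sep, 5 * eps))
  invisible(windows)
}

## angular half-width of a window arc on the disk of radius R
window_half_angle <- function(windows) {
  ws_eps(windows) / 2 / ws_geometry(windows)$R
}

## validate a source position against geometry and windows
assert_source <- function(windows, source) {
  if (!is.numeric(source) || length(source) != 2L || !all(is.finite(source)))
    abort("`source` must be a finite numeric vector c(x, y).")
  geometry <- ws_geometry(windows)
  if (!in_domain(geometry, source[1], source[2]))
    abort("the source must lie strictly inside the domain, off the obstacle boundary.")
  invisible(source)
}
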