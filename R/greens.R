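#' Neumann-Green's functions of the unbounded domains
#'
#' Closed-form Green's functions of the Laplacian with reflecting
#' (zero normal derivative) obstacle boundaries, obtained by the method of
#' images. They are the outer solutions of the matched-asymptotic expansion
#' and the kernels from which all splitting probabilities are built.
#'
#' * `green_neumann_half_plane()`: domain `x > 0` (either side works by
#'   mirror symmetry), reflecting line `x = 0`:
#'   `G(p, q) = -(1/2pi) (ln|p - q| + ln|p - q*|)` with `q*` the mirror
#'   image of `q` across the boundary line. Its normal derivative vanishes
#'   on the line.
#' * `green_neumann_disk()`: free space outside a reflecting disk of radius
#'   `R` centred at the origin:
#'   `G(p, q) = -(1/2pi) (ln|p - q| + ln|(R^2/|p|^2) p - q|)`, the sum of a
#'   free singularity and its circle-inverted image; the radial derivative
#'   in `p` vanishes at `|p| = R`.
#' * `green_semistrip()`: semi-strip `x1 > 0`, `0 < x2 < a`, absorbing at
#'   `x1 = 0` and reflecting on the lateral walls. The eigenfunction series
#'   sums to a closed form of four logarithms plus a `min(x1, y1)/a` term,
#'   with mode frequency `omega = pi / a`. It vanishes on the absorbing end
#'   and generates the strip exit density via its boundary flux.
#'
#' @param p,q Evaluation and source points: numeric vectors `c(x, y)` or
#'   matrices with two columns (rows are recycled to a common length).
#' @param R Obstacle disk radius.
#' @param x1,x2 Evaluation point in the semi-strip (`x1 > 0`,
#'   `0 < x2 < a`); `x1` is the distance from the absorbing end and `x2`
#'   the cross-strip coordinate.
#' @param y1,y2 Source point in the semi-strip, same convention.
#' @param a Strip width (`0 < x2 < a`).
#' @return Numeric vector of Green's function values.
#' @examples
#' # vanishes for a boundary point at unit distance from the source
#' # (mirror symmetry makes both logarithms equal):
#' green_neumann_half_plane(c(0, 2), c(1, 2))
#' green_neumann_half_plane(c(1, 2), c(2, 5))
#' green_neumann_disk(c(3, 0), c(0, 2), R = 1)
#' green_semistrip(0.7, 0.4, 0.2, 0.6, a = 1)
#' @name greens_functions
NULL

as_points <- function(p, name) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) abort(sprintf("`%s` must have two columns.", name))
    return(p)
  }
  if (!is.numeric(p) || length(p) != 2L)
    abort(sprintf("`%s` must be a numeric c(x, y) or a two-column matrix.", name))
  matrix(p, ncol = 2L)
}

recycle2 <- function(p, q) {
  n <- max(nrow(p), nrow(q))
  list(p = p[rep_len(seq_len(nrow(p)), n), , drop = FALSE],
       q = q[rep_len(seq_len(nrow(q)), n), , drop = FALSE])
}

.coincidence_tol <- 1e-12

dist2d <- function(p, q) sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)

check_not_coincident <- function(d) {
  if (any(d < .coincidence_tol))
    abort("evaluation and source points coincide (logarithmic singularity).")
  invisible(d)
}

#' @rdname greens_functions
#' @export
green_neumann_half_plane <- function(p, q) {
  p <- as_points(p, "p"); q <- as_points(q, "q")
  pq <- recycle2(p, q); p <- pq$p; q <- pq$q
  if (any(p[, 1] * q[, 1] < 0))
    abort("`p` and `q` must lie on the same side of the boundary line x = 0.")
  qbar <- cbind(-q[, 1], q[, 2])
  d1 <- dist2d(p, q)
  check_not_coincident(d1)
  d2 <- dist2d(p, qbar)
  -(log(d1) + log(d2)) / (2 * pi)
}

#' @rdname greens_functions
#' @export
green_neumann_disk <- function(p, q, R = 1) {
  p <- as_points(p, "p"); q <- as_points(q, "q")
  pq <- recycle2(p, q); p <- pq$p; q <- pq$q
  rp2 <- p[, 1]^2 + p[, 2]^2
  rq2 <- q[, 1]^2 + q[, 2]^2
  tol <- 1 - 1e-9
  if (any(rp2 < (R^2) * tol) || any(rq2 < (R^2) * tol))
    abort("both points must lie outside (or on) the obstacle disk |x| >= R.")
  d1 <- dist2d(p, q)
  check_not_coincident(d1)
  pim <- p * (R^2 / rp2)                      # circle inversion of p
  d2 <- dist2d(pim, q)
  check_not_coincident(d2)
  -(log(d1) + log(d2)) / (2 * pi)
}

#' @rdname greens_functions
#' @export
green_semistrip <- function(x1, x2, y1, y2, a = 1) {
  n <- max(length(x1), length(x2), length(y1), length(y2))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  if (any(x1 < 0) || any(y1 < 0))
    abort("`x1` and `y1` must be >= 0 (distance from the absorbing end).")
  if (any(x2 <= 0 | x2 >= a) || any(y2 <= 0 | y2 >= a))
    abort("cross-strip coordinates must lie strictly inside (0, a).")
  if (any(abs(x1 - y1) < .coincidence_tol & abs(x2 - y2) < .coincidence_tol))
    abort("evaluation and source points coincide (logarithmic singularity).")
  w <- pi / a
  Pk <- function(t, phi) 1 - 2 * exp(-w * t) * cos(phi) + exp(-2 * w * t)
  dm <- abs(x1 - y1); dp <- x1 + y1
  fp <- w * (x2 + y2); fm <- w * (x2 - y2)
  -(log(Pk(dm, fp)) + log(Pk(dm, fm)) -
      log(Pk(dp, fp)) - log(Pk(dp, fm))) / (4 * pi) + pmin(x1, y1) / a
}

## Green's function value at a window centre for the matched-asymptotic
## system; dispatches on the geometry of the window set.
green_at <- function(geometry, p, q) {
  switch(geometry$type,
    half_plane    = green_neumann_half_plane(p, q),
    exterior_disk = green_neumann_disk(p, q, R = geometry$R),
    abort(sprintf(
      "no Neumann-Green's function is available for geometry '%s'; use the hybrid simulator.",
      geometry$type)))
}
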