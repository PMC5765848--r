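#' Recover the source position from observed window fluxes
#'
#' With `N >= 3` windows, the splitting probabilities determine the source
#' position: each observed flux constrains the source to a curve, and all
#' curves intersect in exactly one point (two fluxes are independent, the
#' last is redundant because the probabilities sum to one). The recovery
#' solves the nonlinear system `P_i(x0) = alpha_i`, `i = 1..N-1`, where the
#' forward map is the matched-asymptotic window system, by damped
#' Gauss-Newton iteration from multiple starting points on a polar grid.
#' Candidate roots are de-duplicated and filtered by the *full* flux
#' vector (including the redundant window): spurious pairwise curve
#' intersections fail that filter, leaving the unique common intersection.
#'
#' @param windows A [window set][window_set] with at least three windows on
#'   a half-plane or exterior-disk geometry.
#' @param observed Observed splitting probabilities: either the first
#'   `N - 1` values, or all `N` (must then sum to one within `1e-6`).
#'   All values must be positive with sum below one.
#' @param starts Optional matrix of starting points (rows `c(x, y)`);
#'   defaults to a polar multi-start grid of 8 directions times 6
#'   logarithmically spaced radii spanning `[d, 50 d]` around the windows,
#'   with `d` the minimum window separation.
#' @param tol Convergence tolerance of the Gauss-Newton step (position
#'   units).
#' @param keep_tol Maximum full-flux residual for a candidate to count as
#'   a consistent solution.
#' @param max_radius Radius of the search domain around the windows, in
#'   units of the window separation (a solver guard, not physics).
#' @return An object of class `gs_recovery`: a list with `position` (the
#'   best root), `residual` (its full-flux maximum residual), a
#'   `candidates` tibble of all distinct converged roots, `ambiguous`
#'   (TRUE when several distinct roots pass `keep_tol`), the `observed`
#'   vector and the `windows`. Use [tidy()] / [glance()] for tabular
#'   views.
#' @examples
#' w <- windows_on_line(c(-1, 0, 1), eps = 0.1, geometry = half_plane(-1))
#' p <- splitting_asymptotic(w, source = c(-2, 8))$p
#' recover_source(w, observed = p[1:2])
#' @export
recover_source <- function(windows, observed, starts = NULL,
                           tol = 1e-12, keep_tol = 1e-6, max_radius = 50) {
  assert_window_set(windows)
  N <- nrow(windows)
  if (N < 3L)
    abort("source recovery needs at least three windows; with two, use `recover_two_windows()`.")
  observed <- check_observed(observed, N)
  obs_full <- c(observed, 1 - sum(observed))

  forward <- function(x0) window_system(windows, x0)$p
  resid_all <- function(x0) max(abs(forward(x0) - obs_full))

  if (is.null(starts)) starts <- recovery_starts(windows, max_radius)
  geometry <- ws_geometry(windows)
  d <- pairwise_min_sep(windows)
  centre <- c(mean(windows$x), mean(windows$y))
  in_search <- function(p) {
    in_domain(geometry, p[1], p[2]) &&
      sqrt(sum((p - centre)^2)) <= 1.5 * max_radius * d
  }

  roots <- list()
  for (k in seq_len(nrow(starts))) {
    sol <- gauss_newton(function(x0) forward(x0)[seq_len(N - 1L)] - observed,
                        starts[k, ], tol = tol, accept = in_search)
    if (is.null(sol) || !sol$converged) next
    dup <- FALSE
    for (r in roots) if (sqrt(sum((r$x - sol$x)^2)) < 1e-4) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1L]] <- sol
  }
  if (length(roots) == 0L)
    abort("no source position consistent with the observed fluxes was found in the search domain.")

  cand <- tibble(
    x = vapply(roots, function(r) r$x[1], numeric(1)),
    y = vapply(roots, function(r) r$x[2], numeric(1)),
    residual = vapply(roots, function(r) resid_all(r$x), numeric(1)))
  cand <- dplyr::arrange(cand, .data$residual)
  consistent <- cand$residual <= keep_tol

  structure(list(
    position = c(cand$x[1], cand$y[1]),
    residual = cand$residual[1],
    candidates = cand,
    ambiguous = sum(consistent) > 1L,
    converged = consistent[1],
    observed = obs_full,
    windows = windows), class = "gs_recovery")
}

check_observed <- function(observed, N) {
  if (!is.numeric(observed) || !length(observed) %in% c(N - 1L, N))
    abort(sprintf("`observed` must hold %d (or all %d) window probabilities.", N - 1L, N))
  if (length(observed) == N) {
    if (abs(sum(observed) - 1) > 1e-6)
      abort("a full set of observed probabilities must sum to one.")
    observed <- observed[seq_len(N - 1L)]
  }
  if (any(observed <= 0) || sum(observed) >= 1)
    abort("observed probabilities must be positive with sum below one.")
  observed
}

recovery_starts <- function(windows, max_radius) {
  geometry <- ws_geometry(windows)
  d <- pairwise_min_sep(windows)
  centre <- c(mean(windows$x), mean(windows$y))
  radii <- exp(seq(log(d), log(max_radius * d), length.out = 6))
  if (geometry$type == "exterior_disk") radii <- radii + geometry$R
  angles <- switch(geometry$type,
    half_plane = seq(-0.45 * pi, 0.45 * pi, length.out = 8),
    seq(0, 2 * pi, length.out = 9)[-9])
  dirs <- if (geometry$type == "half_plane") {
    cbind(geometry$side * cos(angles), sin(angles))
  } else {
    cbind(cos(angles), sin(angles))
  }
  starts <- do.call(rbind, lapply(radii, function(r) {
    cbind(centre[1] + r * dirs[, 1], centre[2] + r * dirs[, 2])
  }))
  ok <- in_domain(geometry, starts[, 1], starts[, 2])
  starts[ok, , drop = FALSE]
}

## damped Gauss-Newton with central-difference Jacobian; `accept` keeps
## iterates inside the domain/search region
gauss_newton <- function(fn, x0, tol = 1e-12, max_iter = 60, accept = NULL) {
  x <- x0
  f <- tryCatch(fn(x), error = function(e) NULL)
  if (is.null(f) || !all(is.finite(f))) return(NULL)
  for (it in seq_len(max_iter)) {
    h <- pmax(1e-7, 1e-7 * abs(x))
    J <- matrix(0, length(f), 2L)
    for (j in 1:2) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h[j]; xm[j] <- xm[j] - h[j]
      fp <- tryCatch(fn(xp), error = function(e) NULL)
      fm <- tryCatch(fn(xm), error = function(e) NULL)
      if (is.null(fp) || is.null(fm)) return(NULL)
      J[, j] <- (fp - fm) / (2 * h[j])
    }
    step <- tryCatch(qr.solve(J, -f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn_ok <- is.null(accept) || accept(xn)
      fnew <- if (fn_ok) tryCatch(fn(xn), error = function(e) NULL) else NULL
      if (!is.null(fnew) && all(is.finite(fnew)) &&
          sum(fnew^2) <= sum(f^2) * (1 - 1e-4 * lam) + 1e-30) break
      lam <- lam / 2
      if (lam < 1e-10) return(list(x = x, f = f, converged = sum(f^2) < 1e-20))
    }
    moved <- sqrt(sum((lam * step)^2))
    x <- xn; f <- fnew
    if (moved < tol || sum(f^2) < 1e-28)
      return(list(x = x, f = f, converged = TRUE))
  }
  list(x = x, f = f, converged = sum(f^2) < 1e-16)
}

#' @export
print.gs_recovery <- function(x, ...) {
  cat(sprintf("# Recovered source position: (%.6g, %.6g), max flux residual %.3g\n",
              x$position[1], x$position[2], x$residual))
  if (x$ambiguous)
    cat("# WARNING: several distinct candidate positions pass the consistency filter\n")
  if (nrow(x$candidates) > 1L)
    cat(sprintf("# %d distinct converged roots (spurious pairwise intersections filtered by the full flux vector)\n",
                nrow(x$candidates)))
  invisible(x)
}

#' @export
tidy.gs_recovery <- function(x, ...) x$candidates

#' @export
glance.gs_recovery <- function(x, ...) {
  # extract before building: tibble's mask would shadow `x` with the column
  pos <- x$position; res <- x$residual; nc <- nrow(x$candidates)
  amb <- x$ambiguous; conv <- x$converged
  tibble(x = pos[1], y = pos[2], residual = res,
         n_candidates = nc, ambiguous = amb, converged = conv)
}

#' Uncertainty region of a recovered source under flux perturbation
#'
#' Propagates small multiplicative perturbations of the observed fluxes
#' through the recovery: the first two observations are perturbed as
#' `alpha0 * (1 + eta_1)`, `beta0 * (1 + eta_2)` over a regular grid of
#' the box `[-eta, eta]^2` (including all sign corners), each perturbed
#' system is re-inverted (warm-started from the unperturbed solution), and
#' the image of the box is returned as a point cloud with its convex hull.
#' The region always contains the unperturbed solution (`eta_1 = eta_2 =
#' 0` is a grid point) and its area grows with the source distance,
#' reflecting the nonlinear flux-to-distance relationship.
#'
#' @inheritParams recover_source
#' @param eta Perturbation amplitude (`eta >= 0`); `eta = 0` degenerates
#'   to the single unperturbed solution.
#' @param n_grid Odd number of grid points per box edge.
#' @return A tibble of class `gs_region` with one row per grid node:
#'   `eta1`, `eta2`, recovered `x`, `y`, and `ok` (FALSE where the
#'   perturbed system had no solution). Attributes: `centre` (unperturbed
#'   solution), `hull` (row indices of the convex hull), `area` (shoelace
#'   area of the hull) and `partial` (TRUE if any node failed).
#' @examples
#' w <- windows_on_line(c(-1, 0, 1), eps = 0.1, geometry = half_plane(-1))
#' p <- splitting_asymptotic(w, source = c(-2, 8))$p
#' region <- recovery_region(w, observed = p[1:2], eta = 0.005, n_grid = 5)
#' attr(region, "area")
#' @export
recovery_region <- function(windows, observed, eta = 0.005, n_grid = 11,
                            keep_tol = 1e-6) {
  assert_window_set(windows)
  N <- nrow(windows)
  observed <- check_observed(observed, N)
  if (eta < 0) abort("`eta` must be non-negative.")
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L

  base <- recover_source(windows, observed, keep_tol = keep_tol)
  centre <- base$position
  etas <- if (eta == 0) 0 else seq(-eta, eta, length.out = n_grid)
  grid <- expand.grid(eta1 = etas, eta2 = etas)

  forward <- function(x0) window_system(windows, x0)$p
  geometry <- ws_geometry(windows)
  solve_one <- function(e1, e2) {
    obs <- observed
    obs[1] <- obs[1] * (1 + e1)
    obs[2] <- obs[2] * (1 + e2)
    if (any(obs <= 0) || sum(obs) >= 1) return(NULL)
    sol <- gauss_newton(function(x0) forward(x0)[seq_len(N - 1L)] - obs,
                        centre,
                        accept = function(p) in_domain(geometry, p[1], p[2]))
    if (is.null(sol) || !sol$converged) return(NULL)
    sol$x
  }

  pts <- purrr::map2(grid$eta1, grid$eta2, solve_one)
  ok <- !vapply(pts, is.null, logical(1))
  out <- tibble(
    eta1 = grid$eta1, eta2 = grid$eta2,
    x = vapply(pts, function(p) if (is.null(p)) NA_real_ else p[1], numeric(1)),
    y = vapply(pts, function(p) if (is.null(p)) NA_real_ else p[2], numeric(1)),
    ok = ok)

  hull <- if (sum(ok) >= 3L) {
    idx <- which(ok)
    idx[grDevices::chull(out$x[idx], out$y[idx])]
  } else which(ok)
  area <- polygon_area(out$x[hull], out$y[hull])

  structure(out, centre = centre, hull = hull, area = area,
            partial = any(!ok), class = c("gs_region", class(out)))
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  i2 <- c(seq_len(n)[-1L], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Distance-flux maps for three windows
#'
#' For a fixed three-window arrangement, maps each admissible pair of
#' fluxes `(P1, P3)` (with `P2 = 1 - P1 - P3 > 0`) to the distance of the
#' source that produces it, by inverting the window system on a grid over
#' the flux simplex. Inadmissible flux combinations are masked, not
#' errors. The distance is measured from the centroid of the windows
#' (half-plane) or the disk centre.
#'
#' @inheritParams recover_source
#' @param n Grid resolution per flux axis.
#' @param margin Distance to the simplex boundary below which cells are
#'   masked (the inversion degenerates as any flux approaches 0 or the
#'   pair approaches the diagonal).
#' @return A tibble of class `gs_distance_map` with columns `p1`, `p3`,
#'   `admissible`, recovered `x`, `y` and `distance` (NA where masked or
#'   unsolvable).
#' @examples
#' w <- windows_on_line(c(-1, 0, 1), eps = 0.1)
#' dm <- distance_map(w, n = 11)
#' @export
distance_map <- function(windows, n = 41, margin = 0.02, keep_tol = 1e-6) {
  assert_window_set(windows, n = 3L)
  geometry <- ws_geometry(windows)
  ref <- if (geometry$type == "half_plane") {
    c(mean(windows$x), mean(windows$y))
  } else c(0, 0)

  ps <- seq(margin, 1 - margin, length.out = n)
  grid <- expand.grid(p1 = ps, p3 = ps)
  grid$admissible <- grid$p1 + grid$p3 < 1 - margin

  N <- nrow(windows)
  forward <- function(x0) window_system(windows, x0)$p
  xs <- rep(NA_real_, nrow(grid)); ys <- rep(NA_real_, nrow(grid))
  warm <- NULL
  for (k in seq_len(nrow(grid))) {
    if (!grid$admissible[k]) { warm <- NULL; next }
    obs <- c(grid$p1[k], 1 - grid$p1[k] - grid$p3[k])
    sol <- NULL
    if (!is.null(warm)) {
      sol <- gauss_newton(function(x0) forward(x0)[1:2] - obs, warm,
                          accept = function(p) in_domain(geometry, p[1], p[2]))
      if (!is.null(sol) && (!sol$converged || max(abs(sol$f)) > keep_tol)) sol <- NULL
    }
    if (is.null(sol)) {
      rec <- tryCatch(recover_source(windows, obs, keep_tol = keep_tol),
                      error = function(e) NULL)
      if (!is.null(rec) && rec$converged)
        sol <- list(x = rec$position, converged = TRUE)
    }
    if (!is.null(sol)) {
      xs[k] <- sol$x[1]; ys[k] <- sol$x[2]
      warm <- sol$x
    } else warm <- NULL
  }
  out <- tibble(p1 = grid$p1, p3 = grid$p3, admissible = grid$admissible,
                x = xs, y = ys,
                distance = sqrt((xs - ref[1])^2 + (ys - ref[2])^2))
  structure(out, reference = ref, class = c("gs_distance_map", class(out)))
}
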