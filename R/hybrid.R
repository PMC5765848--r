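#' Hybrid analytical-stochastic splitting simulation
#'
#' Monte-Carlo estimation of window splitting probabilities without ever
#' tracking Brownian excursions through unbounded space. Each trajectory
#' is placed directly on an artificial inner boundary (a half-circle or
#' circle of radius `re` around the windows, or the strip cross-section at
#' `|x| = de`) by sampling the exact first-hitting density of that
#' boundary seen from the source. Inside the working region the trajectory
#' follows Euler steps `x <- x + sqrt(2 D dt) w`; a step segment crossing
#' the obstacle is absorbed if it crosses a window and specularly
#' reflected otherwise. When the trajectory leaves the outer boundary
#' (radius `ro`, or `|x| > do` in the strip) it is re-injected on the
#' inner boundary through the same exit density seen from the escape
#' point - exact because the obstacle lies entirely inside the inner
#' boundary - so absorption at some window is certain (planar Brownian
#' motion is recurrent) and arrival times are deliberately not tracked.
#'
#' The fine time step obeys `sqrt(4 D dt) = eps / 3`, resolving the window
#' scale; away from the windows (and from the curved obstacle, where
#' specular reflection requires short chords) the step grows with the
#' distance to the nearest absorbing structure, keeping the root mean
#' square displacement at one third of that distance. Reflections at
#' straight boundaries are exact folds at any step size.
#'
#' @param windows A [window set][window_set] on any of the three
#'   geometries.
#' @param source Source position `c(x, y)`; must lie outside the inner
#'   artificial boundary.
#' @param n Number of independent trajectories.
#' @param seed Integer seed; the same seed reproduces the estimate
#'   exactly.
#' @param re Inner (injection) radius; default 1.5 times the obstacle
#'   extent. For the strip geometry this is the injection abscissa `de`.
#' @param ro Outer (escape) radius; default 3 times the obstacle extent.
#'   For the strip geometry this is the escape abscissa `do`.
#' @param dt Fine time step; default `eps^2 / (36 D)` from the
#'   `sqrt(4 D dt) = eps/3` rule. A value with `sqrt(4 D dt) >= eps`
#'   triggers a warning: the mean-square displacement per step must stay
#'   below the window size.
#' @param D Diffusivity (the splitting probabilities do not depend on it;
#'   it only scales time).
#' @param max_reinject Safety cap on re-injections per trajectory; hitting
#'   it indicates mis-sized `re` / `ro` and raises an error.
#' @return A tibble of class `gs_split` with columns `window`, `x`, `y`,
#'   `p` (absorption frequencies, summing to one exactly), `se` (binomial
#'   standard errors `sqrt(p (1 - p) / n)`), and attributes `provenance =
#'   "simulated"`, `counts`, `config` (the resolved simulation
#'   parameters) and step/re-injection diagnostics.
#' @examples
#' w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
#' splitting_simulate(w, source = c(1, 2), n = 2000, seed = 1)
#' @export
splitting_simulate <- function(windows, source, n = 1e5, seed = 1,
                               re = NULL, ro = NULL, dt = NULL, D = 1,
                               max_reinject = 1e4) {
  assert_window_set(windows)
  assert_source(windows, source)
  if (n < 1) abort("`n` must be at least 1.")
  geometry <- ws_geometry(windows)
  eps <- ws_eps(windows)
  extent <- obstacle_extent(windows)
  if (is.null(re)) re <- 1.5 * extent
  if (is.null(ro)) ro <- 3 * extent
  if (!(ro > re && re > extent * (1 - 1e-12)))
    abort("need outer > inner artificial boundary > obstacle extent (ro > re > extent).")
  if (is.null(dt)) dt <- eps^2 / (36 * D)
  if (sqrt(4 * D * dt) >= eps)
    warn("time step too coarse: sqrt(4 D dt) should stay below the window size eps.")

  res <- switch(geometry$type,
    half_plane = {
      sx <- geometry$side * source[1]
      if (sqrt(sx^2 + source[2]^2) <= re)
        abort("the source must lie outside the inner artificial boundary (|x0| > re).")
      gs_run_halfplane(windows$y, eps, sx, source[2], re, ro, dt, D,
                       as.integer(n), as.integer(max_reinject), seed)
    },
    exterior_disk = {
      if (sqrt(sum(source^2)) <= re)
        abort("the source must lie outside the inner artificial boundary (|x0| > re).")
      gs_run_disk(atan2(windows$y, windows$x), window_half_angle(windows),
                  geometry$R, source[1], source[2], re, ro, dt, D,
                  as.integer(n), as.integer(max_reinject), seed)
    },
    disk_in_strip = {
      if (abs(source[1]) <= re)
        abort("the source must lie beyond the injection abscissa (|x0| > de).")
      gs_run_strip(atan2(windows$y, windows$x), window_half_angle(windows),
                   geometry$R, geometry$a, source[1], source[2], re, ro,
                   dt, D, as.integer(n), as.integer(max_reinject), seed)
    })

  if (res$capped > 0)
    abort(sprintf(
      "%d trajectories hit the re-injection cap (%d); re/ro are mis-sized for this scenario.",
      res$capped, max_reinject))

  counts <- res$counts
  p <- counts / n
  se <- sqrt(p * (1 - p) / n)
  cfg <- list(n = n, seed = seed, re = re, ro = ro, dt = dt, D = D,
              max_reinject = max_reinject, eps = eps)
  new_split(windows, p, se, n = n, provenance = "simulated", source = source,
            extra = list(counts = counts, config = cfg,
                         steps = res$steps, reinjections = res$reinjections,
                         max_reinjections = res$max_reinjections))
}

#' Euler step of planar Brownian motion
#'
#' Advances one or more positions by a single Euler increment
#' `x <- x + sqrt(2 D dt) w`, with `w` a pair of independent standard
#' normal deviates per position (so the mean-square planar displacement is
#' `4 D dt`). Uses R's RNG: `set.seed()` makes the trajectory
#' reproducible.
#'
#' @param pos A position `c(x, y)` or an `n x 2` matrix of positions.
#' @param dt Time step (`> 0`).
#' @param D Diffusivity (`>= 0`).
#' @return Positions in the same shape as `pos`.
#' @examples
#' set.seed(1)
#' euler_step(c(0, 0), dt = 1e-3)
#' @export
euler_step <- function(pos, dt, D = 1) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (D < 0) abort("`D` must be non-negative.")
  vec <- !is.matrix(pos)
  p <- as_points(pos, "pos")
  s <- sqrt(2 * D * dt)
  out <- p + s * matrix(rnorm(2L * nrow(p)), ncol = 2L)
  if (vec) drop(out) else out
}

#' Injection onto the inner artificial boundary
#'
#' Draws starting points on the inner artificial boundary from the exact
#' exit (harmonic-measure) density seen from the source - the first step
#' of the hybrid algorithm. Uses R's RNG.
#'
#' @inheritParams splitting_simulate
#' @param n Number of injection points.
#' @return An `n x 2` matrix of positions on the inner boundary.
#' @examples
#' w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
#' set.seed(1)
#' inject(w, source = c(2, 1), n = 5)
#' @export
inject <- function(windows, source, re = NULL, n = 1) {
  assert_window_set(windows)
  assert_source(windows, source)
  geometry <- ws_geometry(windows)
  if (is.null(re)) re <- 1.5 * obstacle_extent(windows)
  switch(geometry$type,
    half_plane = {
      sx <- geometry$side * source[1]
      r <- sqrt(sx^2 + source[2]^2)
      if (r <= re) abort("the source must lie outside the inner boundary.")
      pdf <- exit_pdf("half_space", r = r, theta_src = atan2(sx, source[2]),
                      Re = re)
      th <- sample_exit_point(pdf, n)
      cbind(x = geometry$side * re * sin(th), y = re * cos(th))
    },
    exterior_disk = {
      r <- sqrt(sum(source^2))
      if (r <= re) abort("the source must lie outside the inner boundary.")
      pdf <- exit_pdf("full_space", r = r,
                      theta_src = atan2(source[2], source[1]), Re = re)
      th <- sample_exit_point(pdf, n)
      cbind(x = re * cos(th), y = re * sin(th))
    },
    disk_in_strip = {
      if (abs(source[1]) <= re)
        abort("the source must lie beyond the injection abscissa.")
      a <- geometry$a
      pdf <- exit_pdf("semi_strip", y1 = abs(source[1]) - re,
                      y2 = source[2] + a, a = 2 * a)
      u <- sample_exit_point(pdf, n)
      cbind(x = sign(source[1]) * re, y = u - a)
    })
}

#' Classify a single Euler move against the obstacle
#'
#' Applies the simulator's segment rule to one proposed move: a segment
#' crossing the obstacle boundary inside a window is absorbed; crossing
#' elsewhere is specularly reflected (an exact fold for the straight
#' half-plane boundary, tangent reflection for the disk); an endpoint
#' beyond the outer boundary escapes; anything else continues.
#'
#' @inheritParams splitting_simulate
#' @param from,to Start and proposed end of the move, `c(x, y)`.
#' @return A list with `status` (`"continue"`, `"absorbed"` or
#'   `"escaped"`), `window` (index, for absorption) and `position` (the
#'   reflected/final position otherwise).
#' @examples
#' w <- windows_on_line(0, eps = 0.1)
#' resolve_step(w, from = c(0.05, 0), to = c(-0.05, 0))
#' @export
resolve_step <- function(windows, from, to, ro = NULL) {
  assert_window_set(windows)
  geometry <- ws_geometry(windows)
  if (is.null(ro)) ro <- 3 * obstacle_extent(windows)
  res <- switch(geometry$type,
    half_plane = {
      s <- geometry$side
      r <- gs_step_halfplane(windows$y, ws_eps(windows),
                             c(s * from[1], from[2]), c(s * to[1], to[2]), ro)
      if (!is.null(r$position)) r$position[1] <- s * r$position[1]
      r
    },
    exterior_disk = gs_step_disk(atan2(windows$y, windows$x),
                                 window_half_angle(windows), geometry$R,
                                 from, to, ro),
    abort("single-step classification is implemented for the half-plane and disk geometries."))
  list(status = c("continue", "absorbed", "escaped")[res$status + 1L],
       window = res$window,
       position = res$position)
}
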