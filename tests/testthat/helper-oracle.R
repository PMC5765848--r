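# Independent spectral solver for the mixed Dirichlet/Neumann splitting
# problem, used as ground truth for the asymptotics and the simulator.
#
# The splitting probability to window 1 equals u(x0), where u is harmonic
# in the domain with u = 1 on window 1, u = 0 on the other windows and
# zero normal derivative on the reflecting boundary. A conformal map sends
# the domain to the unit disk (where windows become boundary arcs and the
# reflecting rest keeps its Neumann condition); u is expanded in a Fourier
# basis fitted by least squares on a dense boundary grid and evaluated at
# the mapped source. Accuracy is limited only by the basis size (the edge
# singularities give algebraic convergence; ~1e-3 at n_modes = 400).

# u at w0 for arcs (list of c(lo, hi), counter-clockwise) with values uvals
fit_disk_mixed_bvp <- function(arcs, uvals, w0, n_modes = 400,
                               n_col = 8 * n_modes) {
  r0 <- Mod(w0); t0 <- Arg(w0)
  th <- seq(0, 2 * pi, length.out = n_col + 1)[-(n_col + 1)]
  in_arc <- function(th, a) {
    d <- (th - a[1]) %% (2 * pi)
    d <= (a[2] - a[1]) %% (2 * pi)
  }
  which_arc <- rep(0L, n_col)
  for (k in seq_along(arcs)) which_arc[in_arc(th, arcs[[k]])] <- k
  dirichlet <- which_arc > 0
  A <- matrix(0, n_col, 2 * n_modes + 1)
  A[dirichlet, 1] <- 1
  rhs <- numeric(n_col)
  for (k in seq_along(arcs)) rhs[which_arc == k] <- uvals[k]
  for (n in seq_len(n_modes)) {
    cn <- cos(n * th); sn <- sin(n * th)
    A[dirichlet, 2 * n] <- cn[dirichlet]
    A[dirichlet, 2 * n + 1] <- sn[dirichlet]
    A[!dirichlet, 2 * n] <- n * cn[!dirichlet]
    A[!dirichlet, 2 * n + 1] <- n * sn[!dirichlet]
  }
  coef <- qr.solve(A, rhs)
  u <- coef[1]
  for (n in seq_len(n_modes))
    u <- u + r0^n * (coef[2 * n] * cos(n * t0) + coef[2 * n + 1] * sin(n * t0))
  u
}

# full splitting vector for a window set, by the spectral solver
splitting_bvp_oracle <- function(windows, source, n_modes = 400) {
  geometry <- attr(windows, "geometry")
  eps <- attr(windows, "eps")
  if (geometry$type == "half_plane") {
    s <- geometry$side
    # map s*x > 0 canonically to x > 0, then w = (1 - z)/(1 + z)
    arcs <- lapply(seq_len(nrow(windows)), function(i) {
      lo <- windows$y[i] - eps / 2; hi <- windows$y[i] + eps / 2
      sort(c(-2 * atan(lo), -2 * atan(hi)))
    })
    z0 <- complex(real = s * source[1], imaginary = source[2])
    w0 <- (1 - z0) / (1 + z0)
  } else {
    R <- geometry$R
    ha <- eps / 2 / R
    ang <- atan2(windows$y, windows$x)
    arcs <- lapply(ang, function(a) c(a - ha, a + ha))
    w0 <- R / Conj(complex(real = source[1], imaginary = source[2]))
  }
  vapply(seq_along(arcs), function(k) {
    uv <- rep(0, length(arcs)); uv[k] <- 1
    fit_disk_mixed_bvp(arcs, uv, w0, n_modes = n_modes)
  }, numeric(1))
}

# truncated Fourier-series form of the semi-strip Green's function
# (mode frequencies n*pi/a), the independent check of the closed form
green_semistrip_series <- function(x1, x2, y1, y2, a = 1, n_modes = 1e4) {
  n <- seq_len(n_modes)
  wn <- n * pi / a
  min(x1, y1) / a + (1 / (2 * pi)) * sum(
    (1 / n) * (exp(-wn * abs(x1 - y1)) - exp(-wn * (x1 + y1))) *
      (cos(wn * (x2 - y2)) + cos(wn * (x2 + y2))))
}

# chi-square goodness of fit of samples against a density on [lo, hi]
chisq_pdf_test <- function(samples, density, lo, hi, bins = 36) {
  brk <- seq(lo, hi, length.out = bins + 1)
  obs <- hist(samples, breaks = brk, plot = FALSE)$counts
  pr <- vapply(seq_len(bins), function(i) {
    integrate(density, brk[i], brk[i + 1], rel.tol = 1e-9)$value
  }, numeric(1))
  pr <- pr / sum(pr)
  expd <- length(samples) * pr
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = bins - 1, lower.tail = FALSE)
}

# random well-separated window sets for property tests
random_window_set <- function(n, geometry_type = "half_plane", eps = 0.1) {
  if (geometry_type == "half_plane") {
    repeat {
      z <- sort(runif(n, -4, 4))
      if (n == 1 || min(diff(z)) > 5 * eps) break
    }
    windows_on_line(z, eps = eps)
  } else {
    min_gap <- 2 * asin(pmin(1, 2.6 * eps))   # chord separation > 5 * eps
    repeat {
      th <- sort(runif(n, 0, 2 * pi))
      gaps <- diff(c(th, th[1] + 2 * pi))
      if (n == 1 || min(gaps) > min_gap) break
    }
    windows_on_disk(th, eps = eps, geometry = exterior_disk(1))
  }
}

random_source <- function(windows, r_range = c(2, 10)) {
  geometry <- attr(windows, "geometry")
  r <- exp(runif(1, log(r_range[1]), log(r_range[2])))
  if (geometry$type == "half_plane") {
    ang <- runif(1, -0.45 * pi, 0.45 * pi)
    c(geometry$side * r * cos(ang), r * sin(ang) + mean(windows$y))
  } else {
    ang <- runif(1, 0, 2 * pi)
    c(r * cos(ang), r * sin(ang))
  }
}
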