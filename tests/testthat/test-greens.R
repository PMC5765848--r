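# Neumann-Green's functions: closed-form values, boundary conditions,
# symmetries and the series cross-check of the semi-strip form.

test_that("half-plane Green's function matches direct evaluation and vanishing cases", {
  # boundary point at unit distance: both logs equal ln 1 = 0
  expect_equal(green_neumann_half_plane(c(0, 2), c(1, 2)), 0)
  # direct two-log evaluation: -(1/4pi) ln 180
  expect_equal(green_neumann_half_plane(c(1, 2), c(2, 5)),
               -log(180) / (4 * pi), tolerance = 1e-12)
  # symmetric in its two arguments
  expect_equal(green_neumann_half_plane(c(1, 2), c(2, 5)),
               green_neumann_half_plane(c(2, 5), c(1, 2)))
  expect_error(green_neumann_half_plane(c(1, 2), c(1, 2)), "coincide")
  expect_error(green_neumann_half_plane(c(-1, 2), c(1, 2)), "same side")
})

test_that("half-plane Green's function is harmonic away from the source", {
  h <- 1e-4
  p <- c(0.7, 1.3); q <- c(2, 5)
  lap <- (green_neumann_half_plane(p + c(h, 0), q) +
          green_neumann_half_plane(p - c(h, 0), q) +
          green_neumann_half_plane(p + c(0, h), q) +
          green_neumann_half_plane(p - c(0, h), q) -
          4 * green_neumann_half_plane(p, q)) / h^2
  expect_lt(abs(lap), 1e-4)
})

test_that("Neumann condition holds numerically on both reflecting boundaries", {
  # one-sided second-order stencil at the boundary: error O(h^2)
  h <- 1e-5
  ddn <- function(f0, f1, f2) (-3 * f0 + 4 * f1 - f2) / (2 * h)

  zs <- seq(-4, 4, length.out = 10)
  q <- c(1.5, 0.3)
  dGdn <- vapply(zs, function(z) {
    ddn(green_neumann_half_plane(c(0, z), q),
        green_neumann_half_plane(c(h, z), q),
        green_neumann_half_plane(c(2 * h, z), q))
  }, numeric(1))
  expect_true(all(abs(dGdn) < 1e-6))

  # disk: radial derivative at r = R
  R <- 1; q2 <- c(0, 2)
  dGdr <- vapply(seq(0, 2 * pi, length.out = 11)[-11], function(a) {
    u <- c(cos(a), sin(a))
    ddn(green_neumann_disk(R * u, q2, R),
        green_neumann_disk((R + h) * u, q2, R),
        green_neumann_disk((R + 2 * h) * u, q2, R))
  }, numeric(1))
  expect_true(all(abs(dGdr) < 1e-6))
})

test_that("disk Green's function is rotation invariant and matches the two-log form", {
  R <- 1
  g0 <- green_neumann_disk(c(2 * R, 0), c(-2 * R, 0), R)
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  for (a in c(0.3, 1.1, 2.9)) {
    expect_equal(green_neumann_disk(rot(c(2 * R, 0), a), rot(c(-2 * R, 0), a), R),
                 g0, tolerance = 1e-13)
  }
  # independent evaluation of -(1/2pi)(ln|x - x0| + ln|(R^2/|x|^2) x - x0|)
  x <- c(3, 0); x0 <- c(0, 2)
  xim <- x / sum(x^2)
  expect_equal(green_neumann_disk(x, x0, 1),
               -(log(sqrt(sum((x - x0)^2))) + log(sqrt(sum((xim - x0)^2)))) /
                 (2 * pi),
               tolerance = 1e-14)
  expect_error(green_neumann_disk(c(0.5, 0), c(3, 0), 1), "outside")
})

test_that("semi-strip Green's function vanishes at the absorbing end and respects wall symmetry", {
  a <- 1
  expect_equal(green_semistrip(0.7, 0.4, 0, 0.6, a), 0, tolerance = 1e-12)
  g <- green_semistrip(0.7, 0.4, 0.2, 0.6, a)
  expect_equal(g, green_semistrip(0.7, a - 0.4, 0.2, a - 0.6, a),
               tolerance = 1e-13)
  expect_error(green_semistrip(0.7, 1.4, 0.2, 0.6, a), "inside")
})

test_that("semi-strip closed form agrees with the truncated eigenfunction series", {
  a <- 1
  expect_equal(green_semistrip(0.7, 0.4, 0.2, 0.6, a),
               green_semistrip_series(0.7, 0.4, 0.2, 0.6, a, n_modes = 1e4),
               tolerance = 1e-8)
  set.seed(101)
  for (i in 1:100) {
    aa <- runif(1, 0.5, 3)
    x1 <- runif(1, 0.05, 2); y1 <- runif(1, 0.05, 2)
    x2 <- runif(1, 0.05, 0.95) * aa; y2 <- runif(1, 0.05, 0.95) * aa
    if (abs(x1 - y1) < 5e-3) next  # keep the series tail below tolerance
    expect_equal(green_semistrip(x1, x2, y1, y2, aa),
                 green_semistrip_series(x1, x2, y1, y2, aa, n_modes = 1e4),
                 tolerance = 1e-7)
  }
})
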