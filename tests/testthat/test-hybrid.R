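# Hybrid analytical-stochastic simulator: Euler step moments, step
# classification geometry, determinism, symmetry, time-step convergence
# and agreement with the spectral ground truth.

test_that("euler_step has the right moments and degenerate behaviour", {
  expect_equal(euler_step(c(1, 2), dt = 0.1, D = 0), c(1, 2))
  set.seed(21)
  steps <- euler_step(matrix(0, 1e5, 2), dt = 1e-3, D = 1)
  v <- apply(steps, 2, stats::var)
  # sample variance of a normal: sd ~ var * sqrt(2/n)
  expect_true(all(abs(v - 2e-3) < 3 * 2e-3 * sqrt(2 / 1e5)))
  set.seed(22); a <- euler_step(c(0, 0), 0.01)
  set.seed(22); b <- euler_step(c(0, 0), 0.01)
  expect_identical(a, b)
})

test_that("step classification: absorption, reflection and escape on the half-plane", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  # crossing the boundary inside window 1
  r <- resolve_step(w, from = c(0.05, 0.5), to = c(-0.05, 0.5))
  expect_equal(r$status, "absorbed")
  expect_equal(r$window, 1L)
  # crossing at the window edge still counts; just outside does not
  r2 <- resolve_step(w, from = c(0.05, 0.56), to = c(-0.05, 0.56))
  expect_equal(r2$status, "continue")
  expect_equal(r2$position, c(0.05, 0.56))  # specular fold
  # crossing far from all windows reflects
  r3 <- resolve_step(w, from = c(0.05, 3), to = c(-0.07, 3.1), ro = 10)
  expect_equal(r3$status, "continue")
  expect_equal(r3$position, c(0.07, 3.1))
  # leaving the outer boundary escapes
  r4 <- resolve_step(w, from = c(1, 1), to = c(4, 4), ro = 2)
  expect_equal(r4$status, "escaped")
  # mirrored geometry behaves identically
  wneg <- windows_on_line(c(0.5, -0.5), eps = 0.1, geometry = half_plane(-1))
  r5 <- resolve_step(wneg, from = c(-0.05, 0.5), to = c(0.05, 0.5))
  expect_equal(r5$status, "absorbed")
})

test_that("step classification: chord-circle absorption and reflection on the disk", {
  w <- windows_on_disk(c(0, pi / 2), eps = 0.2, geometry = exterior_disk(1))
  # chord dipping into the disk through the window arc at angle 0
  r <- resolve_step(w, from = c(1.05, -0.05), to = c(0.9, 0.05))
  expect_equal(r$status, "absorbed")
  expect_equal(r$window, 1L)
  # same chord rotated away from all windows: reflected outside
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  r2 <- resolve_step(w, from = rot(c(1.05, -0.05), pi), to = rot(c(0.9, 0.05), pi))
  expect_equal(r2$status, "continue")
  expect_gt(sqrt(sum(r2$position^2)), 1)
  # endpoint outside, chord missing the disk entirely: unchanged
  r3 <- resolve_step(w, from = c(1.5, 1.5), to = c(1.4, 1.6))
  expect_equal(r3$status, "continue")
  expect_equal(r3$position, c(1.4, 1.6))
})

test_that("simulation is deterministic given the seed and conserves mass", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  a <- splitting_simulate(w, c(1, 2), n = 3000, seed = 5)
  b <- splitting_simulate(w, c(1, 2), n = 3000, seed = 5)
  expect_identical(a$p, b$p)
  expect_identical(attr(a, "counts"), attr(b, "counts"))
  expect_equal(sum(a$p), 1)
  expect_equal(sum(attr(a, "counts")), 3000)
  expect_equal(a$se, sqrt(a$p * (1 - a$p) / 3000), tolerance = 1e-12)
  c2 <- splitting_simulate(w, c(1, 2), n = 3000, seed = 6)
  expect_false(identical(a$p, c2$p))
})

test_that("symmetric configurations split evenly within Monte-Carlo error", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  s <- splitting_simulate(w, c(2, 0), n = 2e4, seed = 42)
  expect_lt(abs(s$p[1] - 0.5), 3 * s$se[1])

  wd <- windows_on_disk(c(pi / 2, -pi / 2), eps = 0.1)
  sd_ <- splitting_simulate(wd, c(4, 0), n = 2e4, seed = 42)
  expect_lt(abs(sd_$p[1] - 0.5), 3 * sd_$se[1])

  # disk in a strip, source on the strip axis, fore/aft windows:
  # the window facing the source wins; mirrored windows tie
  ws <- windows_on_disk(c(pi / 2, -pi / 2), eps = 0.1,
                        geometry = disk_in_strip(R = 1, a = 2))
  ss <- splitting_simulate(ws, c(6, 0), n = 2e4, seed = 42,
                           re = 1.5, ro = 3)
  expect_lt(abs(ss$p[1] - 0.5), 3 * ss$se[1])
})

test_that("the strip geometry senses source direction much farther than free space", {
  # fore/aft windows, source down the strip axis: the facing window keeps
  # a clear flux advantage even at distance 6 (channelled diffusion)
  ws <- windows_on_disk(c(0, pi), eps = 0.1,
                        geometry = disk_in_strip(R = 1, a = 2))
  ss <- splitting_simulate(ws, c(6, 0), n = 2e4, seed = 42, re = 1.5, ro = 3)
  expect_gt(ss$p[1] - ss$p[2], 0.1)
  expect_equal(sum(ss$p), 1)
})

test_that("halving the time step leaves estimates within combined Monte-Carlo error", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  dt0 <- 0.1^2 / 36
  s1 <- splitting_simulate(w, c(1, 2), n = 2e4, seed = 31, dt = dt0)
  s2 <- splitting_simulate(w, c(1, 2), n = 2e4, seed = 32, dt = dt0 / 2)
  expect_lt(abs(s1$p[1] - s2$p[1]), 3 * sqrt(s1$se[1]^2 + s2$se[1]^2))
})

test_that("the simulator converges to the spectral mixed-BVP solution", {
  # half-plane reference case
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  src <- c(1, 2)
  truth <- splitting_bvp_oracle(w, src, n_modes = 500)[1]
  s <- splitting_simulate(w, src, n = 2e4, seed = 42, dt = 0.1^2 / 36 / 4)
  # tolerance: 3 binomial SE plus the residual first-order step bias
  expect_lt(abs(s$p[1] - truth), 3 * s$se[1] + 0.004)

  # exterior disk reference case
  wd <- windows_on_disk(c(0, pi), eps = 0.1)
  truth_d <- splitting_bvp_oracle(wd, c(3, 0), n_modes = 500)[1]
  sd_ <- splitting_simulate(wd, c(3, 0), n = 1e4, seed = 42,
                            dt = 0.1^2 / 36 / 4)
  expect_lt(abs(sd_$p[1] - truth_d), 3 * sd_$se[1] + 0.004)
})

test_that("no trajectory hits the re-injection cap in reference scenarios", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  s <- splitting_simulate(w, c(1, 2), n = 5000, seed = 9)
  expect_lt(attr(s, "max_reinjections"), 1e4)
  # a tight cap triggers the diagnostic error
  expect_error(splitting_simulate(w, c(1, 2), n = 200, seed = 9,
                                  max_reinject = 1),
               "re-injection cap")
})

test_that("invalid configurations are rejected", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  expect_error(splitting_simulate(w, c(0.2, 0.2), n = 10), "inner artificial")
  expect_error(splitting_simulate(w, c(1, 2), n = 10, re = 3, ro = 2), "ro > re")
  expect_warning(splitting_simulate(w, c(1, 2), n = 10, seed = 1, dt = 1),
                 "too coarse")
})
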