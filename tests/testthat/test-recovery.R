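# Source recovery: round-trip exactness, ambiguity filtering, uncertainty
# regions and distance-flux maps.

test_that("three-window fluxes invert back to the generating source", {
  sc <- scenario_fixture("fig4_three_windows")
  p <- window_system(sc$windows, sc$source)$p
  rec <- recover_source(sc$windows, p[1:2])
  expect_true(rec$converged)
  expect_lt(max(abs(rec$position - sc$source)), 1e-6)
  expect_lt(rec$residual, 1e-8)
})

test_that("noiseless round trips recover random sources to 1e-6", {
  set.seed(41)
  for (gtype in c("half_plane", "exterior_disk")) {
    for (i in 1:15) {
      w <- random_window_set(3, gtype)
      src <- random_source(w, r_range = c(2, 12))
      p <- window_system(w, src)$p
      rec <- tryCatch(recover_source(w, p[1:2]), error = function(e) NULL)
      expect_false(is.null(rec))
      expect_lt(max(abs(rec$position - src)), 1e-6)
    }
  }
})

test_that("symmetric observations put the source on the symmetry axis", {
  w <- windows_on_line(c(-1, 0, 1), eps = 0.1)
  src <- c(5, 0)                      # on the symmetry axis
  p <- window_system(w, src)$p
  expect_equal(p[1], p[3], tolerance = 1e-12)
  rec <- recover_source(w, p[1:2])
  expect_lt(abs(rec$position[2]), 1e-8)
})

test_that("spurious pairwise intersections are filtered by the full flux vector", {
  sc <- scenario_fixture("fig4_five_windows")
  p <- window_system(sc$windows, sc$source)$p
  rec <- recover_source(sc$windows, p[1:4])
  expect_lt(max(abs(rec$position - sc$source)), 1e-6)
  expect_false(rec$ambiguous)
  expect_equal(sum(rec$candidates$residual <= 1e-6), 1)
})

test_that("recovery input validation", {
  w <- windows_on_line(c(-1, 0, 1), eps = 0.1)
  expect_error(recover_source(w, c(0.5, 0.6)), "sum below one")
  expect_error(recover_source(w, c(0.2, -0.1)), "positive")
  expect_error(recover_source(w, c(0.2, 0.3, 0.4)), "sum to one")
  w2 <- windows_on_line(c(-1, 1), eps = 0.1)
  expect_error(recover_source(w2, 0.4), "at least three")
})

test_that("two-window recovery returns the locus with a direction flag", {
  w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
  src <- c(1, 2)
  alpha <- splitting_closed_form(w, src)$p[2]
  curve <- recover_two_windows(w, alpha)
  expect_lt(abs(curve$F(src)), 1e-12)     # source lies on the locus
  expect_equal(curve$toward, 1L)          # window 1 has the larger flux
  curve2 <- recover_two_windows(w, 0.7)
  expect_equal(curve2$toward, 2L)
})

test_that("uncertainty region contains the noiseless solution and grows with eta", {
  sc <- scenario_fixture("fig4_three_windows")
  p <- window_system(sc$windows, sc$source)$p

  r0 <- recovery_region(sc$windows, p[1:2], eta = 0, n_grid = 3)
  expect_equal(nrow(dplyr::filter(r0, ok)), sum(r0$ok))
  expect_lt(max(abs(c(r0$x[r0$ok][1], r0$y[r0$ok][1]) - sc$source)), 1e-6)
  expect_equal(attr(r0, "area"), 0)

  areas <- vapply(c(0.001, 0.0025, 0.005), function(eta) {
    attr(recovery_region(sc$windows, p[1:2], eta = eta, n_grid = 5), "area")
  }, numeric(1))
  expect_true(all(diff(areas) > 0))

  r1 <- recovery_region(sc$windows, p[1:2], eta = 0.005, n_grid = 5)
  # contains the unperturbed solution (the central grid node)
  centre_row <- dplyr::filter(r1, eta1 == 0, eta2 == 0)
  expect_lt(max(abs(c(centre_row$x, centre_row$y) - sc$source)), 1e-6)
  # at this source distance some independent-sign perturbations leave the
  # attainable flux set (the forward map is even across the boundary
  # line), so those corners are flagged rather than silently dropped
  expect_true(all(is.na(r1$x[!r1$ok])))
  expect_gt(sum(r1$ok), 3)
})

test_that("perturbation uncertainty grows with source distance", {
  w <- windows_on_line(c(-1, 0, 1), eps = 0.1)
  area_at <- function(src) {
    p <- window_system(w, src)$p
    attr(recovery_region(w, p[1:2], eta = 0.005, n_grid = 3), "area")
  }
  expect_gt(area_at(c(8, 2)), area_at(c(3, 1)))
})

test_that("distance-flux map inverts the forward model and masks the simplex", {
  w <- windows_on_line(c(-1, 0, 1), eps = 0.1)
  dm <- distance_map(w, n = 9, margin = 0.05)
  expect_true(all(!dm$admissible | dm$p1 + dm$p3 < 1))
  expect_true(all(is.na(dm$distance[!dm$admissible])))

  # spot check: the flux pair of a known source maps back to its distance
  src <- c(4, 1)
  p <- window_system(w, src)$p
  rec <- recover_source(w, c(p[1], p[2]))
  d_ref <- sqrt(sum((src - c(0, 0))^2))
  expect_equal(sqrt(sum(rec$position^2)), d_ref, tolerance = 1e-8)

  # symmetric flux pair: source on the axis, finite distance
  psym <- window_system(w, c(5, 0))$p
  rec2 <- recover_source(w, psym[1:2])
  expect_lt(abs(rec2$position[2]), 1e-8)

  # distance grows toward the equal-flux centre of the simplex
  solved <- dplyr::filter(dm, is.finite(distance))
  expect_gt(nrow(solved), 5)
  centre_dist <- abs(solved$p1 - 1 / 3) + abs(solved$p3 - 1 / 3)
  ord <- order(centre_dist)
  expect_gt(mean(solved$distance[ord[1:3]]),
            mean(solved$distance[rev(ord)[1:3]]))
})

test_that("tidy and glance summarize recovery results", {
  sc <- scenario_fixture("fig4_three_windows")
  p <- window_system(sc$windows, sc$source)$p
  rec <- recover_source(sc$windows, p[1:2])
  td <- tidy(rec)
  expect_true(all(c("x", "y", "residual") %in% names(td)))
  gl <- glance(rec)
  expect_equal(nrow(gl), 1)
  expect_equal(c(gl$x, gl$y), rec$position)
})
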