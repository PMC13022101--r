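# ---- window_rmsf ----------------------------------------------------------

test_that("window_rmsf closed-form cases", {
  co <- array(rep(point_cloud(4, 2), 5), dim = c(4, 3, 5))
  expect_equal(window_rmsf(co), rep(0, 4))
  # one atom at x = +1 then -1, others fixed
  co2 <- array(0, dim = c(3, 3, 2))
  co2[1, 1, ] <- c(1, -1)
  co2[2, , ] <- 5; co2[3, 2, ] <- -2
  expect_equal(window_rmsf(co2), c(1, 0, 0))
  expect_error(window_rmsf(co2[, , 1, drop = FALSE]), "window too short")
})

test_that("window_rmsf matches the literal-definition oracle", {
  set.seed(14)
  co <- array(rnorm(6 * 3 * 25), dim = c(6, 3, 25))
  expect_equal(window_rmsf(co), naive_rmsf(co), tolerance = 1e-12)
})

# ---- compute_rmsx / classic_rmsf ------------------------------------------

test_that("single-slice RMSX equals classical RMSF and the naive oracle", {
  sys <- tiny_system(n_residues = 9, n_frames = 40,
                     sigma = seq(0.1, 0.9, length.out = 9), seed = 6)
  plan <- plan_slices(40, n_slices = 1, dt_ps = sys$dt_ps)
  one <- compute_rmsx(sys, plan, align_mode = "none")
  expect_equal(dim(one$values), c(9L, 1L))
  expect_equal(as.vector(one$values),
               classic_rmsf(sys, align_mode = "none"), tolerance = 1e-12)
  expect_equal(as.vector(one$values), naive_rmsf(sys$coords),
               tolerance = 1e-12)
})

test_that("RMSX is reference-free within windows (offset invariance)", {
  sys <- tiny_system(n_residues = 6, n_frames = 24, seed = 8)
  plan <- plan_slices(24, n_slices = 4, dt_ps = sys$dt_ps)
  m0 <- compute_rmsx(sys, plan, align_mode = "none")
  off <- sys
  off$coords <- sys$coords + array(rep(c(3, 4, 0), each = n_atoms(sys)),
                                   dim = dim(sys$coords))
  m1 <- compute_rmsx(off, plan, align_mode = "none")
  expect_equal(m1$values, m0$values, tolerance = 1e-12)
  # ... while the unaligned shift map moves by exactly the offset norm
  s0 <- shift_map(sys, align = FALSE)
  s1 <- shift_map(off, align = FALSE)
  # offset applied to all frames including the reference: map unchanged;
  # applied to non-reference frames only: every entry grows toward 5
  off2 <- sys
  for (f in 2:n_frames(sys)) {
    off2$coords[, , f] <- sys$coords[, , f] +
      matrix(c(30, 40, 0), n_atoms(sys), 3, byrow = TRUE)
  }
  s2 <- shift_map(off2, align = FALSE)
  expect_equal(s1$values, s0$values, tolerance = 1e-12)
  expect_equal(mean(s2$values[, -1] ), 50, tolerance = 0.01)
})

test_that("stationary jitter gives no spurious time structure", {
  sys <- tiny_system(n_residues = 8, n_frames = 400, sigma = 0.5, seed = 31)
  plan <- plan_slices(400, n_slices = 4, dt_ps = sys$dt_ps)
  m <- compute_rmsx(sys, plan, align_mode = "none")
  expected <- 0.5 * sqrt(3)
  expect_true(all(abs(m$values - expected) / expected < 0.15))
})

test_that("event trajectories are localized by the RMSX argmax", {
  spec <- synthetic_spec(
    n_residues = 20, n_frames = 200, sigma = 0.2, seed = 77,
    events = list(list(residues = 10:12, frames = 101:160, multiplier = 10)))
  sys <- generate_trajectory(spec)
  plan <- plan_slices(200, n_slices = 10, dt_ps = spec$dt_ps)
  m <- compute_rmsx(sys, plan, align_mode = "none")
  for (r in 10:12) {
    expect_true(which.max(m$values[r, ]) %in% 6:8)
  }
  # unperturbed residues stay near baseline in all slices
  expect_lt(max(m$values[-(10:12), ]), 0.2 * sqrt(3) * 2)
})

test_that("per_window alignment mode returns finite, comparable values", {
  sys <- tiny_system(n_residues = 6, n_frames = 40, seed = 13)
  plan <- plan_slices(40, n_slices = 4, dt_ps = sys$dt_ps)
  pw <- compute_rmsx(sys, plan, align_mode = "per_window")
  gl <- compute_rmsx(sys, plan, align_mode = "global")
  expect_true(all(is.finite(pw$values)))
  # per-window fitting absorbs rigid degrees of freedom, shrinking the
  # apparent fluctuation on average
  expect_lt(mean(pw$values), mean(gl$values) + 1e-9)
})

test_that("axis means follow the stated arithmetic", {
  m <- structure(list(kind = "rmsx",
                      values = matrix(c(1, 2, 3, 4), 2),
                      residue_labels = data.frame(chain_id = c("A", "A"),
                                                  residue_id = 1:2,
                                                  residue_name = "ALA"),
                      time_axis = c(0.5, 1.5)), class = "MetricMatrix")
  expect_equal(mean_rmsx_per_residue(m), c(2, 3))
  expect_equal(mean_rmsx_per_slice(m), c(1.5, 3.5))
})

# ---- shift maps -----------------------------------------------------------

test_that("shift_map reference column, translation and alignment cases", {
  sys <- tiny_system(n_residues = 5, n_frames = 6, sigma = 0, seed = 2,
                     geometry = "helix")
  # build an explicit whole-system translation of frame 1
  for (f in 2:6) {
    sys$coords[, , f] <- sweep(sys$coords[, , 1], 2, (f - 1) * c(3, 4, 0),
                               `+`)
  }
  off <- shift_map(sys, align = FALSE)
  expect_equal(off$values[, 1], rep(0, 5))
  expect_equal(off$values[, 2], rep(5, 5), tolerance = 1e-9)
  expect_equal(off$values[, 6], rep(25, 5), tolerance = 1e-9)
  on <- shift_map(sys, align = TRUE)
  expect_lt(max(on$values), 1e-9)
})

test_that("drift inflates the shift map but not within-window RMSX", {
  base_spec <- synthetic_spec(n_residues = 10, n_frames = 400, sigma = 0.3,
                              seed = 55)
  drift_spec <- synthetic_spec(n_residues = 10, n_frames = 400, sigma = 0.3,
                               drift = c(0.01, 0, 0), seed = 55)
  base <- generate_trajectory(base_spec)
  drif <- generate_trajectory(drift_spec)
  plan <- plan_slices(400, n_slices = 8, dt_ps = 10)
  # per-slice mean shift rises monotonically under drift
  sm <- shift_map(drif, align = FALSE)
  per_slice <- vapply(seq_len(8), function(k) {
    mean(sm$values[, ((k - 1) * 50 + 1):(k * 50)])
  }, numeric(1))
  expect_true(all(diff(per_slice) > 0))
  # slice 8 covers frames 351..400 -> mean drift distance 0.01 * 374.5
  expect_equal(per_slice[8], 0.01 * mean(350:399), tolerance = 0.05)
  # within-window RMSX stays within 10% of the no-drift baseline
  m_base <- compute_rmsx(base, plan, align_mode = "none")
  m_drift <- compute_rmsx(drif, plan, align_mode = "none")
  expect_lt(max(abs(m_drift$values - m_base$values) / m_base$values), 0.10)
})

# ---- lDDT -----------------------------------------------------------------

test_that("lDDT is 1 for the reference and rigid transforms of it", {
  sys <- tiny_system(n_residues = 10, n_frames = 4, sigma = 0, seed = 3,
                     geometry = "helix")
  for (f in 2:4) sys$coords[, , f] <- random_rigid(sys$coords[, , 1])
  m <- lddt_series(sys)
  expect_true(all(m$values == 1))
})

test_that("lDDT matches the brute-force pair enumeration oracle", {
  sys <- tiny_system(n_residues = 5, n_frames = 2, sigma = 0, seed = 9,
                     geometry = "helix")
  sys$coords[3, , 2] <- sys$coords[3, , 2] + c(10, 0, 0)
  m <- lddt_series(sys)
  oracle <- naive_lddt(sys$coords[, , 1], sys$coords[, , 2])
  expect_identical(m$values[, 2], oracle)
  expect_equal(m$values[, 1], rep(1, 5))
  # noisy multi-frame case, larger system
  sys2 <- tiny_system(n_residues = 12, n_frames = 5, sigma = 0.8, seed = 12,
                      geometry = "helix")
  m2 <- lddt_series(sys2, r0 = 9, thresholds = c(0.25, 0.5, 1))
  for (f in 1:5) {
    expect_equal(m2$values[, f],
                 naive_lddt(sys2$coords[, , 1], sys2$coords[, , f],
                            r0 = 9, thresholds = c(0.25, 0.5, 1)))
  }
})

test_that("residues without reference contacts are NA, never 0", {
  sys <- tiny_system(n_residues = 6, n_frames = 2, sigma = 0, seed = 4)
  sys$coords[6, , ] <- sys$coords[6, , ] + c(500, 0, 0)  # isolated residue
  m <- lddt_series(sys, r0 = 8)
  expect_true(is.na(m$values[6, 1]))
  expect_false(any(m$values[1:5, ] == 0, na.rm = TRUE))
  expect_error(lddt_series(sys, thresholds = c(2, 1)), "ascending")
  expect_error(lddt_series(sys, r0 = -1), "r0")
})

test_that("per-slice lDDT aggregation averages frame scores", {
  sys <- tiny_system(n_residues = 6, n_frames = 8, sigma = 0.4, seed = 5,
                     geometry = "helix")
  plan <- plan_slices(8, n_slices = 2, dt_ps = 10)
  per_frame <- lddt_series(sys)
  per_slice <- lddt_series(sys, per_slice = plan)
  expect_equal(per_slice$values[, 1], rowMeans(per_frame$values[, 1:4]))
  expect_equal(per_slice$values[, 2], rowMeans(per_frame$values[, 5:8]))
})

# ---- pearson / window_check ----------------------------------------------

test_that("pearson matches the direct covariance formula and guards input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearson(1:10, -(1:10))$r, -1.0, tolerance = 1e-12)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  p <- pearson(x, y)
  expect_equal(p$r, naive_pearson(x, y), tolerance = 1e-12)
  expect_equal(p$r_squared, p$r^2, tolerance = 1e-12)
  expect_error(pearson(1:3, 1:4), "lengths differ")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "degenerate")
})

test_that("window_check separates coupled and decoupled regimes", {
  # coupled: fluctuation amplitude ramps up over time, so within-window
  # fluctuation and drift from the reference rise together
  ramp <- lapply(1:8, function(k) {
    list(residues = 1:8, frames = ((k - 1) * 80 + 1):(k * 80),
         multiplier = k)
  })
  coupled <- generate_trajectory(synthetic_spec(
    n_residues = 8, n_frames = 640, sigma = 0.15, events = ramp,
    geometry = "helix", seed = 19))
  rep_c <- window_check(coupled, candidate_slice_counts = c(4, 8, 16))
  expect_true(all(!rep_c$skipped))
  expect_true(all(rep_c$pearson_r > 0.8))
  expect_equal(rep_c$r_squared, rep_c$pearson_r^2, tolerance = 1e-12)

  # decoupled: fast jitter plus an internal deformation much slower than the
  # window, so RMSD follows the slow pattern while within-window RMSX stays
  # noise-driven
  flat <- generate_trajectory(synthetic_spec(
    n_residues = 8, n_frames = 640, sigma = 0.4,
    amplitude = seq(0, 3, length.out = 8), period = 640,
    geometry = "helix", seed = 23))
  rep_f <- window_check(flat, candidate_slice_counts = c(64))
  expect_lt(abs(rep_f$pearson_r[1]), 0.3)

  # a candidate that does not fit is skipped, not fatal
  small <- tiny_system(n_residues = 5, n_frames = 100, seed = 3)
  rep_s <- window_check(small, candidate_slice_counts = c(4, 128))
  expect_false(rep_s$skipped[1])
  expect_true(rep_s$skipped[2])
  expect_error(window_check(small, candidate_slice_counts = c(1, 4)),
               ">= 2")
})
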