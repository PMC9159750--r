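test_that("flat-topped envelope matches closed form and its invariants", {
  env <- motion_envelope_spec()
  expect_identical(motion_envelope(env$t0, env), 1)
  # frozen value from independent scalar evaluation of exp(-(1/0.92)^22)
  expect_equal(motion_envelope(0, env), 1.908672e-03, tolerance = 1e-6)
  # even exponent: symmetric about t0, bounded by 1, decreasing in |t - t0|
  d <- seq(0, 1, by = 0.05)
  expect_equal(motion_envelope(env$t0 + d, env), motion_envelope(env$t0 - d, env))
  expect_true(all(motion_envelope(seq(0, 2.1, by = 0.01), env) <= 1))
  g <- motion_envelope(env$t0 + d, env)
  expect_true(all(diff(g) <= 0))
  expect_error(motion_envelope_spec(sigma = 0), "sigma")
  expect_error(motion_envelope_spec(n = 21), "even")
})

test_that("platform trajectory: phase flip and velocity consistent with position", {
  env <- motion_envelope_spec()
  tt <- seq(0, 2.1, by = 0.002)
  tr0 <- platform_trajectory(tt, env)
  tr180 <- platform_trajectory(tt, motion_envelope_spec(phase_deg = 180))
  expect_lt(abs(tr0$position_cm[1]), 1e-2)
  expect_equal(tr180$position_cm, -tr0$position_cm)
  expect_equal(tr180$velocity_cm_s, -tr0$velocity_cm_s)
  # quadrature of the analytic velocity recovers the position change
  pos_num <- cumsum((tr0$velocity_cm_s[-1] + tr0$velocity_cm_s[-length(tt)]) / 2) *
    0.002
  expect_equal(pos_num, (tr0$position_cm - tr0$position_cm[1])[-1],
               tolerance = 1e-4)
  expect_error(platform_trajectory(c(-0.5, 1), env), "within")
})

test_that("pedestal split reproduces the dynamic depth range and is invertible", {
  sp <- split_pedestal(-0.45, -1.53)
  expect_equal(sp$d_mp, -1.215, tolerance = 1e-15)
  expect_equal(sp$d_bd, 0.315, tolerance = 1e-15)
  expect_equal(split_pedestal(-0.45, 0)$d_mp, -0.45)
  expect_equal(split_pedestal(0, 0.57), list(d_mp = 0.285, d_bd = -0.285))
  # invertibility to machine precision over a grid
  for (ped in c(-0.45, 0, 0.51)) {
    for (dd in standard_delta_set()) {
      sp <- split_pedestal(ped, dd)
      expect_lt(abs((sp$d_mp - sp$d_bd) - dd), 1e-14)
      expect_lt(abs((sp$d_mp + sp$d_bd) / 2 - ped), 1e-14)
    }
  }
})

test_that("standard condition table has 16 unique rows with the printed depth range", {
  ct <- build_condition_table()
  expect_identical(nrow(ct), 16L)
  expect_false(anyDuplicated(ct$condition_id) > 0)
  dyn <- ct[ct$kind == "dynamic", ]
  expect_equal(min(c(dyn$d_mp_deg, dyn$d_bd_deg)), -1.215)
  expect_equal(max(c(dyn$d_mp_deg, dyn$d_bd_deg)), 0.315)
  # deterministic ordering: dynamic ascending conflict, then stationary
  expect_identical(ct$kind, rep(c("dynamic", "stationary"), c(7L, 9L)))
  expect_true(!is.unsorted(dyn$delta_depth_deg))
  expect_identical(nrow(build_condition_table(0, 0)), 2L)
  expect_error(build_condition_table(c(0, 0), 0), "duplicate")
})

test_that("dynamic-object ray-trace collapses to the stationary projection monocularly", {
  geom <- viewing_geometry()
  cam <- platform_trajectory(seq(0, 2.1, by = 1 / 60))$position_cm
  # d_MP == d_BD: identical to a stationary object at that depth
  tr <- raytrace_dynamic_object(-0.45, -0.45, cam, geom)
  st <- project_stationary_object(-0.45, cam, geom)
  expect_equal(tr$screen_x_cm, st$screen_x_cm)
  # stationary camera: no image motion
  tr0 <- raytrace_dynamic_object(-1.215, 0.315, rep(1.5, 20), geom)
  expect_equal(diff(tr0$screen_x_cm), rep(0, 19))
  # monocular equivalence on the standard grid: the screen trace of the
  # dynamic object equals that of a stationary object at d_MP
  ct <- build_condition_table()
  dyn <- ct[ct$kind == "dynamic", ]
  for (i in seq_len(nrow(dyn))) {
    tr <- raytrace_dynamic_object(dyn$d_mp_deg[i], dyn$d_bd_deg[i], cam, geom)
    st <- project_stationary_object(dyn$d_mp_deg[i], cam, geom)
    expect_lt(max(abs(tr$screen_x_cm - st$screen_x_cm)), 1e-9)
    expect_equal(unique(tr$disparity_deg), dyn$d_bd_deg[i])
    # the rendered point moves in the world iff the cues conflict
    if (dyn$delta_depth_deg[i] != 0) {
      expect_gt(diff(range(tr$world_x_cm)), 0)
    }
  }
  expect_error(disparity_to_distance(20), "behind the eye")
})

test_that("equivalent-disparity conversion is consistent and sign-correct", {
  geom <- viewing_geometry()
  d <- seq(-2, 2, by = 0.5)
  expect_equal(distance_to_disparity(disparity_to_distance(d, geom), geom), d)
  # negative disparity = nearer than fixation
  expect_lt(disparity_to_distance(-1, geom), geom$distance_cm)
  expect_gt(disparity_to_distance(1, geom), geom$distance_cm)
})
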