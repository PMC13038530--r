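test_that("bone emphasis keeps only high-HU structures", {
  ph <- default_phantom()
  b <- bone_emphasis(ph$volume, 150)
  expect_identical(b$values > 0, ph$labels$values == 4L)
  # all-air volume maps to zero
  air <- voxel_volume(array(-1024, c(8, 8, 8)), 2)
  expect_true(all(bone_emphasis(air, 150)$values == 0))
  # a threshold below the data range is a pure affine shift
  aff <- bone_emphasis(ph$volume, -2000)
  expect_equal(aff$values, ph$volume$values + 2000)
})

test_that("3D/3D self-registration returns the identity", {
  ph <- default_phantom()
  reg <- register_3d(ph$volume, ph$volume)
  expect_true(reg$converged)
  expect_lt(max(abs(reg$transform$t)), 0.1)
  expect_lt(max(abs(reg$transform$r)), 0.1)
})

test_that("3D/3D registration recovers known setup errors", {
  spec <- phantom_spec()
  ph <- default_phantom()

  # pure translation
  tv <- make_treatment_volume(spec, rigid_transform(t = c(10, -6, 4)), 0)
  reg <- register_3d(tv, ph$volume)
  expect_true(reg$converged)
  expect_lt(max(abs(reg$transform$t - c(-10, 6, -4))), 0.5 * 2.5)

  # pure rotation about z
  tv <- make_treatment_volume(spec, rigid_transform(r = c(0, 0, 2)), 0)
  reg <- register_3d(tv, ph$volume)
  expect_lt(abs(reg$transform$r[3] + 2), 0.2)

  # full six-dimensional default setup
  study <- default_study()
  reg <- register_3d(study$treatment[[1]], study$planning)
  truth <- invert(study$true_setup)
  expect_lt(max(abs(reg$transform$t - truth$t)), 0.5 * 2.5)
  expect_lt(max(abs(reg$transform$r - truth$r)), 0.5)

  # tidy/glance surface
  td <- tidy(reg)
  expect_equal(td$term, c("tx", "ty", "tz", "rx", "ry", "rz"))
  expect_true(glance(reg)$converged)
})

test_that("registration is symmetric under swapping moving and fixed", {
  spec <- phantom_spec()
  ph <- default_phantom()
  tv <- make_treatment_volume(spec, default_setup_error(), 0)
  fwd <- register_3d(tv, ph$volume)
  bwd <- register_3d(ph$volume, tv)
  bi <- invert(bwd$transform)
  expect_lt(max(abs(fwd$transform$t - bi$t)), 2 * 0.5 * 2.5)
  expect_lt(max(abs(fwd$transform$r - bi$r)), 2 * 0.5)
})

test_that("registration ignores the tumor position", {
  spec <- phantom_spec()
  ph <- default_phantom()
  r1 <- register_3d(make_treatment_volume(spec, default_setup_error(), 0),
                    ph$volume)
  r2 <- register_3d(make_treatment_volume(spec, default_setup_error(), 20),
                    ph$volume)
  expect_lt(max(abs(r1$transform$t - r2$transform$t)), 0.2)
})

test_that("2D/2D orthogonal-pair registration recovers pure translations", {
  spec <- phantom_spec()
  ph <- default_phantom()
  for (tt in list(c(10, 0, 0), c(0, 0, 10), c(5, -8, 12))) {
    tv <- make_treatment_volume(spec, rigid_transform(t = tt), 0)
    res <- align_ne(ph$volume, tv, mode = "2d2d")
    reg <- res$registration
    expect_true(reg$converged)
    expect_equal(reg$mode, "2d2d")
    expect_lt(max(abs(reg$transform$t + tt)), 1)   # maps treatment -> planning
    expect_equal(reg$transform$r, c(0, 0, 0))      # translation-only mode
  }
})

test_that("2D/2D registration validates its geometry", {
  att <- blob_attenuation(n = 32L, spacing = 6, k = 2)
  g45 <- projection_geometry(45, det_rows = 32, det_cols = 32,
                             det_pitch_mm = 6)
  g135 <- projection_geometry(135, det_rows = 32, det_cols = 32,
                              det_pitch_mm = 6)
  p45 <- project(att, g45)
  p135 <- project(att, g135)
  # identical views: zero shift
  reg <- register_2d_pair(p45, p45, p135, p135)
  expect_lt(max(abs(reg$transform$t)), 1e-6)
  # parallel views are degenerate
  expect_error(register_2d_pair(p45, p45, p45, p45), "parallel")
  # mismatched detector geometry
  expect_error(register_2d_pair(p45, p135, p135, p45), "share detector")
})

test_that("align_ne aligns the bone anatomy onto the planning frame", {
  study <- default_study()
  res <- align_ne(study$planning, study$treatment[[1]], mode = "3d3d")
  bone <- study$labels$values == 4L
  resid <- abs(res$volume$values[bone] - study$planning$values[bone])
  # thin crisp bone is mostly boundary voxels, so trilinear resampling sets
  # the residual floor (~75 HU even at the true transform, against a 600 HU
  # bone contrast); registration itself adds little on top of it
  expect_lt(mean(resid), 100)
  oracle <- resample_rigid(study$treatment[[1]], invert(study$true_setup))
  expect_lt(mean(resid), mean(abs(oracle$values[bone] -
                                  study$planning$values[bone])) + 10)

  # zero-setup-error study: identity transform, output ~ input
  t0 <- make_treatment_volume(study$spec, rigid_transform(), 0)
  res0 <- align_ne(study$planning, t0, mode = "3d3d")
  expect_lt(max(abs(res0$registration$transform$t)), 0.15)
  expect_lt(max(abs(res0$registration$transform$r)), 0.15)

  # 3d3d and 2d2d agree on a translation-only study
  tt <- c(6, -9, 11)
  tv <- make_treatment_volume(study$spec, rigid_transform(t = tt), 0)
  r3 <- align_ne(study$planning, tv, mode = "3d3d")$registration
  r2 <- align_ne(study$planning, tv, mode = "2d2d")$registration
  expect_lt(max(abs(r3$transform$t - r2$transform$t)), 1)
})
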