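test_that("build_phantom assigns HU and labels by precedence", {
  spec <- phantom_spec()
  ph <- default_phantom()
  idx <- round((spec$tumor_center_mm - ph$volume$origin) / ph$volume$spacing) + 1
  expect_equal(ph$volume$values[idx[1], idx[2], idx[3]], spec$tumor_hu)
  expect_equal(ph$labels$values[idx[1], idx[2], idx[3]], 3L)

  # far corner is outside the body: air
  expect_equal(ph$volume$values[1, 1, 1], -1024)
  expect_equal(ph$labels$values[1, 1, 1], 0L)

  # label/HU consistency
  expect_true(all(ph$volume$values[ph$labels$values == 2L] == spec$lung_hu))
  expect_true(all(ph$volume$values[ph$labels$values == 4L] == spec$vert_hu))
  expect_true(all(ph$volume$values[ph$labels$values == 1L] == spec$body_hu))

  # determinism
  ph2 <- build_phantom()
  expect_identical(ph$volume$values, ph2$volume$values)
})

test_that("voxelized tumor volume matches the analytic sphere at 1 mm voxels", {
  spec <- phantom_spec(body_semiaxes_mm = c(45, 40), body_z_mm = c(-45, 45),
                       lung_centers_mm = list(c(0, 0)),
                       lung_semiaxes_mm = c(30, 28), lung_z_mm = c(-38, 38),
                       tumor_center_mm = c(0, 0, 0), tumor_radius_mm = 10,
                       vert_radius_mm = 0, process_radius_mm = 0,
                       sternum_radius_mm = 0)
  ph <- build_phantom(spec, shape = c(100L, 100L, 100L), spacing = 1)
  vox <- sum(ph$labels$values == 3L) * prod(ph$volume$spacing)
  expect_lt(abs(vox / (4 / 3 * pi * spec$tumor_radius_mm^3) - 1), 0.05)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(tumor_center_mm = c(0, 0, 0)), "tumor")
  expect_error(phantom_spec(vert_center_xy_mm = c(0, 95)), "body")
  expect_error(build_phantom(shape = c(20L, 20L, 20L), spacing = 2),
               "grid too small")
})

test_that("treatment volumes move the tumor and the anatomy as requested", {
  spec <- phantom_spec()
  base <- default_phantom()

  # no setup error, no shift: identical to the planning phantom
  t0 <- make_treatment_volume(spec, rigid_transform(), 0)
  expect_identical(t0$values, base$volume$values)

  # tumor shift moves the tumor centroid, leaves everything else unchanged
  t1 <- make_treatment_volume(spec, rigid_transform(), -20, with_labels = TRUE)
  c0 <- pibsim:::label_centroid(base$labels, 3L)
  c1 <- pibsim:::label_centroid(t1$labels, 3L)
  expect_lt(max(abs(c1 - c0 - c(0, 0, -20))), 0.5 * 2.5)
  outside_cavity <- base$labels$values %in% c(0L, 1L, 4L) &
    t1$labels$values %in% c(0L, 1L, 4L)
  expect_identical(t1$volume$values[outside_cavity],
                   base$volume$values[outside_cavity])

  # rigid setup moves the vertebral-chain centroid by the translation
  # (chain-only spec: the centroid of a union of bones is not a rigid
  # tracker when voxelization trades mass between components)
  chain_spec <- phantom_spec(process_radius_mm = 0, sternum_radius_mm = 0)
  b2 <- build_phantom(chain_spec)
  t2 <- make_treatment_volume(chain_spec, rigid_transform(t = c(10, -6, 4)),
                              0, with_labels = TRUE)
  v0 <- pibsim:::label_centroid(b2$labels, 4L)
  v2 <- pibsim:::label_centroid(t2$labels, 4L)
  expect_lt(max(abs(v2 - v0 - c(10, -6, 4))), 0.5 * 2.5)

  # a shift that pushes the tumor out of the lung is rejected
  expect_error(make_treatment_volume(spec, rigid_transform(), 200), "tumor")
})

test_that("make_study builds a consistent, reproducible bundle", {
  study <- default_study()
  expect_length(study$treatment, 3L)
  expect_equal(study$true_tumor_shift_mm, c(0, 10, 20))

  # same seed twice: bit-identical
  s2 <- make_study()
  expect_identical(study$planning$values, s2$planning$values)
  for (k in 1:3)
    expect_identical(study$treatment[[k]]$values, s2$treatment[[k]]$values)

  # noise off: states differ only where the cavity contents differ
  l1 <- make_treatment_volume(study$spec, study$true_setup, 0,
                              with_labels = TRUE)
  l2 <- make_treatment_volume(study$spec, study$true_setup, 10,
                              with_labels = TRUE)
  diff_vox <- study$treatment[[1]]$values != study$treatment[[2]]$values
  label_diff <- l1$labels$values != l2$labels$values
  expect_identical(diff_vox, label_diff)

  # ground truth self-consistency: tumor centroid displacement matches
  c1 <- pibsim:::label_centroid(l1$labels, 3L)
  c2 <- pibsim:::label_centroid(l2$labels, 3L)
  expect_lt(max(abs((c2 - c1) - apply_point(study$true_setup, c(0, 0, 10)) +
                    apply_point(study$true_setup, c(0, 0, 0)))), 0.5 * 2.5)

  expect_error(make_study(tumor_shifts_mm = numeric(0)), "non-empty")
})

test_that("NE tissues are stable across respiratory states", {
  study <- default_study()
  l1 <- make_treatment_volume(study$spec, study$true_setup, 0,
                              with_labels = TRUE)
  ne <- l1$labels$values %in% c(1L, 4L)
  for (k in 2:3)
    expect_identical(study$treatment[[k]]$values[ne],
                     study$treatment[[1]]$values[ne])
})

test_that("HU noise raises uniform-region variance by its variance", {
  noisy <- make_study(noise_sd = 30)
  clean <- default_phantom()
  body <- clean$labels$values == 1L
  expect_gt(sum(body), 1e4)
  dn <- noisy$planning$values[body] - clean$volume$values[body]
  expect_lt(abs(var(dn) / 900 - 1), 0.1)
})
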