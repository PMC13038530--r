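test_that("closed forms: zero volume, uniform slab, sphere chord", {
  g <- projection_geometry(det_rows = 5, det_cols = 5, det_pitch_mm = 0.5)

  zero <- attenuation_volume(array(0, c(11, 11, 11)), 2)
  expect_true(all(project(zero, g)$values == 0))
  expect_true(all(project_oracle(zero, g, 0.5)$values == 0))

  # uniform slab mu = 0.02/mm, 101 mm thick along the central ray
  slab <- attenuation_volume(array(0.02, c(11, 101, 11)), 1)
  expect_equal(project(slab, g)$values[3, 3], 0.02 * 101, tolerance = 1e-6)

  # uniform sphere: central ray reads 2 * r * mu within 1% at 1 mm voxels
  sph <- sphere_attenuation(40, 0.01, n = 96L, spacing = 1)
  expect_lt(abs(project(sph, g)$values[3, 3] / (2 * 40 * 0.01) - 1), 0.01)
})

test_that("exact-path projector agrees with the fixed-step reference", {
  set.seed(5)
  worst <- 0
  for (i in 1:3) {
    att <- blob_attenuation()
    g <- projection_geometry(gantry_deg = runif(1, 0, 180),
                             det_rows = 64, det_cols = 64, det_pitch_mm = 3)
    a <- project(att, g)
    b <- project_oracle(att, g, 0.1 * att$spacing[1])
    worst <- max(worst, max(abs(a$values - b$values)) / max(b$values))
  }
  expect_lt(worst, 0.005)

  # halving the step changes the reference by < 0.1%
  att <- blob_attenuation(n = 48L, spacing = 4)
  g <- projection_geometry(det_rows = 32, det_cols = 32, det_pitch_mm = 6)
  b1 <- project_oracle(att, g, 0.8)
  b2 <- project_oracle(att, g, 0.4)
  expect_lt(max(abs(b1$values - b2$values)) / max(b2$values), 0.001)
  expect_error(project_oracle(att, g, 0), "positive")
})

test_that("projection is linear in the attenuation volume", {
  set.seed(8)
  a1 <- blob_attenuation(n = 48L, spacing = 4)
  a2 <- blob_attenuation(n = 48L, spacing = 4)
  g <- projection_geometry(det_rows = 48, det_cols = 48, det_pitch_mm = 4)
  mix <- attenuation_volume(2 * a1$values + 3 * a2$values, a1$spacing,
                            a1$origin)
  lhs <- project(mix, g)$values
  rhs <- 2 * project(a1, g)$values + 3 * project(a2, g)$values
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("display mapping is the inverted exponential, monotone in L", {
  g <- projection_geometry(det_rows = 1, det_cols = 3, det_pitch_mm = 1)
  rad <- radiograph(matrix(c(0, log(2), log(4)), 1), "line_integral", g)
  ii <- to_intensity(rad)
  expect_equal(as.vector(ii$values), c(1, 0.5, 0.25))
  dd <- to_display(rad, rescale = FALSE)
  expect_equal(as.vector(dd$values), c(0, 0.5, 0.75))

  # zero optical depth everywhere displays as uniformly dark
  zero <- radiograph(matrix(0, 1, 3), "line_integral", g)
  expect_true(all(to_display(zero)$values == 0))

  # rescaled display preserves the pixel ordering of the line integral
  set.seed(1)
  r2 <- radiograph(matrix(runif(64, 0, 4), 8),
                   "line_integral",
                   projection_geometry(det_rows = 8, det_cols = 8))
  expect_equal(order(to_display(r2)$values), order(r2$values))
  expect_error(to_display(to_display(r2)), "line-integral")
})

test_that("angle sweeps produce the documented view sets", {
  expect_equal(standard_angles(), seq(0, 165, by = 15))
  expect_length(standard_angles(), 12L)
  expect_equal(orthogonal_angles(), c(45, 135))

  att <- blob_attenuation(n = 32L, spacing = 6, k = 2)
  g <- projection_geometry(det_rows = 24, det_cols = 24, det_pitch_mm = 8)
  sw <- sweep_projections(att, g, standard_angles())
  expect_length(sw, 12L)
  expect_equal(vapply(sw, function(r) r$geometry$gantry_deg, numeric(1)),
               standard_angles(), ignore_attr = TRUE)
  orth <- sweep_projections(att, g, orthogonal_angles())
  expect_length(orth, 2L)

  # periodicity: theta and theta + 360 give the same image
  g1 <- g; g1$gantry_deg <- 30
  g2 <- g; g2$gantry_deg <- 390
  expect_equal(project(att, g1)$values, project(att, g2)$values,
               tolerance = 1e-9)
})

test_that("a sphere at the isocenter magnifies by SID/SAD", {
  # opaque sphere so the intensity half-max sits at the geometric shadow edge
  sph <- sphere_attenuation(40, 0.1, n = 96L, spacing = 1.5)
  g <- projection_geometry(det_rows = 128, det_cols = 128, det_pitch_mm = 1)
  D <- to_display(project(sph, g), rescale = FALSE)$values
  prof <- (D[64, ] + D[65, ]) / 2
  above <- which(prof >= max(prof) / 2)
  r_meas <- (max(above) - min(above)) / 2  # px = mm at 1 mm pitch
  expect_lt(abs(r_meas / (40 * g$sid_mm / g$sad_mm) - 1), 0.02)
})

test_that("shifting the volume by one pitch-equivalent shifts the image one pixel", {
  g <- projection_geometry(gantry_deg = 0, det_rows = 128, det_cols = 128)
  dx <- g$det_pitch_mm * g$sad_mm / g$sid_mm
  set.seed(3)
  ctrs <- cbind(runif(6, -25, 25), runif(6, -25, 25), runif(6, -25, 25))
  sig <- runif(6, 5, 10)
  # fine voxels: the projected staircase of the voxel model is small
  # relative to the detector pitch
  blobs <- function(shift) {
    n <- 128L; sp <- 0.8
    cs <- pibsim:::voxel_centers(c(n, n, n), rep(sp, 3),
                                 -(c(n, n, n) - 1) / 2 * sp)
    v <- 0
    for (i in 1:6)
      v <- v + 0.02 * exp(-rowSums(sweep(cs, 2, ctrs[i, ] +
                                           c(shift, 0, 0))^2) / (2 * sig[i]^2))
    attenuation_volume(array(v, c(n, n, n)), sp)
  }
  sh <- pibsim:::xcorr_shift_2d(project(blobs(0), g)$values,
                                project(blobs(dx), g)$values)
  expect_lt(abs(sh$dr), 0.25)
  expect_lt(abs(sh$dc - 1), 0.25)
})

test_that("Poisson noise is seeded and stays in the line-integral domain", {
  att <- blob_attenuation(n = 32L, spacing = 6, k = 2)
  g <- projection_geometry(det_rows = 32, det_cols = 32, det_pitch_mm = 6)
  r <- project(att, g)
  n1 <- add_poisson_noise(r, i0 = 1e4, seed = 3)
  n2 <- add_poisson_noise(r, i0 = 1e4, seed = 3)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0))
  expect_false(identical(n1$values, add_poisson_noise(r, 1e4, 4)$values))
})
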