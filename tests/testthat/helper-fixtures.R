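# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixtures$study)) .fixtures$study <- make_study()
  .fixtures$study
}

default_phantom <- function() {
  if (is.null(.fixtures$phantom)) .fixtures$phantom <- build_phantom()
  .fixtures$phantom
}

# oracle-aligned pipeline run over the standard 12-angle sweep
oracle_run <- function() {
  if (is.null(.fixtures$oracle_run))
    .fixtures$oracle_run <- run_pipeline(default_study(), mode = "oracle")
  .fixtures$oracle_run
}

# smooth random attenuation field: sum of broad Gaussian blobs, contained
# well inside the grid so the exact-path and interpolating integrators
# approximate the same continuum integral
blob_attenuation <- function(n = 96L, spacing = 2, k = 4,
                             center_range = 20, sigma_range = c(32, 48)) {
  cs <- pibsim:::voxel_centers(c(n, n, n), rep(spacing, 3),
                               -(c(n, n, n) - 1) / 2 * spacing)
  vol <- 0
  for (i in seq_len(k)) {
    c0 <- runif(3, -center_range, center_range)
    s <- runif(1, sigma_range[1], sigma_range[2])
    a <- runif(1, 0.005, 0.02)
    vol <- vol + a * exp(-rowSums(sweep(cs, 2, c0)^2) / (2 * s^2))
  }
  attenuation_volume(array(vol, c(n, n, n)), spacing)
}

# uniform attenuation sphere at the isocenter
sphere_attenuation <- function(radius_mm, mu, n = 96L, spacing = 1) {
  cs <- pibsim:::voxel_centers(c(n, n, n), rep(spacing, 3),
                               -(c(n, n, n) - 1) / 2 * spacing)
  attenuation_volume(array(mu * (rowSums(cs^2) <= radius_mm^2), c(n, n, n)),
                     spacing)
}

# random six-dimensional setup error with |t| <= max_t mm, |r| <= max_r deg
random_setup <- function(max_t = 20, max_r = 3) {
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  rigid_transform(t = dir * runif(1, 0, max_t), r = runif(3, -max_r, max_r))
}
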