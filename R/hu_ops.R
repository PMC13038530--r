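# HU-domain volume operations: thoracic-cavity segmentation, the
# non-essential-tissue override, HU -> linear attenuation conversion, and
# rigid resampling onto the normal axes.

#' Linear attenuation volume (mm^-1)
#'
#' @param values 3D non-negative numeric array of linear attenuation
#'   coefficients in mm^-1.
#' @param spacing,origin grid geometry as in [voxel_volume()].
#' @return An object of class `attenuation_volume`.
#' @export
attenuation_volume <- function(values, spacing, origin = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (min(values) < 0) stop("attenuation coefficients must be non-negative")
  spacing <- if (length(spacing) == 1L) rep(as.numeric(spacing), 3) else as.numeric(spacing)
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  cat(sprintf("<attenuation_volume> %s voxels @ %s mm, mu range [%.5g, %.5g] mm^-1\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Segment the thoracic cavity
#'
#' With a label volume (the synthetic path) the cavity is exactly the union
#' of the lung and tumor labels. Without labels (the generic path), air-like
#' voxels (HU below `threshold_hu`) enclosed by the body's largest connected
#' component are taken and morphologically closed with a ball so that small
#' gaps around the solid tumor are bridged.
#'
#' @param volume a [voxel_volume()].
#' @param labels optional [label_mask()] on the same grid.
#' @param threshold_hu air threshold for the generic path (default -400 HU).
#' @param close_radius_vox closing ball radius in voxels (default 3).
#' @return A binary [label_mask()] with values 0 (background) and
#'   5 (thoracic cavity).
#' @export
segment_cavity <- function(volume, labels = NULL, threshold_hu = -400,
                           close_radius_vox = 3) {
  dims <- dim(volume$values)
  if (!is.null(labels)) {
    if (!same_grid(volume, labels)) stop("labels geometry must match the volume")
    cav <- labels$values == 2L | labels$values == 3L
  } else {
    air <- volume$values < threshold_hu
    # air components not reaching the volume border are enclosed by the
    # body's (largest) connected component
    air_lab <- array(cpp_label_components(as.vector(air), as.integer(dims)), dims)
    border <- unique(c(air_lab[c(1, dims[1]), , ], air_lab[, c(1, dims[2]), ],
                       air_lab[, , c(1, dims[3])]))
    border <- border[border > 0]
    enclosed <- air_lab > 0 & !(air_lab %in% border)
    if (close_radius_vox > 0 && any(enclosed)) {
      off <- ball_offsets(close_radius_vox)
      d <- cpp_morph(as.vector(enclosed), as.integer(dims), off, TRUE)
      enclosed <- array(cpp_morph(d, as.integer(dims), off, FALSE), dims)
    }
    cav <- enclosed
  }
  label_mask(array(ifelse(cav, 5L, 0L), dims), volume$spacing, volume$origin)
}

#' Invert a binary mask
#' @param mask a binary [label_mask()].
#' @return The complementary mask (selected voxels become background and
#'   vice versa), keeping the nonzero label value.
#' @export
invert_mask <- function(mask) {
  sel <- mask$values != 0L
  val <- if (any(sel)) max(mask$values) else 5L
  label_mask(array(ifelse(sel, 0L, val), dim(mask$values)),
             mask$spacing, mask$origin)
}

#' Override CT numbers inside a mask
#'
#' @param volume a [voxel_volume()].
#' @param mask a [label_mask()] on the same grid; nonzero voxels are
#'   overridden.
#' @param value_hu replacement CT number (default -1024 HU, the lowest value
#'   of a 12-bit scanner).
#' @return A new [voxel_volume()]; the input is not modified.
#' @export
override_region <- function(volume, mask, value_hu = -1024) {
  if (!same_grid(volume, mask)) stop("mask geometry must match the volume")
  v <- volume$values
  v[mask$values != 0L] <- value_hu
  voxel_volume(v, volume$spacing, volume$origin)
}

#' Convert CT numbers to linear attenuation
#'
#' Uses the single-energy linear ramp `mu = mu_water * (1 + HU/1000)` for
#' HU above -1000; CT numbers of -1000 HU and below map to an attenuation
#' coefficient of exactly 0, so the -1024 HU override removes all signal.
#'
#' @param volume a [voxel_volume()].
#' @param mu_water_per_mm attenuation of water, mm^-1 (default 0.019,
#'   approximately water at the effective energy of a 120 kVp beam).
#' @return An [attenuation_volume()].
#' @export
hu_to_mu <- function(volume, mu_water_per_mm = 0.019) {
  if (mu_water_per_mm <= 0) stop("mu_water_per_mm must be positive")
  mu <- mu_water_per_mm * (1 + volume$values / 1000)
  mu[volume$values <= -1000] <- 0
  mu[mu < 0] <- 0
  attenuation_volume(mu, volume$spacing, volume$origin)
}

#' Rigidly resample a volume onto its own grid
#'
#' Applies a rigid motion to the image content while keeping the grid on the
#' normal axes: each output voxel samples the input at the inverse-transformed
#' location via trilinear interpolation (nearest-neighbor for label volumes,
#' which must not be interpolated). Samples falling outside the input read
#' `fill`.
#'
#' @param volume a [voxel_volume()], [attenuation_volume()] or
#'   [label_mask()].
#' @param transform the rigid motion to apply, a [rigid_transform()].
#' @param fill out-of-volume fill value (default -1024 for HU volumes, 0
#'   otherwise).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return An object of the same class as `volume` on the same grid.
#' @export
resample_rigid <- function(volume, transform, fill = NULL,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_lab <- inherits(volume, "label_mask")
  if (is_lab) interpolation <- "nearest"
  if (is.null(fill))
    fill <- if (inherits(volume, "voxel_volume")) -1024 else 0
  dims <- dim(volume$values)
  M <- transform_matrix(invert(transform))[1:3, , drop = FALSE]
  out <- cpp_resample(as.vector(as.numeric(volume$values)), as.integer(dims),
                      volume$spacing, volume$origin, M, fill,
                      interpolation == "nearest")
  out <- array(out, dims)
  if (is_lab)
    return(label_mask(array(as.integer(round(out)), dims), volume$spacing,
                      volume$origin, table = volume$table))
  if (inherits(volume, "attenuation_volume"))
    return(attenuation_volume(out, volume$spacing, volume$origin))
  voxel_volume(out, volume$spacing, volume$origin)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian blur, available as an optional realism dial for the
#' otherwise crisp analytic phantoms (default off everywhere).
#'
#' @param volume a [voxel_volume()] or [attenuation_volume()].
#' @param sigma_mm Gaussian standard deviation, mm.
#' @return A volume of the same class.
#' @export
smooth_gaussian <- function(volume, sigma_mm) {
  v <- as.vector(as.numeric(volume$values))
  dims <- as.integer(dim(volume$values))
  for (ax in 1:3) {
    s <- sigma_mm / volume$spacing[ax]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-0.5 * ((-half):half / s)^2)
    k <- k / sum(k)
    v <- cpp_conv1d(v, dims, k, ax)
  }
  out <- array(v, dims)
  if (inherits(volume, "attenuation_volume"))
    attenuation_volume(out, volume$spacing, volume$origin)
  else voxel_volume(out, volume$spacing, volume$origin)
}
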