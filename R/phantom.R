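# Procedural digital thorax phantom: anthropomorphic elliptic-cylinder body,
# two lung-equivalent regions, a spherical tumor, and a posterior midline
# vertebral chain. Volumes are voxelized analytically (each voxel takes the
# HU of the material containing its center), so treatment-day volumes carry
# no interpolation blur.

#' Specification of the digital thorax phantom
#'
#' Geometry is expressed in patient mm coordinates with the isocenter at the
#' origin. The body is an elliptic cylinder of water-equivalent material; the
#' lungs are two lower-density elliptic cylinders; the tumor is a solid
#' sphere inside one lung; the vertebral column is a chain of posterior
#' midline cylinders with small lateral transverse-process spheres so that
#' bone-driven registration can observe all six rigid degrees of freedom.
#'
#' @param body_semiaxes_mm body ellipse semi-axes (x, y), mm.
#' @param body_z_mm inferior/superior extent of the body, mm.
#' @param body_hu body CT number (water-equivalent default 0 HU).
#' @param lung_centers_mm list of (x, y) centers of the lung cylinders, mm.
#' @param lung_semiaxes_mm lung ellipse semi-axes (x, y), mm.
#' @param lung_z_mm inferior/superior extent of the lungs, mm.
#' @param lung_hu lung CT number.
#' @param tumor_center_mm tumor sphere center, mm (planning position).
#' @param tumor_radius_mm tumor radius, mm.
#' @param tumor_hu tumor CT number (solid-tissue default +20 HU).
#' @param vert_center_xy_mm axial (x, y) position of the vertebral chain, mm.
#' @param vert_radius_mm vertebral body radius, mm.
#' @param vert_height_mm height of each vertebral body, mm.
#' @param vert_spacing_mm center-to-center spacing of consecutive bodies, mm.
#' @param vert_hu bone CT number.
#' @param process_radius_mm radius of the transverse-process spheres, mm
#'   (0 disables them).
#' @param process_offset_mm lateral (x) and posterior (y) offset of the
#'   process spheres from the chain axis, mm.
#' @param sternum_center_xy_mm axial (x, y) position of the sternum rod, mm.
#' @param sternum_radius_mm sternum rod radius, mm (0 disables it). Anterior
#'   bone far from the spine is what makes the rotation about the vertebral
#'   axis observable to bone-driven registration, as it is in real patients.
#' @param background_hu CT number outside the body (air, -1024 HU).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes_mm = c(150, 95),
                         body_z_mm = c(-140, 140),
                         body_hu = 0,
                         lung_centers_mm = list(c(70, -10), c(-70, -10)),
                         lung_semiaxes_mm = c(50, 65),
                         lung_z_mm = c(-120, 120),
                         lung_hu = -700,
                         tumor_center_mm = c(-50, -27, -40),
                         tumor_radius_mm = 15,
                         tumor_hu = 20,
                         vert_center_xy_mm = c(0, 60),
                         vert_radius_mm = 12,
                         vert_height_mm = 20,
                         vert_spacing_mm = 25,
                         vert_hu = 600,
                         process_radius_mm = 6,
                         process_offset_mm = c(20, 10),
                         sternum_center_xy_mm = c(0, -78),
                         sternum_radius_mm = 8,
                         background_hu = -1024) {
  spec <- structure(list(
    body_semiaxes_mm = body_semiaxes_mm, body_z_mm = sort(body_z_mm),
    body_hu = body_hu,
    lung_centers_mm = lung_centers_mm, lung_semiaxes_mm = lung_semiaxes_mm,
    lung_z_mm = sort(lung_z_mm), lung_hu = lung_hu,
    tumor_center_mm = tumor_center_mm, tumor_radius_mm = tumor_radius_mm,
    tumor_hu = tumor_hu,
    vert_center_xy_mm = vert_center_xy_mm, vert_radius_mm = vert_radius_mm,
    vert_height_mm = vert_height_mm, vert_spacing_mm = vert_spacing_mm,
    vert_hu = vert_hu,
    process_radius_mm = process_radius_mm,
    process_offset_mm = process_offset_mm,
    sternum_center_xy_mm = sternum_center_xy_mm,
    sternum_radius_mm = sternum_radius_mm,
    background_hu = background_hu), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# z centers of the vertebral bodies: as many as fit in the body extent
vertebra_centers_z <- function(spec) {
  z0 <- spec$body_z_mm[1] + spec$vert_height_mm / 2
  z1 <- spec$body_z_mm[2] - spec$vert_height_mm / 2
  if (z1 < z0) return(numeric(0))
  seq(z0, z1, by = spec$vert_spacing_mm)
}

# conservative containment check of a sphere inside an elliptic cylinder
sphere_in_ellipse <- function(center_xy, r, ell_center, semi, z, zr) {
  dx <- (abs(center_xy[1] - ell_center[1]) + r) / semi[1]
  dy <- (abs(center_xy[2] - ell_center[2]) + r) / semi[2]
  dx^2 + dy^2 <= 1 && z - r >= zr[1] && z + r <= zr[2]
}

validate_phantom_spec <- function(spec, tumor_dz = 0) {
  hu <- c(spec$body_hu, spec$lung_hu, spec$tumor_hu, spec$vert_hu,
          spec$background_hu)
  if (any(hu < -1024 | hu > 3071))
    stop("invalid phantom spec: HU values outside [-1024, 3071]")
  tc <- spec$tumor_center_mm + c(0, 0, tumor_dz)
  in_lung <- any(vapply(spec$lung_centers_mm, function(lc)
    sphere_in_ellipse(tc[1:2], spec$tumor_radius_mm, lc,
                      spec$lung_semiaxes_mm, tc[3], spec$lung_z_mm),
    logical(1)))
  if (!in_lung)
    stop("invalid phantom spec: tumor sphere not fully inside a lung region")
  # vertebral chain inside the body, outside both lungs
  v <- spec$vert_center_xy_mm
  in_body_xy <- function(cxy, r)
    ((abs(cxy[1]) + r) / spec$body_semiaxes_mm[1])^2 +
    ((abs(cxy[2]) + r) / spec$body_semiaxes_mm[2])^2 <= 1
  ok <- spec$vert_radius_mm <= 0 || in_body_xy(v, spec$vert_radius_mm)
  if (ok && spec$vert_radius_mm > 0 && spec$process_radius_mm > 0) {
    for (sx in c(-1, 1)) {
      pc <- c(v[1] + sx * spec$process_offset_mm[1],
              v[2] + spec$process_offset_mm[2])
      ok <- ok && in_body_xy(pc, spec$process_radius_mm)
    }
  }
  if (spec$sternum_radius_mm > 0)
    ok <- ok && in_body_xy(spec$sternum_center_xy_mm, spec$sternum_radius_mm)
  if (!ok)
    stop("invalid phantom spec: bones extend outside the body")
  bone_xy <- if (spec$vert_radius_mm > 0) list(c(v, spec$vert_radius_mm)) else list()
  if (spec$sternum_radius_mm > 0)
    bone_xy <- c(bone_xy, list(c(spec$sternum_center_xy_mm,
                                 spec$sternum_radius_mm)))
  for (b in bone_xy) for (lc in spec$lung_centers_mm) {
    d <- sqrt(((b[1] - lc[1]) / spec$lung_semiaxes_mm[1])^2 +
              ((b[2] - lc[2]) / spec$lung_semiaxes_mm[2])^2)
    if (d < 1 + b[3] / min(spec$lung_semiaxes_mm))
      stop("invalid phantom spec: bones overlap a lung region")
  }
  invisible(spec)
}

# Evaluate phantom materials at arbitrary world points (n x 3). Precedence:
# tumor > vertebra > lung > body > background. Returns HU and label vectors.
phantom_materials <- function(coords, spec, tumor_dz = 0) {
  n <- nrow(coords)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  hu <- rep(spec$background_hu, n)
  lab <- integer(n)

  in_body <- (x / spec$body_semiaxes_mm[1])^2 +
             (y / spec$body_semiaxes_mm[2])^2 <= 1 &
             z >= spec$body_z_mm[1] & z <= spec$body_z_mm[2]
  hu[in_body] <- spec$body_hu
  lab[in_body] <- 1L

  in_lung <- rep(FALSE, n)
  for (lc in spec$lung_centers_mm) {
    in_lung <- in_lung |
      (((x - lc[1]) / spec$lung_semiaxes_mm[1])^2 +
       ((y - lc[2]) / spec$lung_semiaxes_mm[2])^2 <= 1 &
       z >= spec$lung_z_mm[1] & z <= spec$lung_z_mm[2])
  }
  hu[in_lung] <- spec$lung_hu
  lab[in_lung] <- 2L

  vz <- vertebra_centers_z(spec)
  if (length(vz) > 0 && spec$vert_radius_mm > 0) {
    vc <- spec$vert_center_xy_mm
    r2 <- (x - vc[1])^2 + (y - vc[2])^2
    span <- range(vz)
    # each body occupies |z - nearest center| <= height/2
    zn <- vz[pmin(pmax(round((z - span[1]) / spec$vert_spacing_mm), 0),
                  length(vz) - 1) + 1]
    in_vert <- r2 <= spec$vert_radius_mm^2 &
      abs(z - zn) <= spec$vert_height_mm / 2
    if (spec$process_radius_mm > 0) {
      px <- spec$process_offset_mm[1]; py <- spec$process_offset_mm[2]
      for (sx in c(-1, 1)) {
        d2 <- (x - (vc[1] + sx * px))^2 + (y - (vc[2] + py))^2 + (z - zn)^2
        in_vert <- in_vert | d2 <= spec$process_radius_mm^2
      }
    }
    hu[in_vert] <- spec$vert_hu
    lab[in_vert] <- 4L
  }
  if (spec$sternum_radius_mm > 0) {
    sc <- spec$sternum_center_xy_mm
    in_st <- (x - sc[1])^2 + (y - sc[2])^2 <= spec$sternum_radius_mm^2 &
      z >= spec$body_z_mm[1] & z <= spec$body_z_mm[2]
    hu[in_st] <- spec$vert_hu
    lab[in_st] <- 4L
  }

  tc <- spec$tumor_center_mm + c(0, 0, tumor_dz)
  in_tumor <- (x - tc[1])^2 + (y - tc[2])^2 + (z - tc[3])^2 <=
    spec$tumor_radius_mm^2
  hu[in_tumor] <- spec$tumor_hu
  lab[in_tumor] <- 3L

  list(hu = hu, label = lab)
}

check_grid_contains_body <- function(spec, shape, spacing, origin) {
  hi <- origin + (shape - 1) * spacing
  if (-spec$body_semiaxes_mm[1] < origin[1] || spec$body_semiaxes_mm[1] > hi[1] ||
      -spec$body_semiaxes_mm[2] < origin[2] || spec$body_semiaxes_mm[2] > hi[2] ||
      spec$body_z_mm[1] < origin[3] - spacing[3] / 2 ||
      spec$body_z_mm[2] > hi[3] + spacing[3] / 2)
    stop("invalid phantom spec: grid too small to contain the body")
}

#' Voxelize the planning phantom
#'
#' Deterministically renders the phantom onto a regular grid centered on the
#' isocenter. Each voxel takes the HU of the material containing its center
#' (precedence tumor > vertebra > lung > body > background); the label volume
#' is consistent with the HU assignment.
#'
#' @param spec a [phantom_spec()].
#' @param shape length-3 integer voxel counts (default desk-scale 160 x 128
#'   x 120).
#' @param spacing voxel size in mm (scalar or length-3; default 2.5).
#' @return A list with elements `volume` ([voxel_volume()]) and `labels`
#'   ([label_mask()]).
#' @export
build_phantom <- function(spec = phantom_spec(), shape = c(160L, 128L, 120L),
                          spacing = 2.5) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3) else as.numeric(spacing)
  shape <- as.integer(shape)
  origin <- -(shape - 1) / 2 * spacing
  validate_phantom_spec(spec)
  check_grid_contains_body(spec, shape, spacing, origin)
  mat <- phantom_materials(voxel_centers(shape, spacing, origin), spec)
  list(volume = voxel_volume(array(mat$hu, shape), spacing, origin),
       labels = label_mask(array(mat$label, shape), spacing, origin))
}

#' Voxelize one treatment-day volume
#'
#' The tumor is displaced by `(0, 0, tumor_dz_mm)` (superior positive) and
#' the whole phantom is then rigidly moved by `setup`. Shapes are transformed
#' before voxelization, so the result carries no interpolation blur.
#'
#' @param spec a [phantom_spec()].
#' @param setup the six-dimensional setup error, a [rigid_transform()].
#' @param tumor_dz_mm superior tumor displacement relative to the planning
#'   position, mm.
#' @param shape,spacing grid as in [build_phantom()].
#' @param with_labels also return the treatment-day label volume.
#' @return A [voxel_volume()], or a list `(volume, labels)` if `with_labels`.
#' @export
make_treatment_volume <- function(spec, setup = rigid_transform(),
                                  tumor_dz_mm = 0,
                                  shape = c(160L, 128L, 120L), spacing = 2.5,
                                  with_labels = FALSE) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3) else as.numeric(spacing)
  shape <- as.integer(shape)
  origin <- -(shape - 1) / 2 * spacing
  validate_phantom_spec(spec, tumor_dz = tumor_dz_mm)
  check_grid_contains_body(spec, shape, spacing, origin)
  coords <- voxel_centers(shape, spacing, origin)
  if (!is_identity_transform(setup))
    coords <- apply_point(invert(setup), coords)
  mat <- phantom_materials(coords, spec, tumor_dz = tumor_dz_mm)
  vol <- voxel_volume(array(mat$hu, shape), spacing, origin)
  if (!with_labels) return(vol)
  list(volume = vol, labels = label_mask(array(mat$label, shape), spacing, origin))
}

#' Default six-dimensional setup error of the synthetic study
#' @return A [rigid_transform()] with translation (8, -5, 12) mm and rotation
#'   (1, -1, 2) degrees — a clinically plausible setup error.
#' @export
default_setup_error <- function() {
  rigid_transform(t = c(8, -5, 12), r = c(1, -1, 2))
}

#' Generate a complete synthetic study
#'
#' Builds the planning CT (tumor at the most inferior position, emulating
#' end-of-inhalation), its labels, and one treatment-day CT per requested
#' superior tumor shift, all sharing one setup error. Optional Gaussian HU
#' noise is applied with the stored seed.
#'
#' @param spec a [phantom_spec()].
#' @param setup setup error applied to every treatment-day volume.
#' @param tumor_shifts_mm superior tumor displacement per respiratory state,
#'   mm (default `c(0, 10, 20)`: end-inhalation, mid-inhalation,
#'   end-exhalation).
#' @param shape,spacing grid as in [build_phantom()].
#' @param seed integer seed controlling the noise draws.
#' @param noise_sd HU standard deviation of additive Gaussian noise
#'   (default 0: noise off).
#' @return An object of class `study_bundle` with elements `planning`,
#'   `labels`, `treatment` (list of volumes), `true_setup`,
#'   `true_tumor_shift_mm`, `true_tumor_planning` / `true_tumor_treatment`
#'   (per-state tumor centers in the planning-aligned and treatment frames),
#'   `spec`, `seed`, `noise_sd`.
#' @export
make_study <- function(spec = phantom_spec(), setup = default_setup_error(),
                       tumor_shifts_mm = c(0, 10, 20),
                       shape = c(160L, 128L, 120L), spacing = 2.5,
                       seed = 1L, noise_sd = 0) {
  if (length(tumor_shifts_mm) == 0) stop("tumor_shifts_mm must be non-empty")
  ph <- build_phantom(spec, shape, spacing)
  planning <- ph$volume
  add_noise <- function(vol, k) {
    if (noise_sd <= 0) return(vol)
    set.seed(as.integer(seed) + k)
    v <- vol$values + array(rnorm(length(vol$values), sd = noise_sd),
                            dim(vol$values))
    vol$values <- pmin(pmax(v, -1024), 3071)
    vol
  }
  planning <- add_noise(planning, 0L)
  treatment <- lapply(seq_along(tumor_shifts_mm), function(k) {
    add_noise(make_treatment_volume(spec, setup, tumor_shifts_mm[k],
                                    shape, spacing), k)
  })
  tumor_planning <- lapply(tumor_shifts_mm, function(dz)
    spec$tumor_center_mm + c(0, 0, dz))
  tumor_treatment <- lapply(tumor_planning, function(p) apply_point(setup, p))
  structure(list(planning = planning, labels = ph$labels,
                 treatment = treatment, true_setup = setup,
                 true_tumor_shift_mm = as.numeric(tumor_shifts_mm),
                 true_tumor_planning = tumor_planning,
                 true_tumor_treatment = tumor_treatment,
                 spec = spec, seed = as.integer(seed), noise_sd = noise_sd),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %s voxels @ %s mm; %d treatment state(s), SI shifts (%s) mm\n",
              paste(dim(x$planning$values), collapse = "x"),
              paste(format(x$planning$spacing), collapse = "x"),
              length(x$treatment),
              paste(x$true_tumor_shift_mm, collapse = ", ")))
  cat(sprintf("  setup error t = (%s) mm, r = (%s) deg; seed %d, noise SD %g HU\n",
              paste(x$true_setup$t, collapse = ", "),
              paste(x$true_setup$r, collapse = ", "),
              x$seed, x$noise_sd))
  invisible(x)
}

# centroid of a labelled region in world mm (used by ground-truth checks)
label_centroid <- function(labels, which) {
  idx <- which(labels$values == which, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_, NA_real_))
  labels$origin + (colMeans(idx) - 1) * labels$spacing
}
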