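#' @useDynLib pibsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var rnorm runif quantile median fft
#' @importFrom utils modifyList write.csv read.csv
"_PACKAGE"

# Patient coordinate convention used throughout: LPS-style axes with a supine
# patient — +x patient-left, +y posterior, +z superior. Voxel (i,j,k) (1-based
# in R) has world position origin + (i-1, j-1, k-1) * spacing, in mm.

#' 3D scalar volume of CT numbers
#'
#' A `voxel_volume` wraps a 3D array of Hounsfield units together with its
#' voxel spacing (mm) and the world position of the first voxel center.
#' CT numbers are constrained to the 12-bit scanner range \[-1024, 3071\].
#'
#' @param values 3D numeric array (HU).
#' @param spacing length-3 positive numeric, voxel size in mm per axis.
#' @param origin length-3 numeric, world mm position of voxel (1,1,1)'s center.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("all three spacings must be strictly positive")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  rng <- range(values)
  if (rng[1] < -1024 - 1e-9 || rng[2] > 3071 + 1e-9)
    stop("CT numbers must lie in [-1024, 3071]")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels @ %s mm, origin (%s) mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integer label volume sharing a parent volume's grid
#'
#' Label semantics: 0 background, 1 body, 2 lung, 3 tumor, 4 bone,
#' 5 thoracic cavity.
#'
#' @param values 3D integer array of labels.
#' @param spacing,origin grid geometry, as in [voxel_volume()].
#' @param table named integer vector declaring the admissible labels.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(values, spacing, origin = NULL,
                       table = c(background = 0L, body = 1L, lung = 2L,
                                 tumor = 3L, bone = 4L, cavity = 5L)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  storage.mode(values) <- "integer"
  if (!all(unique(as.vector(values)) %in% table))
    stop("labels outside the declared table")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), table = table),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(x$values)
  cat(sprintf("<label_mask> %s voxels; counts: %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Six-parameter rigid-body transform
#'
#' Translations in mm, rotations in degrees applied intrinsically in the
#' fixed order Z, then Y, then X about `center` (default: the isocenter at
#' the world origin), followed by the translation:
#' `p' = Rz Ry Rx (p - center) + center + t`.
#'
#' @param t length-3 translation, mm.
#' @param r length-3 rotation angles (rx, ry, rz), degrees.
#' @param center rotation center, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(t = c(0, 0, 0), r = c(0, 0, 0), center = c(0, 0, 0)) {
  structure(list(t = as.numeric(t), r = as.numeric(r),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, r = (%s) deg, center = (%s) mm\n",
              paste(format(x$t, digits = 6), collapse = ", "),
              paste(format(x$r, digits = 6), collapse = ", "),
              paste(format(x$center, digits = 6), collapse = ", ")))
  invisible(x)
}

rot_matrix <- function(r_deg) {
  a <- r_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param x a [rigid_transform()].
#' @return 4x4 numeric matrix acting on column vectors.
#' @export
transform_matrix <- function(x) {
  R <- rot_matrix(x$r)
  d <- x$t + x$center - as.vector(R %*% x$center)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- d
  M
}

matrix_to_transform <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock: fold everything into rz
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  }
  r <- c(rx, ry, rz) * 180 / pi
  d <- M[1:3, 4]
  t <- d - center + as.vector(R %*% center)
  rigid_transform(t = t, r = r, center = center)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects sharing the same rotation center.
#' @return The composed [rigid_transform()].
#' @export
compose <- function(a, b) {
  if (max(abs(a$center - b$center)) > 1e-9)
    stop("transforms must share the same rotation center")
  matrix_to_transform(transform_matrix(a) %*% transform_matrix(b), a$center)
}

#' Invert a rigid transform
#' @param x a [rigid_transform()].
#' @return The inverse [rigid_transform()] (same rotation center).
#' @export
invert <- function(x) {
  M <- transform_matrix(x)
  Minv <- diag(4)
  Rt <- t(M[1:3, 1:3])
  Minv[1:3, 1:3] <- Rt
  Minv[1:3, 4] <- -as.vector(Rt %*% M[1:3, 4])
  matrix_to_transform(Minv, x$center)
}

#' Apply a rigid transform to points
#' @param x a [rigid_transform()].
#' @param p length-3 vector or n x 3 matrix of points, mm.
#' @return Transformed points, same shape as `p`.
#' @export
apply_point <- function(x, p) {
  M <- transform_matrix(x)
  if (is.matrix(p)) {
    sweep(p %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
  } else {
    as.vector(M[1:3, 1:3] %*% p) + M[1:3, 4]
  }
}

is_identity_transform <- function(x, tol = 1e-9) {
  max(abs(x$t)) < tol && max(abs(x$r)) < tol
}

#' Cone-beam projection geometry
#'
#' Gantry angle 0 deg places the source anterior of a supine patient; angles
#' increase toward patient-left. The central ray passes through `isocenter`
#' and meets the detector orthogonally at its center. Detector u lies in the
#' axial plane, v is anti-parallel to patient z (image row 1 = superior).
#'
#' @param gantry_deg gantry angle, degrees.
#' @param sad_mm source-to-axis distance, mm.
#' @param sid_mm source-to-imager distance, mm (must exceed `sad_mm`).
#' @param det_rows,det_cols detector pixel counts.
#' @param det_pitch_mm detector pixel pitch, mm.
#' @param isocenter world point the rotation axis passes through, mm.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(gantry_deg = 0, sad_mm = 1000, sid_mm = 1500,
                                det_rows = 256L, det_cols = 256L,
                                det_pitch_mm = 1.668,
                                isocenter = c(0, 0, 0)) {
  if (!(sid_mm > sad_mm && sad_mm > 0))
    stop("projection geometry requires sid_mm > sad_mm > 0")
  structure(list(gantry_deg = as.numeric(gantry_deg), sad_mm = sad_mm,
                 sid_mm = sid_mm, det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols),
                 det_pitch_mm = det_pitch_mm,
                 isocenter = as.numeric(isocenter)),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> gantry %.1f deg, SAD %.0f / SID %.0f mm, detector %dx%d @ %.4g mm\n",
              x$gantry_deg, x$sad_mm, x$sid_mm, x$det_rows, x$det_cols,
              x$det_pitch_mm))
  invisible(x)
}

# Unit vectors and key points of one acquisition: source position, ray
# direction through the isocenter, detector center and in-plane axes.
geometry_vectors <- function(geom) {
  th <- geom$gantry_deg * pi / 180
  us <- c(sin(th), -cos(th), 0)        # isocenter -> source direction
  src <- geom$isocenter + geom$sad_mm * us
  dhat <- -us
  uhat <- c(cos(th), sin(th), 0)
  vhat <- c(0, 0, -1)
  det_center <- src + geom$sid_mm * dhat
  list(src = src, dhat = dhat, uhat = uhat, vhat = vhat,
       det_center = det_center)
}

#' Source position of a projection geometry
#' @param geom a [projection_geometry()].
#' @return Length-3 world position of the X-ray source, mm.
#' @export
source_position <- function(geom) geometry_vectors(geom)$src

#' 2D radiograph tagged with its value domain
#'
#' @param values det_rows x det_cols numeric matrix.
#' @param domain one of `"line_integral"` (dimensionless optical depth, >= 0),
#'   `"intensity"` (transmitted fraction in (0, 1\]) or `"display"` (unitless,
#'   inverted so thicker tissue is brighter).
#' @param geometry the [projection_geometry()] that produced the image.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(values, domain = c("line_integral", "intensity", "display"),
                       geometry) {
  domain <- match.arg(domain)
  stopifnot(is.matrix(values))
  if (!identical(dim(values), c(geometry$det_rows, geometry$det_cols)))
    stop("radiograph dimensions must match the detector grid")
  if (domain == "line_integral" && min(values) < -1e-9)
    stop("line-integral values must be non-negative")
  if (domain == "intensity" && (min(values) <= 0 || max(values) > 1 + 1e-12))
    stop("intensity values must lie in (0, 1]")
  structure(list(values = values, domain = domain,
                 pitch_mm = geometry$det_pitch_mm, geometry = geometry),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %dx%d px @ %.4g mm, domain %s, gantry %.1f deg, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pitch_mm, x$domain,
              x$geometry$gantry_deg, min(x$values), max(x$values)))
  invisible(x)
}

same_detector_geometry <- function(a, b, tol = 1e-9) {
  ga <- a$geometry; gb <- b$geometry
  abs(ga$gantry_deg - gb$gantry_deg) < tol &&
    abs(ga$sad_mm - gb$sad_mm) < tol && abs(ga$sid_mm - gb$sid_mm) < tol &&
    ga$det_rows == gb$det_rows && ga$det_cols == gb$det_cols &&
    abs(ga$det_pitch_mm - gb$det_pitch_mm) < tol &&
    max(abs(ga$isocenter - gb$isocenter)) < tol
}

# world coordinates of every voxel center, as an n x 3 matrix (i fastest)
voxel_centers <- function(dims, spacing, origin) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  cbind(rep(xs, times = dims[2] * dims[3]),
        rep(rep(ys, each = dims[1]), times = dims[3]),
        rep(zs, each = dims[1] * dims[2]))
}
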