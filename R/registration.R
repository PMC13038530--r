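# Bone-driven rigid alignment of non-essential tissues between the
# treatment-day and planning frames: automated 3D/3D registration by
# normalized cross-correlation over a coarse-to-fine pyramid, and
# orthogonal-pair 2D/2D registration with back-projection of the in-plane
# shifts to a 3D couch correction.

#' Result of a rigid registration
#'
#' The recovered transform maps the treatment frame onto the planning frame:
#' resampling the treatment volume by it aligns the non-essential tissues
#' with the planning CT.
#'
#' @param transform the recovered [rigid_transform()].
#' @param final_metric similarity (NCC) at the optimum.
#' @param iterations number of metric evaluations spent.
#' @param converged logical convergence flag; `FALSE` results still carry
#'   the best transform found.
#' @param mode `"3d3d"`, `"2d2d"` or `"oracle"`.
#' @return An object of class `registration_result`.
#' @export
registration_result <- function(transform, final_metric, iterations,
                                converged, mode) {
  structure(list(transform = transform, final_metric = final_metric,
                 iterations = as.integer(iterations),
                 converged = isTRUE(converged), mode = mode),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> mode %s, %s (metric %.4f, %d evaluations)\n",
              x$mode, if (x$converged) "converged" else "NOT converged",
              x$final_metric, x$iterations))
  print(x$transform)
  invisible(x)
}

#' Tidy a registration result
#' @param x a [registration_result()].
#' @param ... unused.
#' @return A tibble with one row per rigid parameter (term, estimate, unit).
#' @export
tidy.registration_result <- function(x, ...) {
  tibble::tibble(
    term = c("tx", "ty", "tz", "rx", "ry", "rz"),
    estimate = c(x$transform$t, x$transform$r),
    unit = rep(c("mm", "deg"), each = 3))
}

#' One-row summary of a registration result
#' @param x a [registration_result()].
#' @param ... unused.
#' @return A one-row tibble (mode, final_metric, iterations, converged).
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, final_metric = x$final_metric,
                 iterations = x$iterations, converged = x$converged)
}

#' Generic for broom-style tidying
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for broom-style one-row summaries
#' @param x object to summarise.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Emphasize high-contrast bony structures
#'
#' Soft-threshold transfer `max(HU - threshold, 0)`: only structures above
#' the threshold (vertebral bodies at the default 150 HU) drive a similarity
#' metric computed on the output.
#'
#' @param volume a [voxel_volume()].
#' @param threshold_hu soft threshold, HU (default 150).
#' @return A volume of the same class with non-negative values.
#' @export
bone_emphasis <- function(volume, threshold_hu = 150) {
  v <- pmax(volume$values - threshold_hu, 0)
  structure(list(values = v, spacing = volume$spacing, origin = volume$origin),
            class = class(volume))
}

# mean-pool a volume by an integer factor (cropping to full blocks);
# doubles as the smoothing step of the image pyramid
pool_volume <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol$values) %/% f * f
  v <- vol$values[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  out <- 0
  for (i in 0:(f - 1)) for (j in 0:(f - 1)) for (k in 0:(f - 1))
    out <- out + v[seq(1 + i, d[1], f), seq(1 + j, d[2], f), seq(1 + k, d[3], f),
                   drop = FALSE]
  structure(list(values = out / f^3, spacing = vol$spacing * f,
                 origin = vol$origin + (f - 1) / 2 * vol$spacing),
            class = class(vol))
}

weighted_centroid <- function(vol) {
  w <- vol$values
  s <- sum(w)
  if (s <= 0) return(c(0, 0, 0))
  d <- dim(w)
  vapply(1:3, function(ax) {
    m <- apply(w, ax, sum)
    x <- vol$origin[ax] + (seq_len(d[ax]) - 1) * vol$spacing[ax]
    sum(x * m) / s
  }, numeric(1))
}

default_reg3d_opts <- function() {
  list(threshold_hu = 150, levels = c(4L, 2L, 1L), dilate_vox = 2,
       ncc_floor = 0.2, max_eval = 4000L, trans_tol_mm = 0.05,
       rot_tol_deg = 0.02, trans_step_mm = 8, rot_step_deg = 2)
}

# derivative-free coordinate descent over the 6 rigid parameters, with
# repeated stepping in an improving direction and step halving on stall
coordinate_descent <- function(fn, par, steps, tol, max_eval, eval_count = 0L) {
  best <- fn(par)
  evals <- eval_count + 1L
  repeat {
    improved <- FALSE
    for (pi in 1:6) {
      for (sgn in c(1, -1)) {
        repeat {
          cand <- par
          cand[pi] <- cand[pi] + sgn * steps[pi]
          v <- fn(cand)
          evals <- evals + 1L
          if (v > best + 1e-12) {
            par <- cand; best <- v; improved <- TRUE
          } else break
          if (evals >= max_eval) break
        }
        if (evals >= max_eval) break
      }
      if (evals >= max_eval) break
    }
    if (evals >= max_eval) break
    if (!improved) {
      steps <- steps / 2
      if (all(steps < tol)) break
    }
  }
  list(par = par, value = best, evals = evals)
}

#' Automated rigid 3D/3D registration
#'
#' Maximizes normalized cross-correlation between bone-emphasized volumes
#' over the six rigid parameters, coarse-to-fine over a mean-pooled image
#' pyramid with a derivative-free coordinate search per level. Translation
#' is pre-initialized from the bone-weighted centroids. Deterministic given
#' inputs and options (no random restarts).
#'
#' @param moving the treatment-day [voxel_volume()].
#' @param fixed the planning [voxel_volume()].
#' @param opts named list overriding the defaults: `threshold_hu` (150),
#'   `levels` (pyramid factors 4, 2, 1), `dilate_vox` (2), `ncc_floor`
#'   (0.2), `max_eval` (4000), `trans_tol_mm`, `rot_tol_deg`,
#'   `trans_step_mm`, `rot_step_deg`.
#' @return A [registration_result()] whose transform maps the treatment
#'   frame onto the planning frame.
#' @export
register_3d <- function(moving, fixed, opts = list()) {
  o <- utils::modifyList(default_reg3d_opts(), opts)
  bm <- bone_emphasis(moving, o$threshold_hu)
  bf <- bone_emphasis(fixed, o$threshold_hu)
  par <- c(weighted_centroid(bf) - weighted_centroid(bm), 0, 0, 0)
  evals <- 0L
  value <- NA_real_
  for (f in o$levels) {
    pm <- pool_volume(bm, f)
    pf <- pool_volume(bf, f)
    dims <- as.integer(dim(pf$values))
    mask <- pf$values > 0
    if (!any(mask)) next
    if (o$dilate_vox > 0)
      mask <- array(cpp_morph(as.vector(mask), dims,
                              ball_offsets(o$dilate_vox), TRUE), dims)
    idx <- which(mask, arr.ind = TRUE)
    pts <- sweep((idx - 1) %*% diag(pf$spacing), 2, pf$origin, "+")
    fixedvals <- pf$values[mask]
    mvals <- as.vector(as.numeric(pm$values))
    mdims <- as.integer(dim(pm$values))
    fn <- function(p) {
      M <- transform_matrix(invert(rigid_transform(p[1:3], p[4:6])))[1:3, ,
                                                                     drop = FALSE]
      v <- cpp_ncc_points(mvals, mdims, pm$spacing, pm$origin, pts,
                          fixedvals, M)
      if (is.na(v)) -1 else v
    }
    lev <- coordinate_descent(
      fn, par,
      steps = c(rep(o$trans_step_mm * f / max(o$levels), 3),
                rep(o$rot_step_deg * f / max(o$levels), 3)),
      tol = c(rep(o$trans_tol_mm * f, 3), rep(o$rot_tol_deg * f, 3)),
      max_eval = o$max_eval, eval_count = evals)
    par <- lev$par
    value <- lev$value
    evals <- lev$evals
  }
  registration_result(rigid_transform(par[1:3], par[4:6]),
                      final_metric = value, iterations = evals,
                      converged = is.finite(value) && value >= o$ncc_floor,
                      mode = "3d3d")
}

# soft bone emphasis in the projection domain: keep what rises above the
# image median (bone-only projections are essentially unchanged)
emphasize_2d <- function(v) pmax(v - stats::median(v), 0)

# integer-pixel cross-correlation peak via FFT plus quadratic sub-pixel
# refinement; returns the shift (rows, cols) of `moving` relative to `fixed`
# and the normalized peak correlation
xcorr_shift_2d <- function(fixed, moving, max_shift_px = 64) {
  a <- fixed - mean(fixed)
  b <- moving - mean(moving)
  nr <- 2L * nrow(a); nc <- 2L * ncol(a)
  A <- matrix(0, nr, nc); B <- matrix(0, nr, nc)
  A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  B[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) /
    (as.numeric(nr) * nc)
  lag_r <- c(0:(nr / 2 - 1), -(nr / 2):-1)
  lag_c <- c(0:(nc / 2 - 1), -(nc / 2):-1)
  ok_r <- abs(lag_r) <= max_shift_px
  ok_c <- abs(lag_c) <= max_shift_px
  sub <- cc[ok_r, ok_c, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ir <- which(ok_r)[pk[1]]; ic <- which(ok_c)[pk[2]]
  quad <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- lag_r[ir] + quad(cc[wrap(ir - 1, nr), ic], cc[ir, ic], cc[wrap(ir + 1, nr), ic])
  dc <- lag_c[ic] + quad(cc[ir, wrap(ic - 1, nc)], cc[ir, ic], cc[ir, wrap(ic + 1, nc)])
  conf <- cc[ir, ic] / sqrt(sum(a^2) * sum(b^2))
  list(dr = dr, dc = dc, confidence = conf)
}

#' Orthogonal-pair 2D/2D registration
#'
#' Estimates, per view, the in-plane shift maximizing the cross-correlation
#' of bone-emphasized projections (sub-pixel via quadratic peak fit),
#' divides detector shifts by the magnification SID/SAD, and combines the
#' two per-view 2D shifts by least squares into a 3D couch translation
#' (rotations fixed at 0 — translation-only mode).
#'
#' @param moving_a,fixed_a treatment-day and planning [radiograph()]s of the
#'   first view (e.g. gantry 45 degrees); must share detector geometry.
#' @param moving_b,fixed_b the second, non-parallel view (e.g. 135 degrees).
#' @param opts named list: `emphasize` (median soft-threshold before
#'   correlating, default TRUE), `ncc_floor` (0.2), `max_shift_px` (64).
#' @return A [registration_result()] (mode `"2d2d"`) whose translation maps
#'   the treatment frame onto the planning frame.
#' @export
register_2d_pair <- function(moving_a, fixed_a, moving_b, fixed_b,
                             opts = list()) {
  o <- utils::modifyList(list(emphasize = TRUE, ncc_floor = 0.2,
                              max_shift_px = 64), opts)
  if (!same_detector_geometry(moving_a, fixed_a) ||
      !same_detector_geometry(moving_b, fixed_b))
    stop("moving and fixed radiographs must share detector geometry per view")
  dth <- (moving_a$geometry$gantry_deg - moving_b$geometry$gantry_deg) %% 180
  if (min(dth, 180 - dth) < 1e-6)
    stop("degenerate geometry: the two views are parallel")
  views <- list(list(m = moving_a, f = fixed_a), list(m = moving_b, f = fixed_b))
  rows <- NULL; rhs <- NULL; conf <- numeric(0)
  for (vw in views) {
    fv <- vw$f$values; mv <- vw$m$values
    if (o$emphasize) { fv <- emphasize_2d(fv); mv <- emphasize_2d(mv) }
    sh <- xcorr_shift_2d(fv, mv, o$max_shift_px)
    conf <- c(conf, sh$confidence)
    g <- geometry_vectors(vw$m$geometry)
    mag <- vw$m$geometry$sid_mm / vw$m$geometry$sad_mm
    du <- sh$dc * vw$m$pitch_mm / mag   # isocenter-scale, mm
    dv <- sh$dr * vw$m$pitch_mm / mag
    rows <- rbind(rows, g$uhat, g$vhat)
    rhs <- c(rhs, du, dv)
  }
  s <- as.vector(qr.solve(rows, rhs))   # setup displacement, treatment frame
  registration_result(rigid_transform(t = -s),
                      final_metric = min(conf),
                      iterations = 2L,
                      converged = all(conf >= o$ncc_floor),
                      mode = "2d2d")
}

#' Align non-essential tissues of a treatment-day volume
#'
#' Runs the selected registration (3D/3D on the volumes; 2D/2D on
#' bone-emphasized DRRs generated internally at the orthogonal 45/135-degree
#' views), then rigidly resamples the treatment volume by the recovered
#' transform onto the planning grid ("the normal axes").
#'
#' @param planning the planning [voxel_volume()].
#' @param treatment the treatment-day [voxel_volume()].
#' @param mode `"3d3d"` or `"2d2d"`.
#' @param opts registration options (see [register_3d()] /
#'   [register_2d_pair()]); for 2D/2D, `geom` may carry the base
#'   [projection_geometry()] and `mu_water_per_mm` the attenuation scale.
#' @return A list with elements `volume` (the aligned treatment volume) and
#'   `registration` (the [registration_result()]).
#' @export
align_ne <- function(planning, treatment, mode = c("3d3d", "2d2d"),
                     opts = list()) {
  mode <- match.arg(mode)
  if (mode == "3d3d") {
    reg <- register_3d(treatment, planning, opts)
  } else {
    base_geom <- if (!is.null(opts$geom)) opts$geom else projection_geometry()
    thr <- if (!is.null(opts$threshold_hu)) opts$threshold_hu else 150
    muw <- if (!is.null(opts$mu_water_per_mm)) opts$mu_water_per_mm else 0.019
    bone_att <- function(vol) {
      b <- bone_emphasis(vol, thr)
      attenuation_volume(b$values * muw / 1000, b$spacing, b$origin)
    }
    att_f <- bone_att(planning)
    att_m <- bone_att(treatment)
    geoms <- lapply(orthogonal_angles(), function(a) {
      g <- base_geom; g$gantry_deg <- a; g
    })
    reg <- register_2d_pair(project(att_m, geoms[[1]]),
                            project(att_f, geoms[[1]]),
                            project(att_m, geoms[[2]]),
                            project(att_f, geoms[[2]]),
                            opts)
  }
  if (!reg$converged)
    warning("registration did not converge; returning best transform found")
  list(volume = resample_rigid(treatment, reg$transform), registration = reg)
}
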