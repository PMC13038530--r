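# The core subtraction method: build the planning CT of non-essential (NE)
# tissues, simulate its projections, and subtract them from treatment-day
# projections to obtain radiographs in which only the thoracic-cavity
# contents (lung and tumor) remain.

#' Planning CT of non-essential tissues
#'
#' Overrides every thoracic-cavity voxel to -1024 HU (the lowest CT number
#' of a 12-bit scanner, which the attenuation ramp maps to 0), so that only
#' tissues outside the cavity — the non-essential tissues for lung imaging —
#' remain. Pure composition over [override_region()]; bit-reproducible.
#'
#' @param planning the planning [voxel_volume()].
#' @param cavity binary cavity [label_mask()] on the same grid.
#' @return A [voxel_volume()].
#' @export
ne_planning_ct <- function(planning, cavity) {
  override_region(planning, cavity, -1024)
}

#' Cavity-contents-only CT
#'
#' The complement of [ne_planning_ct()]: every voxel outside the cavity is
#' overridden to -1024 HU, leaving only the lung and tumor signal. Its
#' projection is the ideal, perfectly NE-free radiograph that subtraction
#' aims to reproduce.
#'
#' @param volume a [voxel_volume()] (planning or aligned treatment-day).
#' @param cavity binary cavity [label_mask()] on the same grid.
#' @return A [voxel_volume()].
#' @export
cavity_contents_ct <- function(volume, cavity) {
  override_region(volume, invert_mask(cavity), -1024)
}

#' Subtract an NE radiograph from a treatment-day radiograph
#'
#' Pixelwise `treatment - ne`. In the line-integral domain the signals are
#' additive, so the result is exactly the cavity-contents projection when
#' alignment is perfect; negative values are retained because they flag
#' misalignment. The result records its provenance, including whether the
#' input domain is additive.
#'
#' @param treatment_rad treatment-day [radiograph()].
#' @param ne_rad NE-tissue [radiograph()] with identical geometry and
#'   domain.
#' @return An object of class `pibs_image` (a difference image with the
#'   geometry of its inputs plus a `provenance` list).
#' @export
subtract_radiograph <- function(treatment_rad, ne_rad) {
  if (!same_detector_geometry(treatment_rad, ne_rad))
    stop("treatment and NE radiographs must share projection geometry")
  if (!identical(treatment_rad$domain, ne_rad$domain))
    stop("treatment and NE radiographs must share the same value domain")
  structure(list(values = treatment_rad$values - ne_rad$values,
                 domain = treatment_rad$domain,
                 pitch_mm = treatment_rad$pitch_mm,
                 geometry = treatment_rad$geometry,
                 provenance = list(
                   domain = treatment_rad$domain,
                   additive = treatment_rad$domain == "line_integral",
                   gantry_deg = treatment_rad$geometry$gantry_deg)),
            class = c("pibs_image", "radiograph"))
}

#' @export
print.pibs_image <- function(x, ...) {
  cat(sprintf("<pibs_image> %dx%d px, %s domain (%s), gantry %.1f deg, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$domain,
              if (x$provenance$additive) "additive" else "non-additive",
              x$geometry$gantry_deg, min(x$values), max(x$values)))
  invisible(x)
}

#' Run the full subtraction-imaging workflow
#'
#' Executes the complete pipeline on a synthetic study: cavity segmentation
#' from the planning labels, NE planning CT, registration of one treatment
#' state to the planning CT (the recovered transform is applied to all
#' states, matching clinical couch correction), rigid resampling of every
#' state, projection of the NE CT and each aligned state at each angle, and
#' subtraction. The conventional radiograph of each state/angle is the
#' aligned-state projection in the same domain.
#'
#' In `"oracle"` mode the inverse of the study's true setup error replaces
#' the estimated registration; on a noise-free study the aligned states are
#' then regenerated analytically, so subtraction correctness can be tested
#' independently of registration and interpolation error.
#'
#' @param study a [study_bundle()][make_study()].
#' @param angles_deg gantry angles (default the standard 12-angle sweep).
#' @param mode `"3d3d"`, `"2d2d"` or `"oracle"`.
#' @param domain subtraction domain: `"line_integral"` (additive; default)
#'   or `"display"` (absolute exponential mapping `1 - exp(-L)` before
#'   subtracting, emulating subtraction of viewer-mapped images).
#' @param geom base [projection_geometry()] shared by all views.
#' @param opts options forwarded to registration, plus `mu_water_per_mm`,
#'   `reg_state` (state used for registration, default 1) and
#'   `per_state_registration` (default FALSE: one transform reused for all
#'   states).
#' @return An object of class `pibs_run`: list with `conventional` and
#'   `pibs` (lists indexed \[\[state\]\]\[\[angle\]\]), `registration`,
#'   `aligned` (volumes), `ne_ct`, `cavity`, `angles_deg`, `domain`,
#'   `geometry`, `study`.
#' @export
run_pipeline <- function(study, angles_deg = standard_angles(),
                         mode = c("3d3d", "2d2d", "oracle"),
                         domain = c("line_integral", "display"),
                         geom = projection_geometry(), opts = list()) {
  mode <- match.arg(mode)
  domain <- match.arg(domain)
  muw <- if (!is.null(opts$mu_water_per_mm)) opts$mu_water_per_mm else 0.019
  reg_state <- if (!is.null(opts$reg_state)) opts$reg_state else 1L
  per_state <- isTRUE(opts$per_state_registration)
  nstate <- length(study$treatment)

  cavity <- segment_cavity(study$planning, study$labels)
  ne_ct <- ne_planning_ct(study$planning, cavity)

  regs <- vector("list", nstate)
  aligned <- vector("list", nstate)
  if (mode == "oracle") {
    tr <- invert(study$true_setup)
    reg <- registration_result(tr, final_metric = 1, iterations = 0L,
                               converged = TRUE, mode = "oracle")
    for (k in seq_len(nstate)) {
      regs[[k]] <- reg
      aligned[[k]] <- if (study$noise_sd == 0) {
        # analytic regeneration: no interpolation blur in oracle mode
        make_treatment_volume(study$spec, rigid_transform(),
                              study$true_tumor_shift_mm[k],
                              dim(study$planning$values),
                              study$planning$spacing)
      } else resample_rigid(study$treatment[[k]], tr)
    }
  } else {
    states <- if (per_state) seq_len(nstate) else reg_state
    for (k in states) {
      a <- align_ne(study$planning, study$treatment[[k]],
                    mode = mode, opts = c(opts, list(geom = geom)))
      regs[[k]] <- a$registration
      aligned[[k]] <- a$volume
    }
    if (!per_state) {
      # the transformation obtained on one state is applied to all states
      for (k in setdiff(seq_len(nstate), reg_state)) {
        regs[[k]] <- regs[[reg_state]]
        aligned[[k]] <- resample_rigid(study$treatment[[k]],
                                       regs[[reg_state]]$transform)
      }
    }
  }

  map_domain <- function(rad)
    if (domain == "display") to_display(rad, rescale = FALSE) else rad
  ne_rads <- lapply(sweep_projections(hu_to_mu(ne_ct, muw), geom, angles_deg),
                    map_domain)
  conventional <- vector("list", nstate)
  pibs <- vector("list", nstate)
  for (k in seq_len(nstate)) {
    conv_k <- lapply(sweep_projections(hu_to_mu(aligned[[k]], muw), geom,
                                       angles_deg), map_domain)
    pibs_k <- lapply(seq_along(angles_deg), function(a)
      subtract_radiograph(conv_k[[a]], ne_rads[[a]]))
    names(pibs_k) <- names(conv_k)
    conventional[[k]] <- conv_k
    pibs[[k]] <- pibs_k
  }
  structure(list(conventional = conventional, pibs = pibs,
                 registration = regs, aligned = aligned, ne_ct = ne_ct,
                 ne_radiographs = ne_rads, cavity = cavity,
                 angles_deg = angles_deg, domain = domain, geometry = geom,
                 mode = mode, study = study),
            class = "pibs_run")
}

#' @export
print.pibs_run <- function(x, ...) {
  cat(sprintf("<pibs_run> %d state(s) x %d angle(s), %s domain, alignment mode %s\n",
              length(x$pibs), length(x$angles_deg), x$domain, x$mode))
  reg <- x$registration[[1]]
  cat(sprintf("  registration: %s, metric %.4f\n",
              if (reg$converged) "converged" else "NOT converged",
              reg$final_metric))
  invisible(x)
}
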