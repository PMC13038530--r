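# Run configuration: one human-readable file (YAML or JSON) with strict
# schema validation; every field has a documented default that reproduces
# the desk-scale demonstration study.

#' Default run configuration
#'
#' Returns the fully expanded configuration of the desk-scale demonstration
#' study: the default phantom, setup error (8, -5, 12) mm / (1, -1, 2) deg,
#' superior tumor shifts (0, 10, 20) mm, a 160 x 128 x 120 grid at 2.5 mm,
#' and a 256 x 256 detector at 1.668 mm pitch (an exact 4x binning of a
#' 1024^2 detector at 0.417 mm) with 100 cm SAD / 150 cm SID.
#'
#' @return A nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(
      body_semiaxes_mm = c(150, 95), body_z_mm = c(-140, 140), body_hu = 0,
      lung_centers_mm = list(c(70, -10), c(-70, -10)),
      lung_semiaxes_mm = c(50, 65), lung_z_mm = c(-120, 120), lung_hu = -700,
      tumor_center_mm = c(-50, -27, -40), tumor_radius_mm = 15, tumor_hu = 20,
      vert_center_xy_mm = c(0, 60), vert_radius_mm = 12, vert_height_mm = 20,
      vert_spacing_mm = 25, vert_hu = 600, process_radius_mm = 6,
      process_offset_mm = c(20, 10), sternum_center_xy_mm = c(0, -78),
      sternum_radius_mm = 8, background_hu = -1024),
    study = list(
      setup_t_mm = c(8, -5, 12), setup_r_deg = c(1, -1, 2),
      tumor_shifts_mm = c(0, 10, 20), seed = 1L, noise_sd_hu = 0),
    grid = list(shape = c(160L, 128L, 120L), spacing_mm = 2.5),
    geometry = list(
      sad_mm = 1000, sid_mm = 1500, det_rows = 256L, det_cols = 256L,
      det_pitch_mm = 1.668, angles_deg = seq(0, 165, by = 15)),
    registration = list(mode = "3d3d", threshold_hu = 150, ncc_floor = 0.2),
    subtraction = list(domain = "line_integral"),
    evaluation = list(track_angle_deg = 150),
    mu_water_per_mm = 0.019,
    output_dir = "pibs_output"), class = "run_config")
}

# strict recursive merge: every key in `user` must exist in `defaults`
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]], paste0(path, ".", nm))
    else user[[nm]]
  }
  defaults
}

#' Build a run configuration
#'
#' Starts from [default_run_config()] and overrides the given keys, which
#' must all exist in the schema (unknown keys are rejected for typo
#' safety).
#'
#' @param ... named top-level sections (e.g. `study = list(seed = 7)`).
#' @return A `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  structure(merge_config(default_run_config(), over), class = "run_config")
}

#' Read a run configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), validated against the schema:
#' unknown keys are rejected, missing keys take their documented defaults.
#'
#' @param path configuration file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  low <- tolower(path)
  user <- if (grepl("\\.ya?ml$", low)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", low)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported configuration format: ", basename(path))
  structure(merge_config(default_run_config(), user), class = "run_config")
}

#' Write a resolved configuration (defaults expanded) to JSON
#' @param config a `run_config`.
#' @param path output path (.json).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Materialize configuration sections as package objects
#'
#' @param config a `run_config`.
#' @return `config_phantom_spec`: a [phantom_spec()]; `config_geometry`: a
#'   [projection_geometry()] at gantry 0; `config_study`: a fully built
#'   [make_study()] bundle.
#' @export
config_phantom_spec <- function(config) {
  p <- config$phantom
  p$lung_centers_mm <- lapply(seq_len(length(p$lung_centers_mm)), function(i)
    as.numeric(unlist(p$lung_centers_mm[[i]])))
  do.call(phantom_spec, p)
}

#' @rdname config_phantom_spec
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  projection_geometry(0, g$sad_mm, g$sid_mm, g$det_rows, g$det_cols,
                      g$det_pitch_mm)
}

#' @rdname config_phantom_spec
#' @export
config_study <- function(config) {
  s <- config$study
  make_study(config_phantom_spec(config),
             setup = rigid_transform(t = as.numeric(s$setup_t_mm),
                                     r = as.numeric(s$setup_r_deg)),
             tumor_shifts_mm = as.numeric(s$tumor_shifts_mm),
             shape = as.integer(config$grid$shape),
             spacing = as.numeric(config$grid$spacing_mm),
             seed = as.integer(s$seed), noise_sd = s$noise_sd_hu)
}
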