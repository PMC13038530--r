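test_that("perspective point projection matches closed-form geometry", {
  g <- projection_geometry(gantry_deg = 0)
  # isocenter projects to the detector center
  expect_equal(unname(project_point(g, c(0, 0, 0))), c(0, 0))
  # 10 mm superior moves v by 10 * SID/SAD toward the image top
  expect_equal(project_point(g, c(0, 0, 10))[["v"]], -15)
  # points on the rotation axis project to the same (u, v) at any angle
  for (ang in c(30, 120, 150)) {
    ga <- projection_geometry(gantry_deg = ang)
    expect_equal(unname(project_point(ga, c(0, 0, 30))), c(0, -45),
                 tolerance = 1e-9)
  }
  # off-axis points: u depends on the view, v only weakly (depth change)
  p <- c(-50, -27, -40)
  u30 <- project_point(projection_geometry(gantry_deg = 30), p)
  u120 <- project_point(projection_geometry(gantry_deg = 120), p)
  expect_gt(abs(u30[["u"]] - u120[["u"]]), 10)
  expect_lt(abs(u30[["v"]] - u120[["v"]]) / abs(u30[["v"]]), 0.1)
})

test_that("tumor ground-truth projection scales with magnification", {
  spec <- phantom_spec(body_semiaxes_mm = c(100, 80),
                       body_z_mm = c(-100, 100),
                       lung_centers_mm = list(c(0, 0)),
                       lung_semiaxes_mm = c(60, 60), lung_z_mm = c(-80, 80),
                       tumor_center_mm = c(0, 0, 0), tumor_radius_mm = 10,
                       vert_radius_mm = 0, process_radius_mm = 0,
                       sternum_radius_mm = 0)
  study <- make_study(spec, setup = rigid_transform(),
                      tumor_shifts_mm = c(0, 10),
                      shape = c(64L, 64L, 64L), spacing = 4)
  g <- projection_geometry()
  t1 <- project_tumor_truth(study, g, 1L)
  expect_equal(unname(t1$uv), c(0, 0))
  expect_equal(t1$radius_mm, 10 * 1.5)
  t2 <- project_tumor_truth(study, g, 2L)
  expect_equal(t2$uv[["v"]] - t1$uv[["v"]], -10 * 1.5)
})

test_that("cnr is the standard ROI statistic with sane edge cases", {
  g <- projection_geometry(det_rows = 40, det_cols = 40, det_pitch_mm = 1)
  v <- matrix(0.5, 40, 40)
  v[1:10, 1:10] <- 0.8
  tumor <- matrix(FALSE, 40, 40); tumor[1:10, 1:10] <- TRUE
  bg <- matrix(FALSE, 40, 40); bg[21:40, ] <- TRUE
  set.seed(2)
  v[bg] <- rnorm(sum(bg), 0.5, 0.1)
  img <- radiograph(pmax(v, 0), "line_integral", g)
  expect_equal(cnr(img, tumor, bg),
               abs(mean(img$values[tumor]) - mean(img$values[bg])) /
                 sd(img$values[bg]))
  # identical ROI statistics give exactly zero
  veq <- matrix(0.5, 40, 40)
  veq[tumor] <- rep(c(0.4, 0.6), length.out = sum(tumor))
  veq[bg] <- rep(c(0.4, 0.6), length.out = sum(bg))
  eq <- radiograph(veq, "line_integral", g)
  expect_equal(cnr(eq, tumor, bg), 0)
  # zero background SD is flagged undefined, not infinite
  const <- radiograph(matrix(0.5, 40, 40), "line_integral", g)
  out <- cnr(const, tumor, bg)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  # overlap is rejected
  expect_error(cnr(img, tumor, tumor), "overlap")
})

test_that("cnr converges to delta/sigma on a synthetic disc", {
  g <- projection_geometry(det_rows = 80, det_cols = 80, det_pitch_mm = 1)
  set.seed(11)
  sigma <- 0.05; delta <- 0.2
  v <- matrix(rnorm(6400, 1, sigma), 80)
  rows <- row(v); cols <- col(v)
  d <- sqrt((rows - 40)^2 + (cols - 40)^2)
  disc <- d <= 10
  v[disc] <- v[disc] + delta
  img <- radiograph(pmax(v, 0), "line_integral", g)
  bg <- d >= 15 & d <= 25
  expect_gt(sum(bg), 1e3)
  expect_lt(abs(cnr(img, disc, bg) / (delta / sigma) - 1), 0.1)
})

test_that("template matching finds a synthetic disc to sub-pixel accuracy", {
  g <- projection_geometry(det_rows = 96, det_cols = 96, det_pitch_mm = 1)
  tpl <- pibsim:::sphere_template(8)
  v <- matrix(0, 96, 96)
  v[40:56, 60:76] <- tpl  # disc centered at (48, 68)
  img <- radiograph(v, "line_integral", g)
  loc <- locate_tumor(img, 8, search_center = c(50, 65), search_half_px = 15)
  expect_lt(abs(loc$rowcol[["row"]] - 48), 0.25)
  expect_lt(abs(loc$rowcol[["col"]] - 68), 0.25)
  expect_false(loc$low_confidence)
  # a flat image has nothing to find
  flat <- radiograph(matrix(1, 96, 96), "line_integral", g)
  expect_true(locate_tumor(flat, 8)$low_confidence)
  expect_error(locate_tumor(img, 1), "at least 2")
})

test_that("motion tracking recovers the injected SI shifts on PIBS images", {
  run <- oracle_run()
  study <- default_study()
  ti <- which(run$angles_deg == 150)
  g <- run$geometry
  g$gantry_deg <- 150
  trace <- track_motion(lapply(1:3, function(k) run$pibs[[k]][[ti]]), g, study)
  expect_s3_class(trace, "motion_trace")
  expect_equal(trace$truth_mm, c(0, 10, 20))
  expect_lt(max(abs(trace$error_mm)), 1)
  expect_false(any(trace$low_confidence))

  # single-state series reports zero displacement
  single <- track_motion(list(run$pibs[[1]][[ti]]), g, study)
  expect_equal(single$displacement_mm, 0)

  # conventional images at 150 deg: the tumor is masked by vertebral
  # bodies and at least one state is flagged low-confidence
  conv <- track_motion(lapply(1:3, function(k) run$conventional[[k]][[ti]]),
                       g, study)
  expect_true(any(conv$low_confidence))
})

test_that("PIBS localization is at least as accurate as conventional at every angle", {
  run <- oracle_run()
  study <- default_study()
  quarter_px <- 0.25 * run$geometry$det_pitch_mm
  for (ai in seq_along(run$angles_deg)) {
    g <- run$geometry
    g$gantry_deg <- run$angles_deg[ai]
    tr <- project_tumor_truth(study, g, 1)
    ep <- sqrt(sum((locate_tumor(run$pibs[[1]][[ai]], tr$radius_px,
                                 tr$rowcol)$uv - tr$uv)^2))
    ec <- sqrt(sum((locate_tumor(run$conventional[[1]][[ai]], tr$radius_px,
                                 tr$rowcol)$uv - tr$uv)^2))
    expect_lte(ep, ec + quarter_px)
  }
})

test_that("the evaluation report aggregates all angles, states and kinds", {
  run <- oracle_run()
  rep <- evaluation_report(run)
  expect_equal(nrow(rep$contrast), 12 * 3 * 2)
  expect_setequal(unique(rep$contrast$kind), c("conventional", "pibs"))
  expect_equal(nrow(rep$cnr_ratio), 12)
  expect_true(all(rep$cnr_ratio$cnr_pibs > 0))
  expect_equal(nrow(rep$motion), 3)
  expect_equal(rep$registration$error, rep(0, 6))  # oracle alignment

  # PIBS dominates at the angle the tumor is masked by vertebral bodies
  at150 <- rep$cnr_ratio[rep$cnr_ratio$angle_deg == 150, ]
  expect_gt(at150$ratio, 1)

  # serialization round trip
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "contrast.csv")))
  back <- read_report(dir)
  expect_equal(as.data.frame(back$cnr_ratio), as.data.frame(rep$cnr_ratio),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$motion)$displacement_mm,
               rep$motion$displacement_mm, tolerance = 1e-12)
})
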