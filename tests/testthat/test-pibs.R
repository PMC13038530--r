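test_that("NE planning CT overrides exactly the cavity", {
  study <- default_study()
  cav <- segment_cavity(study$planning, study$labels)
  ne <- ne_planning_ct(study$planning, cav)
  inside <- cav$values != 0L
  expect_true(all(ne$values[inside] == -1024))
  expect_identical(ne$values[!inside], study$planning$values[!inside])

  # empty cavity: output equals input; reproducible
  empty <- label_mask(array(0L, dim(study$planning$values)),
                      study$planning$spacing, study$planning$origin)
  expect_identical(ne_planning_ct(study$planning, empty)$values,
                   study$planning$values)
  expect_identical(ne$values, ne_planning_ct(study$planning, cav)$values)

  # cavity-contents volume is the exact complement
  contents <- cavity_contents_ct(study$planning, cav)
  expect_true(all(contents$values[!inside] == -1024))
  expect_identical(contents$values[inside], study$planning$values[inside])
})

test_that("subtraction is exact in the line-integral domain", {
  study <- default_study()
  cav <- segment_cavity(study$planning, study$labels)
  ne <- ne_planning_ct(study$planning, cav)
  contents <- cavity_contents_ct(study$planning, cav)
  g <- projection_geometry(gantry_deg = 45)

  full <- project(hu_to_mu(study$planning), g)
  ne_rad <- project(hu_to_mu(ne), g)
  pibs <- subtract_radiograph(full, ne_rad)

  # self-subtraction
  zero <- subtract_radiograph(full, full)
  expect_true(all(zero$values == 0))

  # linearity of line integrals: PIBS equals the cavity-contents projection
  ref <- project(hu_to_mu(contents), g)
  expect_lt(max(abs(pibs$values - ref$values)) / max(ref$values), 1e-6)
  expect_true(pibs$provenance$additive)

  # domain bookkeeping: display-domain subtraction is flagged non-additive
  d <- subtract_radiograph(to_display(full, rescale = FALSE),
                           to_display(ne_rad, rescale = FALSE))
  expect_false(d$provenance$additive)

  # mismatches are rejected
  g2 <- projection_geometry(gantry_deg = 90)
  expect_error(subtract_radiograph(full, project(hu_to_mu(ne), g2)),
               "geometry")
  expect_error(subtract_radiograph(full, to_display(ne_rad)), "domain")
})

test_that("the pipeline emits the expected image sets and reuses one transform", {
  run <- oracle_run()
  expect_length(run$pibs, 3L)
  expect_length(run$conventional, 3L)
  for (k in 1:3) {
    expect_length(run$pibs[[k]], 12L)
    expect_length(run$conventional[[k]], 12L)
  }
  # one registration result shared across the three states
  expect_identical(run$registration[[1]], run$registration[[2]])
  expect_identical(run$registration[[1]], run$registration[[3]])

  # orthogonal two-view variant
  study <- default_study()
  orth <- run_pipeline(study, angles_deg = orthogonal_angles(),
                       mode = "oracle")
  expect_length(orth$pibs[[1]], 2L)
  expect_equal(orth$pibs[[1]][[2]]$geometry$gantry_deg, 135)
})

test_that("oracle-aligned PIBS equals the cavity-contents projection everywhere", {
  run <- oracle_run()
  worst <- 0
  for (k in 1:3) {
    contents <- cavity_contents_ct(run$aligned[[k]], run$cavity)
    att <- hu_to_mu(contents)
    for (ai in seq_along(run$angles_deg)) {
      g <- run$geometry
      g$gantry_deg <- run$angles_deg[ai]
      ref <- project(att, g)
      worst <- max(worst,
                   max(abs(run$pibs[[k]][[ai]]$values - ref$values)) /
                     max(ref$values))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("estimated alignment keeps the residual background in check", {
  study <- default_study()
  run <- run_pipeline(study, angles_deg = c(45, 150), mode = "3d3d")
  expect_true(run$registration[[1]]$converged)
  for (ai in 1:2) {
    g <- run$geometry
    g$gantry_deg <- run$angles_deg[ai]
    cavproj <- project(hu_to_mu(cavity_contents_ct(run$aligned[[1]],
                                                   run$cavity)), g)$values
    p <- run$pibs[[1]][[ai]]$values
    outside <- cavproj < 1e-6
    tr <- project_tumor_truth(study, g, 1)
    rois <- cnr_rois(g, tr)
    tumor_peak <- max(p[rois$tumor])
    # median background well below the tumor signal; boundary interpolation
    # residuals dominate the upper tail (see the methods vignette)
    expect_lt(median(abs(p[outside])), 0.1 * tumor_peak)
    expect_lt(quantile(abs(p[outside]), 0.99), tumor_peak)
  }
})

test_that("display-domain subtraction reproduces the viewer-mapped operating mode", {
  study <- default_study()
  run <- run_pipeline(study, angles_deg = 150, mode = "oracle",
                      domain = "display")
  expect_equal(run$domain, "display")
  expect_equal(run$pibs[[1]][[1]]$domain, "display")
  expect_false(run$pibs[[1]][[1]]$provenance$additive)
  # display values live in [0, 1): differences bounded by 1
  expect_lt(max(abs(run$pibs[[1]][[1]]$values)), 1)
})
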