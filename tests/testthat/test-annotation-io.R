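# Annotation bundle I/O: sidecar round trips, label-image vectorisation,
# validation errors, measurement tables.

test_that("polyline sidecar round trip preserves coordinates and calibration", {
  wa <- rbind(c(0, 0), c(0.2, 1.5), c(0.1, 3))
  wb <- rbind(c(1, 0), c(0.9, 1.5), c(1.2, 3))
  sec <- annotated_section("s1", 2.0, wa, wb, c(0.5, -0.3), group = "RPM")
  path <- file.path(tempdir(), "s1.json")
  write_annotation(sec, path)
  back <- load_annotation(path)
  expect_equal(back$specimen_id, "s1")
  expect_equal(back$group, "RPM")
  expect_identical(back$calibration$microns_per_pixel, 2.0)
  expect_lt(max(abs(back$wall_a - sec$wall_a)), 1e-6)
  expect_lt(max(abs(back$wall_b - sec$wall_b)), 1e-6)
  expect_equal(back$file_tip, sec$file_tip, tolerance = 1e-9)
})

test_that("invalid annotations are rejected with typed errors", {
  wa <- rbind(c(0, 0), c(0, 2))
  wb <- rbind(c(1, 0), c(1, 2))
  expect_error(scale_calibration(-1), class = "apexmetry_calibration_error")
  expect_error(scale_calibration(Inf), class = "apexmetry_calibration_error")
  expect_error(annotated_section("x", 2, rbind(c(0, 0)), wb, c(0.5, 1)),
               class = "apexmetry_geometry_error")
  expect_error(annotated_section("x", 2, wa, wb, c(NA, 1)),
               class = "apexmetry_validation_error")
  expect_error(annotated_section("x", 2, wa, wb, c(0.5, 1), group = "XXX"),
               class = "apexmetry_validation_error")
  # walls crossing each other
  expect_error(
    annotated_section("x", 2, rbind(c(0, 0), c(1, 2)), rbind(c(1, 0), c(0, 2)),
                      c(0.5, 1)),
    class = "apexmetry_geometry_error")
  # self-intersecting wall
  expect_error(
    annotated_section("x", 2, rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)),
                      rbind(c(5, 0), c(5, 2)), c(3, 1)),
    class = "apexmetry_geometry_error")
})

test_that("sidecar without calibration raises a calibration error", {
  path <- file.path(tempdir(), "nocal.json")
  jsonlite::write_json(list(specimen_id = "x", polylines = list(
    wall_a = rbind(c(0, 0), c(0, 2)), wall_b = rbind(c(1, 0), c(1, 2)),
    tip = c(0.5, 1))), path, auto_unbox = TRUE)
  expect_error(load_annotation(path), class = "apexmetry_calibration_error")
  jsonlite::write_json(list(specimen_id = "x", microns_per_pixel = 2),
                       file.path(tempdir(), "nogeo.json"), auto_unbox = TRUE)
  expect_error(load_annotation(file.path(tempdir(), "nogeo.json")),
               class = "apexmetry_validation_error")
})

test_that("wall ordering is normalised apical-first, with override", {
  # narrow end (apical) placed LAST in the input: auto mode must flip both
  wa <- rbind(c(0, 0), c(0.4, 2))
  wb <- rbind(c(1, 0), c(0.6, 2))
  expect_message(
    sec <- annotated_section("x", 2, wa, wb, c(0.5, 1)),
    "normalised to apical-first")
  expect_equal(sec$wall_a[1, ], c(0.4, 2))
  expect_equal(sec$wall_b[1, ], c(0.6, 2))
  # explicit override keeps the stated orientation
  sec2 <- annotated_section("x", 2, wa, wb, c(0.5, 1), apical_end = "first")
  expect_equal(sec2$wall_a[1, ], c(0, 0))
  # reversed wall_b vertex order is re-aligned to wall_a
  sec3 <- annotated_section("x", 2, wa, wb[2:1, ], c(0.5, 1),
                            apical_end = "first")
  expect_equal(sec3$wall_b[1, ], c(1, 0))
})

test_that("rendered label image vectorises back to the true walls within 1 px", {
  g <- make_apex_geometry(apex_params(contour_jitter_sigma = 0))
  out <- render_annotation(g, file.path(tempdir(), "vec"), "v1")
  sec <- load_quietly(out$sidecar)
  truth <- jsonlite::read_json(out$truth, simplifyVector = TRUE)
  k <- mm_per_pixel(sec$calibration)
  origin <- truth$transform$origin_mm
  for (w in c("wall_a", "wall_b")) {
    got_mm <- sec[[w]] * k
    true_mm <- sweep(truth[[paste0(w, "_mm")]], 2, origin)  # into image frame
    d <- apexmetry:::project_onto_polyline(got_mm, true_mm)$dist
    expect_lt(max(d), 1 * k)
  }
  tip_true <- truth$tip_mm - origin
  expect_lt(sqrt(sum((sec$file_tip * k - tip_true)^2)), 1.5 * k)
})

test_that("measurement tables round-trip and keep a stable order", {
  path <- file.path(tempdir(), "meas.csv")
  save_measurements(list(), path)
  empty <- read_measurements(path)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), apexmetry:::MEASUREMENT_COLUMNS)

  rec <- data.frame(specimen_id = "a1", group = "EPA", d_ac_mm = 0.271234,
                    d_af_mm = 0.64, dist_tip_ac_mm = -0.041,
                    dist_tip_af_mm = 0.301, position_class = "BETWEEN_AC_AF",
                    ac_af_dist_mm = 0.36)
  save_measurements(rec, path)
  back <- read_measurements(path)
  expect_equal(back$d_ac_mm, 0.271234, tolerance = 1e-6)
  expect_equal(back$position_class, "BETWEEN_AC_AF")

  n <- 120
  big <- do.call(rbind, lapply(sample(n), function(i) {
    r <- rec; r$specimen_id <- sprintf("sp_%03d", i); r
  }))
  save_measurements(big, path)
  back <- read_measurements(path)
  expect_equal(nrow(back), n)
  expect_equal(back$specimen_id, sort(big$specimen_id))
  expect_error(save_measurements(rec, file.path(tempdir(), "no/such/dir/x.csv")),
               class = "apexmetry_io_error")
  expect_error(save_measurements(rec[, 1:3], path),
               class = "apexmetry_validation_error")
})
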