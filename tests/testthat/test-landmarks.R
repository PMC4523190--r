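# Landmark detection: foramen chord, constriction search, AC-AF separation.

test_that("the foramen chord joins the terminal wall endpoints", {
  wa <- rbind(c(0, 0), c(0.05, 1), c(0, 2))
  wb <- rbind(c(0.64, 0), c(0.59, 1), c(0.64, 2))
  sec <- mm_section(wa, wb, c(0.3, 0.5), apical_end = "first")
  prof <- compute_width_profile(sec, build_medial_path(sec, step = 0.05))
  af <- detect_af(sec, prof)
  expect_equal(af$diameter, 0.64, tolerance = 1e-12)
  expect_identical(af$s, 0)
  expect_equal(af$midpoint, c(0.32, 0), tolerance = 1e-12)
})

test_that("coincident terminal endpoints raise a geometry error", {
  wa <- rbind(c(0, 0), c(-0.3, 2))
  wb <- rbind(c(0, 0), c(0.3, 2))
  sec <- mm_section(wa, wb, c(0, 1), apical_end = "first")
  path <- suppressWarnings(build_medial_path(sec, step = 0.05))
  prof <- suppressWarnings(compute_width_profile(sec, path))
  expect_error(detect_af(sec, prof), class = "apexmetry_geometry_error")
})

test_that("constriction detection recovers generator truth on exact polylines", {
  for (curv in c(0, 0.1)) {
    g <- make_apex_geometry(apex_params(curvature = curv,
                                        contour_jitter_sigma = 0))
    sec <- geometry_as_section(g)
    m <- measure_quietly(sec)
    tol <- 2 * mm_per_pixel(sec$calibration)
    expect_lt(abs(m$ac$diameter - g$ac_diameter), tol)
    expect_lt(abs(m$af$diameter - g$af_diameter), tol)
    expect_lt(abs(m$ac$s - 0.36), 2 * 0.01)
    expect_lt(abs(m$ac_af_dist - g$ac_af_perp), tol)
  }
})

test_that("a monotone taper yields a no-distinct-constriction warning", {
  wa <- rbind(c(-0.1, 0), c(-0.5, 4))
  wb <- rbind(c(0.1, 0), c(0.5, 4))
  sec <- mm_section(wa, wb, c(0, 1), apical_end = "first")
  prof <- compute_width_profile(sec, build_medial_path(sec))
  af <- detect_af(sec, prof)
  expect_warning(ac <- detect_ac(prof, af), "no distinct constriction")
  # the reported chord is the most apical in-window sample
  idx <- which(prof$samples$s > prof$step & prof$samples$s <= 3)
  expect_equal(ac$s, prof$samples$s[idx[1]])
})

test_that("detect_ac errors when the search window holds no samples", {
  wa <- rbind(c(0, 0), c(0, 2))
  wb <- rbind(c(1, 0), c(1, 2))
  sec <- mm_section(wa, wb, c(0.5, 1), apical_end = "first")
  prof <- compute_width_profile(sec, build_medial_path(sec, step = 0.05))
  af <- detect_af(sec, prof)
  expect_error(detect_ac(prof, af, window = 0.01),
               class = "apexmetry_detection_error")
})

test_that("AC-AF distance is an axis-aligned perpendicular and isometry-invariant", {
  af <- landmark("AF", c(0, 0), c(0.64, 0))
  ac <- landmark("AC", c(0.365, 0.36), c(0.635, 0.36), s = 0.36)
  expect_equal(ac$midpoint, c(0.5, 0.36), tolerance = 1e-12)
  expect_equal(ac_af_distance(ac, af), 0.36, tolerance = 1e-12)

  th <- 1.1; ctr <- c(4, -2)
  rot <- function(p) as.numeric(apexmetry:::rotate_points(rbind(p), th, ctr))
  af_r <- landmark("AF", rot(c(0, 0)), rot(c(0.64, 0)))
  ac_r <- landmark("AC", rot(c(0.365, 0.36)), rot(c(0.635, 0.36)), s = 0.36)
  expect_equal(ac_af_distance(ac_r, af_r), 0.36, tolerance = 1e-9)
  expect_error(ac_af_distance(ac, landmark("AF", c(0, 0), c(0, 0))),
               class = "apexmetry_geometry_error")
})

test_that("detected AF is never narrower than detected AC on hourglass apices", {
  sw <- draw_apex_params(12, seed = 31, jitter = 0.002)
  for (i in seq_len(nrow(sw$draws))) {
    g <- make_apex_geometry(apex_params_from_draw(sw$draws[i, ], sw$config),
                            seed = sw$draws$jitter_seed[i])
    m <- measure_quietly(geometry_as_section(g))
    expect_gte(m$af$diameter, m$ac$diameter)
  }
})

test_that("detect_ac matches the brute-force vertex-pair oracle on coarse sections", {
  # noise-free walls so the enumeration oracle and the denoised detector
  # measure the same quantity (with jitter the global vertex-pair minimum
  # chases noise dips that detection deliberately averages away)
  sw <- draw_apex_params(10, seed = 17, jitter = 0)
  for (i in seq_len(nrow(sw$draws))) {
    g <- make_apex_geometry(apex_params_from_draw(sw$draws[i, ], sw$config),
                            seed = sw$draws$jitter_seed[i], step = 0.02)
    sec <- geometry_as_section(g)
    m <- measure_quietly(sec)
    oracle <- brute_force_min_chord(sec)
    expect_lt(abs(m$ac$diameter - oracle$width),
              2 * mm_per_pixel(sec$calibration))
  }
})

test_that("AC diameter is recovered across the anatomical range", {
  # sweep of constriction sizes at fixed anatomy, exact polyline route
  acs <- seq(0.1, 0.5, length.out = 50)
  errs <- vapply(seq_along(acs), function(i) {
    p <- apex_params(ac_diameter = acs[i], af_diameter = acs[i] + 0.3,
                     coronal_width = 1.2, contour_jitter_sigma = 0.002)
    g <- make_apex_geometry(p, seed = 1000 + i)
    m <- measure_quietly(geometry_as_section(g))
    abs(m$ac$diameter - acs[i])
  }, 0)
  expect_lt(mean(errs), 2 * 0.002)
})
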