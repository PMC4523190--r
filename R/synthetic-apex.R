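# Synthetic ground-truth apex generator.
#
# Emulates the cross-sectional geometry the measurement pipeline is built
# for: a canal that tapers from its coronal width down to the apical
# constriction and then re-flares to the foramen at the terminus (hourglass
# apex), with a file tip placed at a known signed offset from the foramen
# chord. Geometries can be rendered as label-image annotation bundles, and
# whole cohorts can be sampled with the per-group distributions of a study
# design, so every pipeline stage is testable against stored truth.

#' Parameters of one synthetic apex geometry
#'
#' All lengths in mm. The canal width tapers linearly from `coronal_width`
#' at the coronal end to `ac_diameter` at axial position `ac_af_distance`
#' from the terminus, then re-flares linearly to `af_diameter` at the
#' terminus.
#'
#' @param canal_length Axial length of the generated section (default 2.5).
#' @param coronal_width Canal width at the coronal end (default 1.0).
#' @param ac_diameter Constriction diameter (default 0.27).
#' @param af_diameter Foramen diameter (default 0.64).
#' @param ac_af_distance Axial distance from terminus to constriction
#'   (default 0.36).
#' @param curvature Centerline curvature in 1/mm; 0 = straight (default).
#' @param tip_offset_af Signed ground-truth distance from the tip to the AF
#'   chord; negative = beyond the foramen (default 0.3).
#' @param contour_jitter_sigma SD of Gaussian vertex jitter emulating
#'   hand-marked strokes, mm (default 0.002, about one pixel at the default
#'   resolution).
#' @param microns_per_pixel Rendering resolution (default 2).
#' @return Validated list of class `apex_params`.
#' @export
apex_params <- function(canal_length = 2.5, coronal_width = 1.0,
                        ac_diameter = 0.27, af_diameter = 0.64,
                        ac_af_distance = 0.36, curvature = 0,
                        tip_offset_af = 0.3, contour_jitter_sigma = 0.002,
                        microns_per_pixel = 2) {
  p <- list(canal_length = canal_length, coronal_width = coronal_width,
            ac_diameter = ac_diameter, af_diameter = af_diameter,
            ac_af_distance = ac_af_distance, curvature = curvature,
            tip_offset_af = tip_offset_af,
            contour_jitter_sigma = contour_jitter_sigma,
            microns_per_pixel = microns_per_pixel)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                  is.finite(v), TRUE)
  if (!all(num))
    abort("all apex parameters must be single finite numbers",
          "apexmetry_validation_error")
  if (!(ac_diameter > 0 && ac_diameter < af_diameter &&
        af_diameter <= coronal_width))
    abort("need 0 < ac_diameter < af_diameter <= coronal_width",
          "apexmetry_validation_error")
  if (!(ac_af_distance > 0 && ac_af_distance < canal_length))
    abort("need 0 < ac_af_distance < canal_length",
          "apexmetry_validation_error")
  if (contour_jitter_sigma < 0)
    abort("contour_jitter_sigma must be >= 0", "apexmetry_validation_error")
  if (microns_per_pixel <= 0)
    abort("microns_per_pixel must be positive", "apexmetry_calibration_error")
  structure(p, class = "apex_params")
}

# Smooth (window-averaged) Gaussian vertex jitter with marginal SD sigma.
correlated_jitter <- function(n, sigma, window = 5) {
  raw <- matrix(stats::rnorm(2 * n, 0, sigma), ncol = 2)
  if (n < window) return(raw)
  sm <- apply(raw, 2, function(x) {
    f <- stats::filter(x, rep(1 / window, window), sides = 2)
    f[is.na(f)] <- x[is.na(f)] / sqrt(window)   # keep end variance bounded
    as.numeric(f)
  })
  sm * sqrt(window)
}

# Centerline position, tangent and inward normal at axial stations t (mm
# from the terminus). Tangent points coronally.
centerline_frame <- function(t, curvature) {
  if (abs(curvature) < 1e-12) {
    pos <- cbind(rep(0, length(t)), t)
    tan <- cbind(rep(0, length(t)), rep(1, length(t)))
  } else {
    th <- curvature * t
    pos <- cbind((1 - cos(th)) / curvature, sin(th) / curvature)
    tan <- cbind(sin(th), cos(th))
  }
  nrm <- cbind(tan[, 2], -tan[, 1])
  list(pos = pos, tan = tan, nrm = nrm)
}

#' Generate one ground-truth apex geometry
#'
#' @param params An [apex_params()] object.
#' @param seed Optional integer seed for the contour jitter.
#' @param step Axial sampling of wall vertices, mm (default 0.01).
#' @return List of class `apex_geometry`: jittered `wall_a`, `wall_b` and
#'   `tip` (mm, terminus at the origin, coronal direction +y), the noise-free
#'   `centerline`, true AC/AF chords (`true_ac`, `true_af`, each a 2 x 2
#'   matrix of endpoints), and the stored truth `ac_diameter`, `af_diameter`,
#'   `ac_af_perp` (perpendicular AC-midpoint-to-AF-chord distance),
#'   `d_ac_true`, `d_af_true` and `position_class_true`.
#' @export
make_apex_geometry <- function(params, seed = NULL, step = 0.01) {
  if (!inherits(params, "apex_params"))
    abort("params must be an apex_params object", "apexmetry_validation_error")
  # knots of the piecewise-linear width profile; make sure the constriction
  # station is itself a vertex so the true minimal chord is realisable
  t <- sort(unique(c(seq(0, params$canal_length, by = step),
                     params$canal_length, params$ac_af_distance)))
  w <- stats::approx(
    x = c(0, params$ac_af_distance, params$canal_length),
    y = c(params$af_diameter, params$ac_diameter, params$coronal_width),
    xout = t, ties = "ordered")$y
  fr <- centerline_frame(t, params$curvature)
  wall_a <- fr$pos + fr$nrm * (w / 2)
  wall_b <- fr$pos - fr$nrm * (w / 2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (params$contour_jitter_sigma > 0) {
    # hand-marking tremor wobbles smoothly along the stroke rather than
    # independently per vertex; correlated jitter also keeps the jittered
    # polylines simple (non-self-intersecting)
    for (attempt in 1:20) {
      ja <- correlated_jitter(nrow(wall_a), params$contour_jitter_sigma)
      jb <- correlated_jitter(nrow(wall_b), params$contour_jitter_sigma)
      wa <- wall_a + ja
      wb <- wall_b + jb
      if (!polyline_self_intersects(wa) && !polyline_self_intersects(wb) &&
          !polylines_cross(wa, wb)) break
      if (attempt == 20)
        abort("could not draw non-self-intersecting jittered walls",
              "apexmetry_validation_error")
    }
    wall_a <- wa
    wall_b <- wb
  }

  i_ac <- which(t == params$ac_af_distance)[1]
  f0 <- centerline_frame(0, params$curvature)
  fac <- centerline_frame(params$ac_af_distance, params$curvature)
  true_af <- rbind(f0$pos[1, ] + f0$nrm[1, ] * params$af_diameter / 2,
                   f0$pos[1, ] - f0$nrm[1, ] * params$af_diameter / 2)
  true_ac <- rbind(fac$pos[1, ] + fac$nrm[1, ] * params$ac_diameter / 2,
                   fac$pos[1, ] - fac$nrm[1, ] * params$ac_diameter / 2)
  tip <- f0$pos[1, ] + params$tip_offset_af * f0$tan[1, ]

  af_lm <- new_landmark("AF", true_af[1, ], true_af[2, ], 0)
  ac_lm <- new_landmark("AC", true_ac[1, ], true_ac[2, ],
                        params$ac_af_distance)
  ref <- f0$pos[1, ] - f0$tan[1, ]          # strictly apical reference
  d_ac_true <- signed_distance_to_landmark(tip, ac_lm, ref)$distance
  d_af_true <- signed_distance_to_landmark(tip, af_lm, ref)$distance
  structure(list(
    params = params, wall_a = wall_a, wall_b = wall_b, tip = tip,
    centerline = fr$pos, axial = t,
    true_ac = true_ac, true_af = true_af,
    ac_diameter = params$ac_diameter, af_diameter = params$af_diameter,
    ac_af_perp = ac_af_distance(ac_lm, af_lm),
    d_ac_true = d_ac_true, d_af_true = d_af_true,
    position_class_true = classify_tip(d_ac_true, d_af_true)
  ), class = "apex_geometry")
}

#' Turn a geometry directly into an annotated section (no rasterisation)
#'
#' Exact polyline route, useful for isolating algorithmic error from pixel
#' quantisation.
#'
#' @param geometry An `apex_geometry`.
#' @param specimen_id,group Passed through to the section.
#' @return An [annotated_section()] whose pixel coordinates are the mm
#'   coordinates divided by the calibration scale.
#' @export
geometry_as_section <- function(geometry, specimen_id = "synthetic",
                                group = NA_character_) {
  k <- geometry$params$microns_per_pixel / 1000
  annotated_section(specimen_id, geometry$params$microns_per_pixel,
                    geometry$wall_a / k, geometry$wall_b / k,
                    geometry$tip / k, group = group, apical_end = "first")
}

# Rasterise one polyline (mm) into 0-based integer pixel chain coordinates.
raster_chain <- function(V, origin, mmpp) {
  den <- resample_polyline(V, mmpp * 0.4)$points
  px <- round(sweep(den, 2, origin) / mmpp)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px[keep, , drop = FALSE]
}

#' Render a geometry as an annotation bundle on disk
#'
#' Writes a grayscale PNG label image (wall A pixels = 1, wall B = 2, file
#' tip = 3), a sidecar JSON loadable by [load_annotation()], and a ground
#' truth JSON (never read by the measurement pipeline) holding the stored
#' true values and the mm-to-pixel transform.
#'
#' @param geometry An `apex_geometry`.
#' @param out_dir Output directory (created if needed).
#' @param specimen_id,group Identification written into the sidecar.
#' @return Named list with paths `sidecar`, `mask`, `truth`.
#' @export
render_annotation <- function(geometry, out_dir, specimen_id = "synthetic",
                              group = NA_character_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mmpp <- geometry$params$microns_per_pixel / 1000
  all_pts <- rbind(geometry$wall_a, geometry$wall_b, geometry$tip)
  lo <- apply(all_pts, 2, min)
  hi <- apply(all_pts, 2, max)
  margin <- pmax(0.1 * (hi - lo), 5 * mmpp)
  origin <- lo - margin
  size_px <- ceiling((hi + margin - origin) / mmpp) + 1
  if (any(size_px < 8) || any(size_px > 20000))
    abort(sprintf("canvas %d x %d px out of range for this geometry/scale",
                  size_px[1], size_px[2]), "apexmetry_rendering_error")
  mask <- matrix(0L, nrow = size_px[2], ncol = size_px[1])   # rows = y
  put <- function(px, label) {
    idx <- cbind(px[, 2] + 1, px[, 1] + 1)
    mask[idx] <<- label
  }
  put(raster_chain(geometry$wall_a, origin, mmpp), 1L)
  put(raster_chain(geometry$wall_b, origin, mmpp), 2L)
  tip_px <- round((geometry$tip - origin) / mmpp)
  if (mask[tip_px[2] + 1, tip_px[1] + 1] != 0L)
    abort("file-tip pixel collides with a wall stroke at this resolution",
          "apexmetry_rendering_error")
  mask[tip_px[2] + 1, tip_px[1] + 1] <- 3L

  mask_path <- file.path(out_dir, paste0(specimen_id, "_mask.png"))
  sidecar_path <- file.path(out_dir, paste0(specimen_id, ".json"))
  truth_path <- file.path(out_dir, paste0(specimen_id, "_truth.json"))
  png::writePNG(mask / 255, mask_path)
  sidecar <- list(
    specimen_id = specimen_id,
    microns_per_pixel = geometry$params$microns_per_pixel,
    apical_end = "auto",
    mask = basename(mask_path)
  )
  if (!is.na(group)) sidecar$group <- group
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    specimen_id = specimen_id,
    params = unclass(geometry$params),
    transform = list(origin_mm = origin, mm_per_px = mmpp),
    wall_a_mm = geometry$wall_a, wall_b_mm = geometry$wall_b,
    tip_mm = geometry$tip,
    ac_diameter = geometry$ac_diameter, af_diameter = geometry$af_diameter,
    ac_af_perp = geometry$ac_af_perp,
    d_ac_true = geometry$d_ac_true, d_af_true = geometry$d_af_true,
    position_class_true = geometry$position_class_true
  ), truth_path, auto_unbox = TRUE, digits = NA)
  list(sidecar = sidecar_path, mask = mask_path, truth = truth_path)
}

# ---- cohort sampling --------------------------------------------------------

# Truncated-normal sampler parameterised by the TARGET mean of the truncated
# distribution: the underlying normal location is solved (monotone root) so
# that the post-truncation mean equals `target_mean`.
rtnorm_target <- function(n, target_mean, sd, lower) {
  if (sd < 0) abort("sd must be >= 0", "apexmetry_validation_error")
  if (sd == 0) {
    if (target_mean < lower)
      abort("degenerate distribution entirely below its truncation bound",
            "apexmetry_validation_error")
    return(rep(target_mean, n))
  }
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * exp(stats::dnorm(a, log = TRUE) -
                    stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  # A truncated mean can never fall below the bound: when the target is
  # unattainable (possible for conditional bounds like af >= ac + gap on an
  # extreme companion draw) the target is used as the location parameter
  # instead, accepting the small truncation shift on those rare draws.
  mu <- if (target_mean <= lower + 1e-8) target_mean else tryCatch(
    stats::uniroot(function(m) trunc_mean(m) - target_mean,
                   lower = target_mean - 20 * sd, upper = target_mean + sd,
                   tol = 1e-10)$root,
    error = function(e) target_mean)
  # inverse-CDF sampling of the upper tail: exact for arbitrarily deep
  # truncation, where naive rejection would stall
  p_tail <- stats::pnorm((lower - mu) / sd, lower.tail = FALSE)
  if (p_tail <= 0)
    abort("truncation bound unsatisfiable for these parameters",
          "apexmetry_validation_error")
  mu + sd * stats::qnorm(stats::runif(n) * p_tail, lower.tail = FALSE)
}

#' Default cohort configuration
#'
#' Three groups (RPM, EPM, EPA) of `n_per_group` specimens. Apical
#' dimensions are truncated normals whose post-truncation means match the
#' configured values: AC diameter 0.27 (0.11) mm (lower bound 0.05), AF
#' diameter 0.64 (0.22) mm (lower bound AC + 0.05), AC-AF interval
#' 0.36 (0.26) mm (lower bound 0.05). Signed tip offsets from the foramen
#' are untruncated normals per group: RPM 0.301 (0.22), EPM 0.411 (0.28),
#' EPA 0.238 (0.35) mm.
#'
#' @param n_per_group Specimens per group (default 40).
#' @param seed RNG seed used by [sample_cohort()].
#' @return List of class `cohort_config`.
#' @export
default_cohort_config <- function(n_per_group = 40, seed = 1) {
  structure(list(
    n_per_group = n_per_group,
    seed = seed,
    ac_diameter = list(mean = 0.27, sd = 0.11, lower = 0.05),
    af_diameter = list(mean = 0.64, sd = 0.22, lower_gap = 0.05),
    ac_af_distance = list(mean = 0.36, sd = 0.26, lower = 0.05),
    tip_offset_af = list(RPM = list(mean = 0.301, sd = 0.22),
                         EPM = list(mean = 0.411, sd = 0.28),
                         EPA = list(mean = 0.238, sd = 0.35)),
    contour_jitter_sigma = 0.002,
    curvature = 0,
    microns_per_pixel = 2
  ), class = "cohort_config")
}

#' Read a cohort configuration from JSON
#' @param path JSON file with any subset of the [default_cohort_config()]
#'   fields; missing fields take the defaults.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_cohort_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

#' Sample ground-truth parameters for a synthetic cohort
#'
#' @param config A `cohort_config`.
#' @param groups Which groups to sample (default all three).
#' @return Data frame with one row per specimen: `specimen_id`, `group`,
#'   the drawn `ac_diameter`, `af_diameter`, `ac_af_distance`,
#'   `tip_offset_af`, and a per-specimen `jitter_seed`.
#' @export
sample_cohort_params <- function(config, groups = GROUPS) {
  if (!inherits(config, "cohort_config"))
    abort("config must be a cohort_config", "apexmetry_validation_error")
  if (config$n_per_group < 1)
    abort("n_per_group must be >= 1", "apexmetry_validation_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  rows <- list()
  for (g in GROUPS) {            # draw in fixed group order for determinism
    n <- config$n_per_group
    ac <- rtnorm_target(n, config$ac_diameter$mean, config$ac_diameter$sd,
                        config$ac_diameter$lower)
    af <- vapply(ac, function(a)
      rtnorm_target(1, config$af_diameter$mean, config$af_diameter$sd,
                    a + config$af_diameter$lower_gap), 0)
    acaf <- rtnorm_target(n, config$ac_af_distance$mean,
                          config$ac_af_distance$sd,
                          config$ac_af_distance$lower)
    off <- stats::rnorm(n, config$tip_offset_af[[g]]$mean,
                        config$tip_offset_af[[g]]$sd)
    jseed <- sample.int(.Machine$integer.max, n)
    if (g %in% groups)
      rows[[g]] <- data.frame(
        specimen_id = sprintf("%s_%03d", g, seq_len(n)), group = g,
        ac_diameter = ac, af_diameter = af, ac_af_distance = acaf,
        tip_offset_af = off, jitter_seed = jseed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apex parameters for one sampled cohort draw
#'
#' Expands a row of [sample_cohort_params()] into a full [apex_params()],
#' applying the cohort-level rendering settings and auto-sizing the canal
#' length and coronal width to the draw.
#'
#' @param row One-row data frame from [sample_cohort_params()].
#' @param config The `cohort_config` the draw came from.
#' @return An [apex_params()] object.
#' @export
apex_params_from_draw <- function(row, config) {
  apex_params(
    canal_length = max(2.5, row$ac_af_distance + 1.0),
    coronal_width = max(1.0, row$af_diameter + 0.05),
    ac_diameter = row$ac_diameter,
    af_diameter = row$af_diameter,
    ac_af_distance = row$ac_af_distance,
    curvature = config$curvature,
    tip_offset_af = row$tip_offset_af,
    contour_jitter_sigma = config$contour_jitter_sigma,
    microns_per_pixel = config$microns_per_pixel)
}

#' Sample and render a synthetic cohort
#'
#' Draws per-specimen ground-truth parameters with [sample_cohort_params()]
#' and renders each specimen as an annotation bundle. Deterministic given
#' `config$seed`.
#'
#' @param config A `cohort_config`.
#' @param out_dir Directory for the rendered bundles.
#' @param groups Which groups to generate (default all three).
#' @return Data frame: `specimen_id`, `group`, `sidecar`, `truth` (paths).
#' @export
sample_cohort <- function(config, out_dir, groups = GROUPS) {
  draws <- sample_cohort_params(config, groups)
  res <- vector("list", nrow(draws))
  for (i in seq_len(nrow(draws))) {
    row <- draws[i, ]
    geom <- make_apex_geometry(apex_params_from_draw(row, config),
                               seed = row$jitter_seed)
    paths <- render_annotation(geom, out_dir, specimen_id = row$specimen_id,
                               group = row$group)
    res[[i]] <- data.frame(specimen_id = row$specimen_id, group = row$group,
                           sidecar = paths$sidecar, truth = paths$truth)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
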