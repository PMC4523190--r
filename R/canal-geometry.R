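# Medial path and canal width profile between the two marked walls.
#
# The medial path is built from a symmetric nearest-point correspondence:
# every vertex of wall A is projected onto wall B and vice versa, the
# midpoints of both correspondence sets are merged and ordered by their
# arclength station along wall A, and the resulting polyline is resampled at
# uniform spacing from the apical terminus (midpoint of the two apical wall
# endpoints). The canal width at a medial sample is the length of the chord
# joining the nearest points on either wall, the discrete analogue of the
# smallest distance between the walls at that axial station.

#' Build the medial path of an annotated section
#'
#' @param section An [annotated_section()].
#' @param step Sampling spacing along the path, mm (default 0.01).
#' @param smooth_window Optional moving-average window (vertex count) applied
#'   to each wall before path construction; `1` (default) disables smoothing.
#' @return Object of class `medial_path`: `points` (n x 2, mm), `s`
#'   (cumulative arclength from the apical terminus, mm), `wall_a`, `wall_b`
#'   (the smoothed walls in mm used for construction), and `step`.
#' @export
build_medial_path <- function(section, step = 0.01, smooth_window = 1) {
  if (!inherits(section, "annotated_section"))
    abort("section must be an annotated_section", "apexmetry_validation_error")
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    abort("step must be a positive number (mm)", "apexmetry_validation_error")
  sm <- section_mm(section)
  A <- smooth_polyline(sm$wall_a, smooth_window)
  B <- smooth_polyline(sm$wall_b, smooth_window)

  # Seed axis: wall-A vertices paired with their nearest points on wall B
  # (ordered by construction), anchored at the apical terminus midpoint.
  projAB <- project_onto_polyline(A, B)
  mids <- (A + projAB$point) / 2
  terminus <- (A[1, ] + B[1, ]) / 2
  mids <- rbind(terminus, mids)
  keep <- c(TRUE, sqrt(rowSums(diff(mids)^2)) > 1e-9)
  mids <- mids[keep, , drop = FALSE]
  if (nrow(mids) < 2)
    abort("walls too short to form a medial path", "apexmetry_geometry_error")

  # Symmetrise: re-centre every resampled point to the midpoint of its
  # nearest points on both walls (fixed-point iteration removes the seeding
  # wall's bias and corner-cutting distortions of the raw correspondence).
  rs <- resample_polyline(mids, step)
  pts <- rs$points
  for (iter in 1:3) {
    fa <- project_onto_polyline(pts, A)$point
    fb <- project_onto_polyline(pts, B)$point
    pts <- (fa + fb) / 2
    pts[1, ] <- terminus                  # the apical anchor stays put
    keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-9)
    rs <- resample_polyline(pts[keep, , drop = FALSE], step)
    pts <- rs$points
  }
  # Residual point-level noise makes the polyline wiggle, which inflates
  # arclength relative to the true axial station; a short moving average
  # restores an honest parameterisation.
  if (nrow(pts) > 4) {
    rs <- resample_polyline(smooth_polyline(pts, 7), step)
    pts <- rs$points
  }
  # Trim the coronal tail where the correspondence clamps at a wall's last
  # vertex: midpoints there are boundary artefacts, off the true midline.
  fa <- project_onto_polyline(pts, A)
  fb <- project_onto_polyline(pts, B)
  endA <- A[nrow(A), ]; endB <- B[nrow(B), ]
  clamped <- (abs(fa$point[, 1] - endA[1]) < 1e-9 &
                abs(fa$point[, 2] - endA[2]) < 1e-9) |
    (abs(fb$point[, 1] - endB[1]) < 1e-9 & abs(fb$point[, 2] - endB[2]) < 1e-9)
  last_free <- max(which(!clamped), 2)
  if (last_free < nrow(pts)) {
    keep_n <- min(last_free + 1, nrow(pts))   # retain one boundary sample
    pts <- pts[seq_len(keep_n), , drop = FALSE]
    rs$s <- rs$s[seq_len(keep_n)]
    fa$dist <- fa$dist[seq_len(keep_n)]
    fb$dist <- fb$dist[seq_len(keep_n)]
  }

  # Validate: medial points must lie strictly between the walls.
  dA <- fa$dist
  dB <- fb$dist
  ok <- dA > 0 & dB > 0
  if (!all(ok)) {
    pts <- pts[ok, , drop = FALSE]
    if (nrow(pts) < 2)
      abort("medial path degenerate: points coincide with a wall",
            "apexmetry_geometry_error")
    warning(sprintf("dropped %d medial point(s) touching a wall", sum(!ok)))
    rs$s <- rs$s[ok] - rs$s[which(ok)[1]]
  }

  structure(list(points = pts, s = rs$s, wall_a = A, wall_b = B,
                 wall_a_raw = sm$wall_a, wall_b_raw = sm$wall_b,
                 px_mm = mm_per_pixel(section$calibration),
                 step = step),
            class = "medial_path")
}

#' @export
print.medial_path <- function(x, ...) {
  cat(sprintf("medial_path: %d samples, length %.3f mm, step %.4f mm\n",
              nrow(x$points), max(x$s), x$step))
  invisible(x)
}

#' Canal width profile along the medial path
#'
#' At each medial sample the chord joins the nearest point on wall A and the
#' nearest point on wall B; its length is the local canal width. Chords that
#' cross either wall (possible at sharp bends) are rejected and the sample is
#' dropped with a warning.
#'
#' @param section The [annotated_section()] the path was built from.
#' @param path A [build_medial_path()] result.
#' @return Object of class `width_profile`: data frame `samples` with columns
#'   `s`, `width` (mm) and chord endpoints `ax, ay, bx, by` (mm).
#' @export
compute_width_profile <- function(section, path) {
  if (!inherits(path, "medial_path"))
    abort("path must be a medial_path", "apexmetry_validation_error")
  P <- path$points
  pa <- project_onto_polyline(P, path$wall_a)
  pb <- project_onto_polyline(P, path$wall_b)
  a <- pa$point; b <- pb$point
  width <- sqrt(rowSums((a - b)^2))

  # Chord admissibility: must not cross either wall polyline interior.
  n <- nrow(P)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (width[i] <= 0) { ok[i] <- FALSE; next }
    if (segment_crosses_polyline(a[i, ], b[i, ], path$wall_a) ||
        segment_crosses_polyline(a[i, ], b[i, ], path$wall_b))
      ok[i] <- FALSE
  }
  if (!any(ok))
    abort("no admissible wall-to-wall chord at any medial sample",
          "apexmetry_geometry_error")
  if (!all(ok))
    warning(sprintf("dropped %d profile sample(s) with inadmissible chords",
                    sum(!ok)))
  samples <- data.frame(s = path$s[ok], width = width[ok],
                        ax = a[ok, 1], ay = a[ok, 2],
                        bx = b[ok, 1], by = b[ok, 2])
  structure(list(samples = samples, step = path$step, path = path),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf(
    "width_profile: %d samples, width %.4f-%.4f mm (min at s = %.3f mm)\n",
    nrow(x$samples), min(x$samples$width), max(x$samples$width),
    x$samples$s[which.min(x$samples$width)]))
  invisible(x)
}
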