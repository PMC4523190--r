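# Detection of the apical foramen (AF) and apical constriction (AC) on the
# width profile, and their separation.
#
# The foramen is the canal's terminal opening: its chord joins the two apical
# terminal wall endpoints (axial station s = 0). The constriction is the
# narrowest admissible wall-to-wall chord within a configurable apical search
# window; ties break toward the most apical sample.

new_landmark <- function(kind, chord_a, chord_b, s) {
  chord_a <- as.numeric(chord_a); chord_b <- as.numeric(chord_b)
  diameter <- sqrt(sum((chord_a - chord_b)^2))
  structure(list(kind = kind, chord_a = chord_a, chord_b = chord_b,
                 midpoint = (chord_a + chord_b) / 2,
                 diameter = diameter, s = s),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("landmark %s: diameter %.4f mm at s = %.3f mm\n",
              x$kind, x$diameter, x$s))
  invisible(x)
}

#' Detect the apical foramen
#'
#' @param section The [annotated_section()].
#' @param profile The [compute_width_profile()] result (used for validation
#'   context only; the AF chord is defined by the terminal wall endpoints).
#' @return A `landmark` with `kind = "AF"`, `s = 0`.
#' @export
detect_af <- function(section, profile) {
  sm <- section_mm(section)
  a <- sm$wall_a[1, ]
  b <- sm$wall_b[1, ]
  if (sqrt(sum((a - b)^2)) < 1e-12)
    abort("degenerate apical foramen: terminal wall endpoints coincide",
          "apexmetry_geometry_error")
  new_landmark("AF", a, b, 0)
}

#' Detect the apical constriction
#'
#' Scans the width profile over axial stations `s` in `(step, window]` and
#' returns the globally narrowest chord; the first in-window sample is
#' excluded so the foramen itself is never re-detected. A canal that only
#' tapers (no re-flare toward the foramen) has its minimum at the window's
#' apical boundary and is flagged with a "no distinct constriction" warning.
#'
#' @param profile A [compute_width_profile()] result.
#' @param af The detected foramen `landmark` (for the terminal context).
#' @param window Apical search window, mm from the terminus (default 3).
#' @param refine Localise the constriction station by a two-limb linear fit
#'   of the width profile around the seed minimum (default `TRUE`). A raw
#'   argmin is noise-limited on shallow constrictions because the minimum is
#'   nearly flat; fitting the V over many samples averages the noise.
#' @return A `landmark` with `kind = "AC"`.
#' @export
detect_ac <- function(profile, af, window = 3.0, refine = TRUE) {
  if (!inherits(profile, "width_profile"))
    abort("profile must be a width_profile", "apexmetry_validation_error")
  eps <- profile$step
  sm <- profile$samples
  idx <- which(sm$s > eps & sm$s <= window)
  if (!length(idx))
    abort(sprintf("no profile samples with s in (%.4f, %.1f] mm", eps, window),
          "apexmetry_detection_error")
  w <- sm$width[idx]
  # ties break toward the most apical (smallest s) sample; samples are
  # ordered by increasing s, so which.min already takes the first minimum
  best <- idx[which.min(w)]
  a <- c(sm$ax[best], sm$ay[best])
  b <- c(sm$bx[best], sm$by[best])
  s_best <- sm$s[best]
  boundary <- best == idx[1]

  fit <- NULL
  if (refine && !is.null(profile$path)) {
    near <- idx[abs(sm$s[idx] - s_best) <= 0.12]
    # station fit uses perpendicular-ray widths: unlike nearest-point
    # chords they carry no wall-tilt bias, so the V limbs stay straight
    wp <- vapply(near, function(i) {
      ch <- perp_chord_at_station(profile$path, sm$s[i])
      if (is.null(ch)) sm$width[i] else sqrt(sum((ch$a - ch$b)^2))
    }, 0)
    fit <- vee_fit(sm$s[near], wp)
  }
  if (boundary && is.null(fit)) {
    # no interior V anywhere near the apical boundary: genuine monotone
    # taper (or refinement disabled)
    warning("no distinct constriction: width is minimal at the apical ",
            "boundary of the search window (monotone taper?)")
    return(new_landmark("AC", a, b, s_best))
  }
  if (refine && !is.null(profile$path)) {
    # Two regimes. On a shallow V the minimal chord drifts axially with
    # noise but any chord near the fitted station has the right width, so
    # the chord is cut at the fitted kink. On a steep V the width is
    # slope-sensitive to the station while the minimal chord is pinned to
    # the constriction corner, so a dense local minimal-distance search
    # takes over. Both evaluate against the RAW walls: smoothing
    # stabilises the station fit but rounds the corner, lifting widths
    # and displacing minima toward the shallow limb.
    done <- FALSE
    if (!is.null(fit) && max(fit$p, fit$r) <= 1.5) {
      s_hat <- fit$s_hat
      ch <- perp_chord_at_station(profile$path, s_hat, raw = TRUE)
      if (is.null(ch)) ch <- perp_chord_at_station(profile$path, s_hat)
      if (is.null(ch)) ch <- chord_at_station(profile$path, s_hat)
      if (!is.null(ch)) {
        a <- ch$a; b <- ch$b; s_best <- s_hat; done <- TRUE
      }
    }
    if (!done) {
      # Near-ties within the digitisation noise are resolved toward the
      # steep limb: quantisation dips on the shallow limb can undercut the
      # true notch by a fraction of a pixel while lying far from it.
      tie <- if (!is.null(fit) && fit$r > fit$p) "coronal" else "apical"
      tol <- if (!is.null(profile$path$px_mm))
        0.5 * profile$path$px_mm else 0.001
      rad <- max(0.02, 2 * eps)
      seed <- if (!is.null(fit)) chord_at_station(profile$path, fit$s_hat)
              else NULL
      if (!is.null(seed)) { a0 <- seed$a; b0 <- seed$b }
      else { a0 <- a; b0 <- b }
      rc <- refine_min_chord(a0, b0, profile$path, radius = rad, raw = TRUE,
                             tie_break = tie, tie_tol = tol)
      if (is.null(rc))
        rc <- refine_min_chord(a0, b0, profile$path, radius = rad,
                               tie_break = tie, tie_tol = tol)
      if (!is.null(rc)) {
        a <- rc$a; b <- rc$b
        s_best <- project_onto_polyline(rbind((a + b) / 2),
                                        profile$path$points)$s
      }
      # if the local minimum landed far from the fitted station, deep
      # quantisation dips are suspected: re-search tightly around the fit
      if (!is.null(fit) && abs(s_best - fit$s_hat) > 0.003) {
        seed2 <- chord_at_station(profile$path, fit$s_hat)
        if (!is.null(seed2)) {
          rc2 <- refine_min_chord(seed2$a, seed2$b, profile$path,
                                  radius = 0.003, raw = TRUE,
                                  tie_break = tie, tie_tol = tol)
          if (!is.null(rc2)) {
            a <- rc2$a; b <- rc2$b
            s_best <- project_onto_polyline(rbind((a + b) / 2),
                                            profile$path$points)$s
          }
        }
      }
    }
  }
  new_landmark("AC", a, b, s_best)
}

# Dense local search for the true minimal wall-to-wall chord around a seed
# chord (a0, b0): both walls are clipped to a window around the seed
# endpoints, densified, and the closest admissible point pair returned.
refine_min_chord <- function(a0, b0, path, radius, raw = FALSE,
                             tie_break = "apical", tie_tol = 0) {
  A <- if (raw && !is.null(path$wall_a_raw)) path$wall_a_raw else path$wall_a
  B <- if (raw && !is.null(path$wall_b_raw)) path$wall_b_raw else path$wall_b
  sa <- project_onto_polyline(rbind(a0), A)$s
  sb <- project_onto_polyline(rbind(b0), B)$s
  subA <- clip_polyline(A, sa - radius, sa + radius)
  subB <- clip_polyline(B, sb - radius, sb + radius)
  spacing <- radius / 40
  dA <- if (nrow(subA) > 1) resample_polyline(subA, spacing)$points else subA
  dB <- if (nrow(subB) > 1) resample_polyline(subB, spacing)$points else subB
  d2 <- outer(dA[, 1], dB[, 1], `-`)^2 + outer(dA[, 2], dB[, 2], `-`)^2
  dmin <- sqrt(min(d2))
  near <- which(sqrt(d2) <= dmin + tie_tol, arr.ind = TRUE)
  # walls are apical-first, so smaller indices lie apical
  pos <- near[, 1] + near[, 2]
  k <- near[if (tie_break == "apical") which.min(pos) else which.max(pos), ]
  a <- dA[k[1], ]; b <- dB[k[2], ]
  # admissibility: reject genuine mid-chord wall crossings, but tolerate
  # grazing intersections near the endpoints (digitised strokes are jagged
  # at the pixel scale, so a chord anchored ON a wall often clips an
  # adjacent stair tooth)
  end_tol <- max(2 * if (is.null(path$px_mm)) 0.001 else path$px_mm,
                 0.05 * dmin)
  hits <- rbind(seg_poly_intersections(a, b, A),
                seg_poly_intersections(a, b, B))
  if (nrow(hits)) {
    d_end <- pmin(sqrt((hits[, 1] - a[1])^2 + (hits[, 2] - a[2])^2),
                  sqrt((hits[, 1] - b[1])^2 + (hits[, 2] - b[2])^2))
    if (any(d_end > end_tol)) return(NULL)
  }
  list(a = a, b = b)
}

# Chord through the medial point at station s_hat, perpendicular to the
# local path tangent, with endpoints where the normal ray meets each wall.
# NULL when the ray misses a wall (e.g. beyond the foramen opening).
perp_chord_at_station <- function(path, s_hat, raw = FALSE) {
  smax <- max(path$s)
  if (!is.finite(s_hat) || s_hat < min(path$s) || s_hat > smax) return(NULL)
  px <- stats::approx(path$s, path$points[, 1], xout = s_hat,
                      ties = "ordered")$y
  py <- stats::approx(path$s, path$points[, 2], xout = s_hat,
                      ties = "ordered")$y
  h <- max(3 * path$step, 1e-6)
  qx <- stats::approx(path$s, path$points[, 1],
                      xout = c(max(0, s_hat - h), min(smax, s_hat + h)),
                      ties = "ordered")$y
  qy <- stats::approx(path$s, path$points[, 2],
                      xout = c(max(0, s_hat - h), min(smax, s_hat + h)),
                      ties = "ordered")$y
  tv <- c(qx[2] - qx[1], qy[2] - qy[1])
  L <- sqrt(sum(tv^2))
  if (L < 1e-12) return(NULL)
  nv <- c(-tv[2], tv[1]) / L
  p <- c(px, py)
  reach <- 5 * (max(path$s) / 2 + 0.5)
  A <- if (raw && !is.null(path$wall_a_raw)) path$wall_a_raw else path$wall_a
  B <- if (raw && !is.null(path$wall_b_raw)) path$wall_b_raw else path$wall_b
  hits_a <- seg_poly_intersections(p - nv * reach, p + nv * reach, A)
  hits_b <- seg_poly_intersections(p - nv * reach, p + nv * reach, B)
  if (!nrow(hits_a) || !nrow(hits_b)) return(NULL)
  da <- sqrt(rowSums(sweep(hits_a, 2, p)^2))
  db <- sqrt(rowSums(sweep(hits_b, 2, p)^2))
  list(a = hits_a[which.min(da), ], b = hits_b[which.min(db), ])
}

# Continuous-breakpoint V fit: width ~ b1 + p * (sk - s)+ + r * (s - sk)+,
# least squares over the breakpoint sk. Unbiased for a kinked profile with
# unequal limb slopes, where argmin- or plateau-based estimates drift toward
# the shallow limb. Returns NULL when the fit is degenerate or not V-shaped.
vee_fit <- function(s, w) {
  n <- length(s)
  if (n < 9) return(NULL)
  sse <- function(sk) {
    X <- cbind(1, pmax(sk - s, 0), pmax(s - sk, 0))
    sum(stats::lm.fit(X, w)$residuals^2)
  }
  grid <- s[seq(3, n - 2)]
  vals <- vapply(grid, sse, 0)
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  sk <- if (hi > lo) stats::optimize(sse, c(lo, hi))$minimum else grid[k]
  co <- stats::lm.fit(cbind(1, pmax(sk - s, 0), pmax(s - sk, 0)),
                      w)$coefficients
  if (anyNA(co) || co[2] <= 0 || co[3] <= 0) return(NULL)
  list(s_hat = unname(sk), p = unname(co[2]), r = unname(co[3]))
}

# Wall-to-wall chord at a given arclength station of the medial path.
chord_at_station <- function(path, s_hat) {
  if (s_hat < min(path$s) || s_hat > max(path$s)) return(NULL)
  px <- stats::approx(path$s, path$points[, 1], xout = s_hat,
                      ties = "ordered")$y
  py <- stats::approx(path$s, path$points[, 2], xout = s_hat,
                      ties = "ordered")$y
  p <- c(px, py)
  a <- project_onto_polyline(rbind(p), path$wall_a)$point[1, ]
  b <- project_onto_polyline(rbind(p), path$wall_b)$point[1, ]
  if (segment_crosses_polyline(a, b, path$wall_a) ||
      segment_crosses_polyline(a, b, path$wall_b)) return(NULL)
  list(a = a, b = b)
}

#' Distance between constriction and foramen
#'
#' Perpendicular distance from the AC chord midpoint to the infinite line
#' through the AF chord -- the same trigonometric construction used for
#' file-tip distances, with the AC midpoint in the tip's role. Always
#' non-negative.
#'
#' @param ac,af `landmark`s from the same section.
#' @return Distance in mm.
#' @export
ac_af_distance <- function(ac, af) {
  d <- af$chord_b - af$chord_a
  L <- sqrt(sum(d^2))
  if (L < 1e-12)
    abort("degenerate AF chord", "apexmetry_geometry_error")
  abs((ac$midpoint[1] - af$chord_a[1]) * d[2] -
      (ac$midpoint[2] - af$chord_a[2]) * d[1]) / L
}
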