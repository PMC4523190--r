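# Signed file-tip distances to the apical landmarks and position
# classification.
#
# The distance D from the tip to a landmark chord is computed as the
# perpendicular distance to the infinite line through the chord. This equals
# the trigonometric construction D = b * sin(alpha), where b is the distance
# from the tip to the nearer chord endpoint and alpha the angle at that
# endpoint between the chord and the tip segment; both quantities are
# returned as diagnostics. The sign follows the convention that negative
# values mean the tip lies beyond (apical to) the landmark.

#' Signed distance from the file tip to a landmark chord
#'
#' @param tip Length-2 numeric, tip position (mm).
#' @param landmark A `landmark` (AC or AF).
#' @param apical_reference Length-2 numeric point known to lie strictly
#'   apical to the landmark chord; determines the negative side.
#' @return List: `distance` (signed mm; negative = tip beyond/apical to the
#'   landmark), `b` (mm, tip to nearest chord endpoint), `alpha` (radians,
#'   included angle at that endpoint). `abs(distance) == b * sin(alpha)`.
#' @export
signed_distance_to_landmark <- function(tip, landmark, apical_reference) {
  tip <- as.numeric(tip)
  ref <- as.numeric(apical_reference)
  c1 <- landmark$chord_a; c2 <- landmark$chord_b
  d <- c2 - c1
  L <- sqrt(sum(d^2))
  if (L < 1e-12)
    abort("degenerate (zero-length) landmark chord", "apexmetry_geometry_error")
  nvec <- c(-d[2], d[1]) / L                 # unit normal to the chord line
  h_tip <- sum((tip - c1) * nvec)            # signed offset of the tip
  h_ref <- sum((ref - c1) * nvec)            # signed offset of the apical side
  if (abs(h_ref) < 1e-12)
    abort("apical_reference lies on the landmark chord line; cannot orient",
          "apexmetry_geometry_error")
  # negative iff tip on the same (apical) side as the reference point
  distance <- if (sign(h_tip) == sign(h_ref)) -abs(h_tip) else abs(h_tip)

  # Trigonometric diagnostics: b and alpha at the nearer chord endpoint.
  b1 <- sqrt(sum((tip - c1)^2)); b2 <- sqrt(sum((tip - c2)^2))
  if (b1 <= b2) { anchor <- c1; other <- c2; b <- b1 } else {
    anchor <- c2; other <- c1; b <- b2 }
  if (b < 1e-15) {
    alpha <- 0
  } else {
    u <- (other - anchor) / L
    v <- (tip - anchor) / b
    alpha <- acos(pmin(1, pmax(-1, sum(u * v))))
  }
  list(distance = distance, b = b, alpha = alpha)
}

#' Classify the file-tip position relative to AC and AF
#'
#' Sign convention: negative distances mean the tip lies beyond (apical to)
#' the landmark. A tip exactly at a landmark chord (distance 0) counts as
#' having reached, but not passed, the landmark, so both boundary cases
#' classify as `BETWEEN_AC_AF`.
#'
#' @param dist_tip_ac,dist_tip_af Signed distances (mm).
#' @return One of `"SHORT_OF_AC"`, `"BETWEEN_AC_AF"`, `"BEYOND_AF"`.
#' @export
classify_tip <- function(dist_tip_ac, dist_tip_af) {
  if (!is.finite(dist_tip_ac) || !is.finite(dist_tip_af))
    abort("tip distances must be finite", "apexmetry_validation_error")
  if (dist_tip_ac > 0 && dist_tip_af < 0)
    abort(paste("inconsistent distance pair: tip short of AC yet beyond AF",
                "is geometrically impossible when AC is coronal to AF"),
          "apexmetry_validation_error")
  if (dist_tip_ac > 0) return("SHORT_OF_AC")
  if (dist_tip_af < 0) return("BEYOND_AF")
  "BETWEEN_AC_AF"
}

#' Full tip measurement for a section
#'
#' @param section The [annotated_section()].
#' @param ac,af Detected `landmark`s.
#' @param path The [build_medial_path()] used for detection; its apical end
#'   anchors the sign convention.
#' @return List of class `tip_measurement`: signed `dist_tip_ac`,
#'   `dist_tip_af` (mm), diagnostics `b_ac`, `b_af`, `alpha_ac`, `alpha_af`,
#'   and `position_class`.
#' @export
measure_tip <- function(section, ac, af, path) {
  tip <- section_mm(section)$file_tip
  # The path starts ON the AF chord, so extrapolate one step outward along
  # the terminal tangent to obtain a point strictly apical to both chords.
  p0 <- path$points[1, ]
  p1 <- path$points[2, ]
  ref <- p0 - (p1 - p0)
  mac <- signed_distance_to_landmark(tip, ac, ref)
  maf <- signed_distance_to_landmark(tip, af, ref)
  structure(list(
    dist_tip_ac = mac$distance, dist_tip_af = maf$distance,
    b_ac = mac$b, alpha_ac = mac$alpha,
    b_af = maf$b, alpha_af = maf$alpha,
    position_class = classify_tip(mac$distance, maf$distance)
  ), class = "tip_measurement")
}

#' @export
print.tip_measurement <- function(x, ...) {
  cat(sprintf("tip_measurement: D_AC = %+.4f mm, D_AF = %+.4f mm -> %s\n",
              x$dist_tip_ac, x$dist_tip_af, x$position_class))
  invisible(x)
}
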