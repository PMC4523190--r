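# End-to-end measurement pipeline: annotated section -> medial path -> width
# profile -> landmarks -> signed tip distances -> one measurement record.

#' Construct a landmark chord directly
#'
#' Mostly useful for computing tip distances against externally defined
#' chords (e.g. ground truth) without running detection.
#'
#' @param kind `"AC"` or `"AF"`.
#' @param chord_a,chord_b Chord endpoints (mm).
#' @param s Axial station from the apical terminus, mm.
#' @return A `landmark`.
#' @export
landmark <- function(kind = c("AC", "AF"), chord_a, chord_b, s = 0) {
  kind <- match.arg(kind)
  new_landmark(kind, chord_a, chord_b, s)
}

#' Measure one annotated section
#'
#' Runs the full pipeline and returns all detected quantities.
#'
#' @param section An [annotated_section()].
#' @param step Medial sampling step, mm (default 0.01).
#' @param ac_window Apical search window for the constriction, mm
#'   (default 3).
#' @param smooth_window Wall moving-average window for path construction
#'   (default 3); the final landmark chords are still measured against the
#'   unsmoothed annotation.
#' @return List of class `section_measurement`: the `ac` and `af` landmarks,
#'   `ac_af_dist` (mm), the `tip` measurement, and `record`, a one-row data
#'   frame with the columns of [save_measurements()].
#' @export
measure_section <- function(section, step = 0.01, ac_window = 3.0,
                            smooth_window = 3) {
  path <- build_medial_path(section, step = step,
                            smooth_window = smooth_window)
  profile <- compute_width_profile(section, path)
  af <- detect_af(section, profile)
  ac <- detect_ac(profile, af, window = ac_window)
  acaf <- ac_af_distance(ac, af)
  tip <- measure_tip(section, ac, af, path)
  record <- data.frame(
    specimen_id = section$specimen_id,
    group = section$group,
    d_ac_mm = ac$diameter,
    d_af_mm = af$diameter,
    dist_tip_ac_mm = tip$dist_tip_ac,
    dist_tip_af_mm = tip$dist_tip_af,
    position_class = tip$position_class,
    ac_af_dist_mm = acaf,
    stringsAsFactors = FALSE)
  structure(list(ac = ac, af = af, ac_af_dist = acaf, tip = tip,
                 profile = profile, record = record),
            class = "section_measurement")
}

#' @export
print.section_measurement <- function(x, ...) {
  cat(sprintf(
    "section_measurement: AC %.3f mm, AF %.3f mm, AC-AF %.3f mm, %s\n",
    x$ac$diameter, x$af$diameter, x$ac_af_dist, x$tip$position_class))
  invisible(x)
}

#' Measure a batch of annotation bundles
#'
#' @param sidecars Character vector of sidecar JSON paths.
#' @param ... Passed to [measure_section()].
#' @return Data frame with one measurement row per bundle.
#' @export
measure_bundles <- function(sidecars, ...) {
  rows <- lapply(sidecars, function(p) {
    measure_section(load_annotation(p), ...)$record
  })
  do.call(rbind, rows)
}
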