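# Reading, validating and writing per-specimen annotation bundles.
#
# An annotation bundle is a JSON sidecar holding the specimen id, the group
# label, the micrometre-per-pixel calibration, and either explicit wall/tip
# polyline coordinates or a path to a label image (PNG) in which wall A
# pixels carry label 1, wall B pixels label 2 and the file-tip pixel label 3.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "apexmetry_error", "error")))
}

GROUPS <- c("RPM", "EPM", "EPA")
POSITION_CLASSES <- c("SHORT_OF_AC", "BETWEEN_AC_AF", "BEYOND_AF")

#' Micrometre-per-pixel scale calibration
#'
#' @param microns_per_pixel Positive, finite scale in micrometres per pixel.
#' @return An object of class `scale_calibration`.
#' @export
scale_calibration <- function(microns_per_pixel) {
  if (is.null(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.numeric(microns_per_pixel) || !is.finite(microns_per_pixel) ||
      microns_per_pixel <= 0)
    abort("calibration requires a single positive finite microns_per_pixel",
          "apexmetry_calibration_error")
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "scale_calibration")
}

#' Millimetres per pixel implied by a calibration
#' @param calibration A `scale_calibration`.
#' @return Scale in mm per pixel.
#' @export
mm_per_pixel <- function(calibration) calibration$microns_per_pixel / 1000

#' Construct a validated annotated cross-section
#'
#' The two canal walls are ordered polylines in image pixel coordinates
#' (origin top-left, 0-based, y downward). On construction both walls are
#' normalised to apical-terminus-first vertex order: by default the apical
#' end is taken to be the pair of polyline ends where the two walls approach
#' each other most closely; `apical_end = "first"` or `"last"` overrides.
#'
#' @param specimen_id Specimen identifier string.
#' @param calibration A `scale_calibration` (or a bare microns-per-pixel
#'   number).
#' @param wall_a,wall_b n x 2 matrices of wall vertices (pixel coordinates),
#'   each with at least two vertices, non-self-intersecting and mutually
#'   non-crossing.
#' @param file_tip Length-2 numeric, the annotated file-tip point (pixels).
#' @param group Optional group label, one of `"RPM"`, `"EPM"`, `"EPA"`.
#' @param apical_end `"auto"` (default), `"first"` or `"last"`.
#' @return An object of class `annotated_section`.
#' @export
annotated_section <- function(specimen_id, calibration, wall_a, wall_b,
                              file_tip, group = NA_character_,
                              apical_end = c("auto", "first", "last")) {
  apical_end <- match.arg(apical_end)
  if (is.numeric(calibration)) calibration <- scale_calibration(calibration)
  if (!inherits(calibration, "scale_calibration"))
    abort("calibration must be a scale_calibration",
          "apexmetry_calibration_error")
  wall_a <- poly_matrix(wall_a, "wall_a")
  wall_b <- poly_matrix(wall_b, "wall_b")
  if (nrow(wall_a) < 2 || nrow(wall_b) < 2)
    abort("each wall polyline needs at least 2 vertices",
          "apexmetry_geometry_error")
  file_tip <- as.numeric(file_tip)
  if (length(file_tip) != 2 || any(!is.finite(file_tip)))
    abort("file_tip must be a finite (x, y) point", "apexmetry_validation_error")
  if (is.null(group) || length(group) != 1) group <- NA_character_
  group <- as.character(group)
  if (!is.na(group) && !group %in% GROUPS)
    abort(sprintf("unknown group label '%s' (expected RPM, EPM or EPA)", group),
          "apexmetry_validation_error")
  if (polyline_self_intersects(wall_a) || polyline_self_intersects(wall_b))
    abort("wall polyline self-intersects", "apexmetry_geometry_error")
  if (polylines_cross(wall_a, wall_b))
    abort("wall polylines cross each other", "apexmetry_geometry_error")

  # Align wall_b's vertex order with wall_a's so that corresponding ends pair
  # up, then orient both apical-first.
  na <- nrow(wall_a); nb <- nrow(wall_b)
  d_same <- sum((wall_a[1, ] - wall_b[1, ])^2) +
    sum((wall_a[na, ] - wall_b[nb, ])^2)
  d_flip <- sum((wall_a[1, ] - wall_b[nb, ])^2) +
    sum((wall_a[na, ] - wall_b[1, ])^2)
  if (d_flip < d_same) wall_b <- wall_b[nb:1, , drop = FALSE]

  reversed <- FALSE
  if (apical_end == "last") {
    reversed <- TRUE
  } else if (apical_end == "auto") {
    gap_first <- sqrt(sum((wall_a[1, ] - wall_b[1, ])^2))
    gap_last <- sqrt(sum((wall_a[na, ] - wall_b[nrow(wall_b), ])^2))
    reversed <- gap_last < gap_first
  }
  if (reversed) {
    wall_a <- wall_a[na:1, , drop = FALSE]
    wall_b <- wall_b[nrow(wall_b):1, , drop = FALSE]
    message("annotated_section: wall ordering normalised to apical-first ",
            "(input was coronal-first)")
  }

  structure(list(
    specimen_id = as.character(specimen_id),
    calibration = calibration,
    wall_a = wall_a,
    wall_b = wall_b,
    file_tip = file_tip,
    group = if (is.na(group)) NA_character_ else group
  ), class = "annotated_section")
}

#' @export
print.annotated_section <- function(x, ...) {
  cat(sprintf("annotated_section '%s'%s: walls %d/%d vertices, %.3f um/px\n",
              x$specimen_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$wall_a), nrow(x$wall_b),
              x$calibration$microns_per_pixel))
  invisible(x)
}

#' Wall and tip coordinates of a section in millimetres
#' @param section An `annotated_section`.
#' @return List with `wall_a`, `wall_b` (matrices) and `file_tip`, in mm.
#' @export
section_mm <- function(section) {
  k <- mm_per_pixel(section$calibration)
  list(wall_a = section$wall_a * k,
       wall_b = section$wall_b * k,
       file_tip = section$file_tip * k)
}

# ---- label-image vectorisation ---------------------------------------------

# Trace the pixels carrying one label into an ordered 8-connected chain.
# Hand-marked (or rasterised) strokes carry occasional spurs and small
# loops, so the chain is taken as the graph diameter of the pixel adjacency
# graph: BFS from an arbitrary pixel finds one chain end, BFS from there
# finds the other, and the connecting shortest path is the stroke.
# coords: n x 2 (x, y), 0-based.
trace_pixel_chain <- function(coords, label) {
  n <- nrow(coords)
  if (n < 2)
    abort(sprintf("label %d has fewer than 2 pixels", label),
          "apexmetry_geometry_error")
  key <- coords[, 1] * 65536 + coords[, 2]
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  nbr <- matrix(NA_integer_, n, 8)
  for (o in 1:8)
    nbr[, o] <- match(key + offs[o, 1] * 65536 + offs[o, 2], key)

  bfs <- function(start) {
    parent <- integer(n)
    dist <- rep(NA_integer_, n)
    dist[start] <- 0L
    queue <- integer(n)
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (v in nbr[cur, ]) {
        if (!is.na(v) && is.na(dist[v])) {
          dist[v] <- dist[cur] + 1L
          parent[v] <- cur
          tail <- tail + 1L
          queue[tail] <- v
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- integer(0)
  cur <- v
  while (cur != 0L && cur != u) {
    path <- c(path, cur)
    cur <- b2$parent[cur]
  }
  path <- c(path, u)
  n_un <- sum(is.na(b1$dist))
  if (n_un > 0)
    warning(sprintf("label %d: %d disconnected pixel(s) ignored", label, n_un))
  # shortest-path tracing legitimately shortcuts staircase wiggles, so a
  # sizeable fraction of off-chain pixels is normal; warn only when the
  # stroke looks genuinely fragmented
  dropped <- n - n_un - length(path)
  if (dropped > 0.25 * n)
    warning(sprintf("label %d: %d off-chain pixel(s) (spurs/loops) ignored",
                    label, dropped))
  coords[path, , drop = FALSE]
}

# Vectorise a label mask into the two wall polylines and the tip point.
# Chains are kept at raw pixel-centre resolution (simplification tolerance
# well below one pixel) so no subpixel position information is discarded;
# denoising happens later, during medial-path construction.
vectorize_mask <- function(mask, simplify_tol = 0.1, smooth_window = 1) {
  lab <- round(mask * 255)
  get_xy <- function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    # row -> y, col -> x; 0-based pixel coordinates
    cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  }
  wa <- get_xy(1); wb <- get_xy(2); tp <- get_xy(3)
  if (nrow(tp) != 1)
    abort(sprintf("expected exactly one tip pixel (label 3), found %d",
                  nrow(tp)), "apexmetry_validation_error")
  chain <- function(xy, l) {
    v <- trace_pixel_chain(xy, l)
    v <- smooth_polyline(v, smooth_window)
    rdp_simplify(v, simplify_tol)
  }
  list(wall_a = chain(wa, 1), wall_b = chain(wb, 2),
       file_tip = as.numeric(tp[1, ]))
}

# ---- sidecar I/O ------------------------------------------------------------

#' Load an annotation bundle
#'
#' Reads a JSON sidecar and returns a validated [annotated_section()]. The
#' sidecar must carry `specimen_id`, `microns_per_pixel`, optionally `group`
#' and `apical_end`, and either `polylines` (lists `wall_a`, `wall_b`, `tip`
#' of pixel coordinates) or `mask` (path to a grayscale PNG label image,
#' relative to the sidecar, with wall A = 1, wall B = 2, tip = 3).
#'
#' @param path Path to the sidecar JSON.
#' @return An `annotated_section`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path))
    abort(sprintf("sidecar not found: %s", path), "apexmetry_io_error")
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(sc$microns_per_pixel))
    abort(sprintf("sidecar %s lacks 'microns_per_pixel' calibration", path),
          "apexmetry_calibration_error")
  cal <- scale_calibration(sc$microns_per_pixel)
  apical_end <- if (is.null(sc$apical_end)) "auto" else sc$apical_end
  group <- if (is.null(sc$group)) NA_character_ else as.character(sc$group)
  sid <- if (is.null(sc$specimen_id)) basename(path) else sc$specimen_id

  if (!is.null(sc$polylines)) {
    pl <- sc$polylines
    wall_a <- poly_matrix(pl$wall_a, "wall_a")
    wall_b <- poly_matrix(pl$wall_b, "wall_b")
    tip <- as.numeric(unlist(pl$tip))
  } else if (!is.null(sc$mask)) {
    mask_path <- file.path(dirname(path), sc$mask)
    if (!file.exists(mask_path))
      abort(sprintf("label image not found: %s", mask_path),
            "apexmetry_io_error")
    img <- png::readPNG(mask_path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    v <- vectorize_mask(img)
    wall_a <- v$wall_a; wall_b <- v$wall_b; tip <- v$file_tip
  } else {
    abort(sprintf("sidecar %s has neither 'polylines' nor 'mask'", path),
          "apexmetry_validation_error")
  }
  annotated_section(sid, cal, wall_a, wall_b, tip, group = group,
                    apical_end = apical_end)
}

#' Write an annotation bundle as a polyline sidecar
#'
#' Inverse of [load_annotation()] for the polyline representation; a
#' save/load round trip reproduces coordinates to better than 1e-6 px and
#' the calibration exactly.
#'
#' @param section An `annotated_section`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(section, path) {
  obj <- list(
    specimen_id = section$specimen_id,
    microns_per_pixel = section$calibration$microns_per_pixel,
    apical_end = "first",
    polylines = list(
      wall_a = unname(section$wall_a),
      wall_b = unname(section$wall_b),
      tip = section$file_tip
    )
  )
  if (!is.na(section$group)) obj$group <- section$group
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- measurement tables -----------------------------------------------------

MEASUREMENT_COLUMNS <- c("specimen_id", "group", "d_ac_mm", "d_af_mm",
                         "dist_tip_ac_mm", "dist_tip_af_mm",
                         "position_class", "ac_af_dist_mm")

#' Write per-specimen measurements to CSV
#'
#' Columns, in fixed order: `specimen_id`, `group`, `d_ac_mm`, `d_af_mm`,
#' `dist_tip_ac_mm`, `dist_tip_af_mm`, `position_class`, `ac_af_dist_mm`.
#' Rows are sorted by `specimen_id`. All lengths in millimetres.
#'
#' @param records Data frame of measurement rows (see [measure_section()]),
#'   or an empty list/data frame for a header-only file.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_measurements <- function(records, path) {
  if (is.list(records) && !is.data.frame(records) && length(records))
    records <- do.call(rbind, records)
  if (length(records) == 0 || (is.data.frame(records) && nrow(records) == 0)) {
    records <- as.data.frame(
      setNames(rep(list(character(0)), length(MEASUREMENT_COLUMNS)),
               MEASUREMENT_COLUMNS))
  }
  missing <- setdiff(MEASUREMENT_COLUMNS, names(records))
  if (length(missing))
    abort(paste("measurement records lack columns:",
                paste(missing, collapse = ", ")),
          "apexmetry_validation_error")
  records <- records[order(records$specimen_id), MEASUREMENT_COLUMNS,
                     drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    abort(sprintf("cannot write measurements to %s", path),
          "apexmetry_io_error")
  invisible(path)
}

#' Read a measurement table written by [save_measurements()]
#' @param path CSV path.
#' @return Data frame with the documented columns.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    abort(sprintf("measurement table not found: %s", path),
          "apexmetry_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(specimen_id = "character"))
  df
}
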