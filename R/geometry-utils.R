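# Internal 2-D geometry primitives shared by the medial-path, landmark and
# synthetic-apex code. Points are length-2 numeric vectors c(x, y); polylines
# are n x 2 matrices of ordered vertices.

as_poly <- function(p) {
  m <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = is.list(p))
  if (!is.matrix(p) && !is.list(p)) m <- matrix(as.numeric(p), ncol = 2)
  m
}

poly_matrix <- function(p, what = "polyline") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, lapply(p, as.numeric))
  if (!is.matrix(p) || ncol(p) != 2 || !is.numeric(p))
    stop(sprintf("%s must be an n x 2 numeric matrix", what), call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)))
    stop(sprintf("%s contains non-finite coordinates", what), call. = FALSE)
  unname(p)
}

#' @noRd
cum_arclength <- function(v) {
  d <- sqrt(rowSums(diff(v)^2))
  c(0, cumsum(d))
}

# Project a set of points P (n x 2) onto a polyline V (m x 2).
# Returns nearest points, distances, and arclength position of the foot.
project_onto_polyline <- function(P, V) {
  P <- poly_matrix(P, "points")
  V <- poly_matrix(V, "polyline")
  n <- nrow(P)
  m <- nrow(V)
  if (m < 2) stop("polyline needs >= 2 vertices", call. = FALSE)
  s <- cum_arclength(V)
  best_d2 <- rep(Inf, n)
  best_pt <- matrix(NA_real_, n, 2)
  best_s <- rep(NA_real_, n)
  for (i in seq_len(m - 1)) {
    a <- V[i, ]; b <- V[i + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    if (L2 == 0) {
      t <- rep(0, n)
    } else {
      t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / L2
      t <- pmin(1, pmax(0, t))
    }
    qx <- a[1] + t * ab[1]
    qy <- a[2] + t * ab[2]
    d2 <- (P[, 1] - qx)^2 + (P[, 2] - qy)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_pt[upd, 1] <- qx[upd]
      best_pt[upd, 2] <- qy[upd]
      best_s[upd] <- s[i] + t[upd] * sqrt(L2)
    }
  }
  list(point = best_pt, dist = sqrt(best_d2), s = best_s)
}

# Strict segment-segment intersection test, vectorised over rows of the
# (a1,a2) segments against one (b1,b2) segment. Touching at endpoints within
# `eps` does not count as crossing.
segments_cross <- function(a1, a2, b1, b2, eps = 1e-12) {
  d1x <- a2[, 1] - a1[, 1]; d1y <- a2[, 2] - a1[, 2]
  d2x <- b2[1] - b1[1]; d2y <- b2[2] - b1[2]
  denom <- d1x * d2y - d1y * d2x
  ex <- b1[1] - a1[, 1]; ey <- b1[2] - a1[, 2]
  t <- (ex * d2y - ey * d2x) / denom
  u <- (ex * d1y - ey * d1x) / denom
  ok <- abs(denom) > eps
  ok & t > eps & t < 1 - eps & u > eps & u < 1 - eps
}

# Does segment p-q cross polyline V anywhere in the open interior?
segment_crosses_polyline <- function(p, q, V, eps = 1e-12) {
  V <- poly_matrix(V)
  m <- nrow(V)
  if (m < 2) return(FALSE)
  a1 <- V[-m, , drop = FALSE]
  a2 <- V[-1, , drop = FALSE]
  any(segments_cross(a1, a2, p, q, eps))
}

# Self-intersection check over non-adjacent segment pairs.
polyline_self_intersects <- function(V, eps = 1e-12) {
  V <- poly_matrix(V)
  m <- nrow(V) - 1
  if (m < 3) return(FALSE)
  for (j in seq_len(m - 2)) {
    idx <- (j + 2):m
    hit <- segments_cross(V[idx, , drop = FALSE], V[idx + 1, , drop = FALSE],
                          V[j, ], V[j + 1, ], eps)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

polylines_cross <- function(A, B, eps = 1e-12) {
  A <- poly_matrix(A); B <- poly_matrix(B)
  mB <- nrow(B) - 1
  a1 <- A[-nrow(A), , drop = FALSE]
  a2 <- A[-1, , drop = FALSE]
  for (j in seq_len(mB)) {
    if (any(segments_cross(a1, a2, B[j, ], B[j + 1, ], eps))) return(TRUE)
  }
  FALSE
}

# Ramer-Douglas-Peucker simplification, iterative.
rdp_simplify <- function(V, tol) {
  V <- poly_matrix(V)
  n <- nrow(V)
  if (n <= 2 || tol <= 0) return(V)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- V[i, ]; b <- V[j, ]
    ab <- b - a
    L <- sqrt(sum(ab^2))
    idx <- (i + 1):(j - 1)
    if (L == 0) {
      d <- sqrt((V[idx, 1] - a[1])^2 + (V[idx, 2] - a[2])^2)
    } else {
      d <- abs((V[idx, 1] - a[1]) * ab[2] - (V[idx, 2] - a[2]) * ab[1]) / L
    }
    k <- which.max(d)
    if (d[k] > tol) {
      mid <- idx[k]
      keep[mid] <- TRUE
      stack[[length(stack) + 1]] <- c(i, mid)
      stack[[length(stack) + 1]] <- c(mid, j)
    }
  }
  V[keep, , drop = FALSE]
}

# Centered moving-average smoothing of polyline vertices; endpoints fixed.
smooth_polyline <- function(V, window) {
  V <- poly_matrix(V)
  n <- nrow(V)
  if (window <= 1 || n < 3) return(V)
  half <- floor(window / 2)
  out <- V
  for (i in 2:(n - 1)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(V[lo:hi, , drop = FALSE])
  }
  out
}

# Resample a polyline at (approximately) uniform arclength spacing `step`,
# keeping the first and last vertices.
resample_polyline <- function(V, step) {
  V <- poly_matrix(V)
  s <- cum_arclength(V)
  total <- s[length(s)]
  if (total == 0) stop("degenerate polyline of zero length", call. = FALSE)
  ns <- max(2L, ceiling(total / step) + 1L)
  si <- seq(0, total, length.out = ns)
  x <- stats::approx(s, V[, 1], xout = si, ties = "ordered")$y
  y <- stats::approx(s, V[, 2], xout = si, ties = "ordered")$y
  list(points = cbind(x, y), s = si)
}

# All intersection points of segment p-q with polyline V, as a matrix of
# points (0 rows when none).
seg_poly_intersections <- function(p, q, V, eps = 1e-12) {
  V <- poly_matrix(V)
  m <- nrow(V)
  if (m < 2) return(matrix(numeric(0), 0, 2))
  a1 <- V[-m, , drop = FALSE]; a2 <- V[-1, , drop = FALSE]
  d1x <- a2[, 1] - a1[, 1]; d1y <- a2[, 2] - a1[, 2]
  d2x <- q[1] - p[1]; d2y <- q[2] - p[2]
  denom <- d1x * d2y - d1y * d2x
  ex <- p[1] - a1[, 1]; ey <- p[2] - a1[, 2]
  t <- (ex * d2y - ey * d2x) / denom      # along wall segment
  u <- (ex * d1y - ey * d1x) / denom      # along p-q
  ok <- abs(denom) > eps & t >= -1e-9 & t <= 1 + 1e-9 & u >= -1e-9 &
    u <= 1 + 1e-9
  if (!any(ok)) return(matrix(numeric(0), 0, 2))
  cbind(p[1] + u[ok] * d2x, p[2] + u[ok] * d2y)
}

# Extract the sub-polyline between arclength stations [s_lo, s_hi],
# interpolating the cut points.
clip_polyline <- function(V, s_lo, s_hi) {
  V <- poly_matrix(V)
  s <- cum_arclength(V)
  total <- s[length(s)]
  s_lo <- max(0, s_lo); s_hi <- min(total, s_hi)
  if (s_hi <= s_lo) return(V[which.min(abs(s - s_lo)), , drop = FALSE])
  inner <- which(s > s_lo & s < s_hi)
  xs <- c(s_lo, s[inner], s_hi)
  x <- stats::approx(s, V[, 1], xout = xs, ties = "ordered")$y
  y <- stats::approx(s, V[, 2], xout = xs, ties = "ordered")$y
  cbind(x, y)
}

rotate_points <- function(P, theta, center = c(0, 0)) {
  P <- poly_matrix(P, "points")
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(sweep(P, 2, center) %*% t(R), 2, center, `+`)
}
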