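# Silhouette construction: a dense skeletal polyline is offset perpendicular
# to its local tangent by half the locally interpolated width, and closed
# with rounded end caps. Polygons are open vertex matrices (last row does not
# repeat the first), oriented counterclockwise.

#' Signed polygon area (shoelace)
#' @param poly Vertex matrix (columns x, y), not closed.
#' @return Signed area; positive for counterclockwise orientation.
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon perimeter
#' @param poly Vertex matrix (columns x, y), not closed.
#' @return Total boundary length.
#' @export
poly_perimeter <- function(poly) {
  cl <- rbind(poly, poly[1, ])
  sum(sqrt(rowSums(diff(cl)^2)))
}

ensure_ccw <- function(poly) if (poly_area(poly) < 0) poly[nrow(poly):1, ] else poly

# TRUE where points (n x 2) fall inside the polygon.
points_in_poly <- function(pts, poly) {
  mgcv::in.out(rbind(as.matrix(poly), poly[1, , drop = FALSE]), as.matrix(pts))
}

# Quick self-intersection test between non-adjacent edges (vectorized).
has_self_intersection <- function(poly) {
  n <- nrow(poly)
  cl <- rbind(poly, poly[1, ])
  p1 <- cl[-(n + 1), , drop = FALSE]; d <- diff(cl)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(FALSE)
  rx <- d[i, 1]; ry <- d[i, 2]; sx <- d[j, 1]; sy <- d[j, 2]
  qpx <- p1[j, 1] - p1[i, 1]; qpy <- p1[j, 2] - p1[i, 2]
  den <- rx * sy - ry * sx
  ok <- abs(den) > 1e-14
  t <- (qpx * sy - qpy * sx) / den
  u <- (qpx * ry - qpy * rx) / den
  any(ok & t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12)
}

# Resolve self-intersections by a union-with-itself (nonzero fill) and keep
# the largest ring; a no-op for simple polygons.
clean_polygon <- function(poly) {
  if (!has_self_intersection(poly)) return(ensure_ccw(poly))
  rings <- polyclip::polysimplify(list(x = poly[, 1], y = poly[, 2]),
                                  filltype = "nonzero", eps = 1e-12)
  areas <- vapply(rings, function(r) abs(poly_area(cbind(r$x, r$y))), 0)
  r <- rings[[which.max(areas)]]
  ensure_ccw(cbind(x = r$x, y = r$y))
}

# Semicircular cap around endpoint p of radius r, from angle a1 to a2
# (interior points only; endpoints belong to the side chains).
cap_arc <- function(p, r, a1, a2, n = 16L) {
  if (r < 1e-12) return(NULL)
  ang <- seq(a1, a2, length.out = n + 1L)[-c(1L, n + 1L)]
  cbind(x = p[1] + r * cos(ang), y = p[2] + r * sin(ang))
}

#' Build a silhouette polygon around a smoothed skeletal polyline
#'
#' Each polyline vertex is offset perpendicular to the local tangent by half
#' the locally interpolated width; the two offset chains are closed with
#' rounded end caps. The local width is
#' `base_width * rel_width * profile(s) * (1 + (taper - 1) * s)` where
#' `profile` interpolates the per-joint width factors linearly in arc length
#' and `s` is the arc-length fraction from root to tip.
#'
#' @param polyline Dense polyline matrix from [smooth_path()] (or any
#'   n x 2 matrix with n >= 2).
#' @param params A [growth_params()] object supplying `width_profile`,
#'   `taper` and `rel_width`.
#' @param base_width Parent reference width that `rel_width` scales.
#' @return Counterclockwise simple polygon (vertex matrix), cleaned of any
#'   micro self-intersections. Errors if cleanup leaves multiple components.
#' @export
#' @examples
#' pl <- cbind(x = c(0, 0), y = c(0, 1))
#' poly <- build_silhouette(pl, growth_params(n_joints = 2, width_profile = 1,
#'                                            taper = 1, rel_width = 1),
#'                          base_width = 0.2)
#' abs(poly_area(poly) - (0.2 * 1 + pi * 0.1^2)) < 0.01
build_silhouette <- function(polyline, params, base_width = 1) {
  pts <- as.matrix(polyline)
  n <- nrow(pts)
  if (n < 2L) stop("polyline needs at least 2 vertices", call. = FALSE)
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  s <- cs / cs[length(cs)]
  prof_t <- seq(0, 1, length.out = length(params$width_profile))
  prof <- stats::approx(prof_t, params$width_profile, xout = s)$y
  halfw <- base_width * params$rel_width * prof * (1 + (params$taper - 1) * s) / 2

  # unit tangents: central differences in the interior, one-sided at the ends
  tx <- c(pts[2, 1] - pts[1, 1],
          pts[-(1:2), 1] - pts[1:(n - 2), 1],
          pts[n, 1] - pts[n - 1, 1])
  ty <- c(pts[2, 2] - pts[1, 2],
          pts[-(1:2), 2] - pts[1:(n - 2), 2],
          pts[n, 2] - pts[n - 1, 2])
  nrm <- sqrt(tx^2 + ty^2)
  tx <- tx / nrm; ty <- ty / nrm
  # left normal = tangent rotated +90 degrees
  lx <- -ty; ly <- tx

  right <- cbind(x = pts[, 1] - lx * halfw, y = pts[, 2] - ly * halfw)
  left  <- cbind(x = pts[, 1] + lx * halfw, y = pts[, 2] + ly * halfw)

  a_tip  <- atan2(ty[n], tx[n])
  a_root <- atan2(-ty[1], -tx[1])
  tip_cap  <- cap_arc(pts[n, ], halfw[n], a_tip - pi / 2, a_tip + pi / 2)
  root_cap <- cap_arc(pts[1, ], halfw[1], a_root - pi / 2, a_root + pi / 2)

  poly <- rbind(right, tip_cap, left[n:1, , drop = FALSE], root_cap)
  poly <- poly[!duplicated(round(poly, 12)), , drop = FALSE]
  clean_polygon(poly)
}

#' Construct the main body
#'
#' A simple elongated blob in upright orientation: a straight vertical
#' 3-joint skeleton with a mild mid-bulge width profile, rendered through the
#' same silhouette machinery as the limbs. Canvas units are normalized so the
#' skeleton length (body height) is 1.
#'
#' @param width Maximum body width in canvas units (height = 1); must be < 1
#'   so the body stays vertically elongated.
#' @param width_profile Length-3 per-joint width factors (bottom, middle, top).
#' @param samples_per_segment Boundary sampling density.
#' @return Object of class `main_body` with fields `silhouette` (CCW polygon,
#'   vertex 1 at the topmost boundary point), `skeleton` (dense polyline),
#'   `cumlen` (cumulative boundary arc length), `perimeter`, `width`,
#'   `height`, and `axis_x` (the vertical symmetry axis).
#' @export
main_body <- function(width = 0.34,
                      width_profile = c(0.82, 1, 0.72),
                      samples_per_segment = 24L) {
  if (width >= 1) stop("body must be taller than wide (`width` < 1)", call. = FALSE)
  sk <- skeletal_path(cbind(x = c(0, 0, 0), y = c(0, 0.5, 1)))
  dense <- smooth_path(sk, samples_per_segment)
  params <- growth_params(n_joints = 3L, width_profile = width_profile,
                          taper = 1, rel_width = 1, rel_length = 1)
  poly <- build_silhouette(dense, params, base_width = width)
  poly <- ensure_ccw(poly)
  # fix the perimeter origin at the topmost boundary point
  top <- which.max(poly[, 2] - abs(poly[, 1]) * 1e-9)
  poly <- poly[c(top:nrow(poly), seq_len(top - 1L)), , drop = FALSE]
  cl <- rbind(poly, poly[1, ])
  cumlen <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  structure(
    list(silhouette = poly,
         skeleton = dense,
         cumlen = unname(cumlen),
         perimeter = unname(cumlen[length(cumlen)]),
         width = width,
         width_profile = width_profile,
         height = 1,
         axis_x = 0),
    class = "main_body")
}

#' @export
print.main_body <- function(x, ...) {
  cat("<main_body> height 1, width ", x$width, ", perimeter ",
      format(x$perimeter, digits = 4), ", ",
      nrow(x$silhouette), " boundary vertices\n", sep = "")
  invisible(x)
}

#' Point and tangent on the main-body perimeter
#'
#' The perimeter is parameterized by arc length, with origin at the topmost
#' boundary point and counterclockwise orientation (so `t` in (0, 0.5) covers
#' the left flank and (0.5, 1) the right flank); `t = 0` and `t = 1` are the
#' same point.
#'
#' @param body A [main_body()] object.
#' @param t Arc-length fraction(s) in `[0, 1]`.
#' @return For scalar `t`, a list with `point`, `tangent` (unit, along
#'   increasing `t`) and `outward` (unit outward normal). For vector `t`, a
#'   list of such lists.
#' @export
perimeter_point <- function(body, t) {
  stopifnot(inherits(body, "main_body"))
  one <- function(tt) {
    tt <- tt %% 1
    s <- tt * body$perimeter
    i <- findInterval(s, body$cumlen, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(body$silhouette))
    cl <- rbind(body$silhouette, body$silhouette[1, ])
    d <- cl[i + 1L, ] - cl[i, ]
    len <- sqrt(sum(d^2))
    f <- (s - body$cumlen[i]) / len
    tg <- d / len
    list(point = cl[i, ] + f * d,
         tangent = tg,
         outward = c(tg[2], -tg[1]))  # right of travel for a CCW boundary
  }
  if (length(t) == 1L) one(t) else lapply(t, one)
}
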