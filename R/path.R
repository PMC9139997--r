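# Skeletal paths: ordered 2-D joints plus derived segment lengths and
# signed turning angles. All angles are in degrees, coordinates are
# continuous Cartesian with y pointing up; the main body height defines
# the unit of length.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Growth parameters for a skeletal part
#'
#' Bundles the tunable parameters of the stochastic growth process: the
#' turning-angle range, the number of joints, the segment-length range, the
#' per-joint width profile, tapering, and the part's width and length relative
#' to its parent.
#'
#' @param angle_range_deg Symmetric half-range (degrees) of the turning-angle
#'   deviation between consecutive segments. With `angle_min_deg = 0` each
#'   turning angle is drawn uniformly in `[-angle_range_deg, angle_range_deg]`.
#' @param n_joints Integer number of skeletal joints (at least 2).
#' @param seg_length_range Length-2 numeric, min/max distance between
#'   consecutive joints in canvas units (main-body height = 1).
#' @param width_profile Numeric vector of per-joint width factors
#'   (dimensionless); values between joints are interpolated linearly along
#'   arc length. A single value is recycled to all joints.
#' @param taper Terminal-width fraction in `[0, 1]`: the local width is ramped
#'   linearly from 1 at the root to `taper` at the tip. `taper = 0` gives a
#'   pointed tip.
#' @param rel_width Overall width relative to the parent part (dimensionless).
#' @param rel_length Overall length relative to the parent part: the summed
#'   segment length of the child is `rel_length` times the parent's.
#' @param angle_min_deg Lower bound on the *magnitude* of turning angles.
#'   When positive, turning angles are drawn as a uniform magnitude in
#'   `[angle_min_deg, angle_range_deg]` with random sign; this is how
#'   highly curved limbs (e.g. 50--100 degrees) are produced.
#'
#' @return An object of class `growth_params`.
#' @export
#' @examples
#' p <- growth_params(angle_range_deg = 60, n_joints = 4)
#' p$n_joints
growth_params <- function(angle_range_deg = 60,
                          n_joints = 4L,
                          seg_length_range = c(0.08, 0.16),
                          width_profile = 1,
                          taper = 0.4,
                          rel_width = 0.2,
                          rel_length = 0.35,
                          angle_min_deg = 0) {
  n_joints <- as.integer(n_joints)
  if (is.na(n_joints) || n_joints < 2L)
    stop("`n_joints` must be an integer >= 2", call. = FALSE)
  if (angle_range_deg < 0)
    stop("`angle_range_deg` must be >= 0", call. = FALSE)
  if (angle_min_deg < 0 || (angle_min_deg > 0 && angle_min_deg > angle_range_deg))
    stop("`angle_min_deg` must lie in [0, angle_range_deg]", call. = FALSE)
  if (length(seg_length_range) != 2L || any(seg_length_range <= 0) ||
      seg_length_range[1] > seg_length_range[2])
    stop("`seg_length_range` must be an increasing positive pair", call. = FALSE)
  if (length(width_profile) == 1L) width_profile <- rep(width_profile, n_joints)
  if (length(width_profile) != n_joints)
    stop("`width_profile` must have one value per joint (or length 1)", call. = FALSE)
  if (any(width_profile <= 0))
    stop("width factors must be > 0 (tapering handles pointed tips)", call. = FALSE)
  if (taper < 0 || taper > 1) stop("`taper` must lie in [0, 1]", call. = FALSE)
  if (rel_width <= 0 || rel_length <= 0)
    stop("`rel_width` and `rel_length` must be > 0", call. = FALSE)
  structure(
    list(angle_range_deg = angle_range_deg,
         angle_min_deg = angle_min_deg,
         n_joints = n_joints,
         seg_length_range = seg_length_range,
         width_profile = width_profile,
         taper = taper,
         rel_width = rel_width,
         rel_length = rel_length),
    class = "growth_params")
}

# Draw n turning angles under the params' angle model.
draw_turns <- function(n, params) {
  if (n == 0L) return(numeric(0))
  if (params$angle_min_deg > 0) {
    mag <- stats::runif(n, params$angle_min_deg, params$angle_range_deg)
    mag * sample(c(-1, 1), n, replace = TRUE)
  } else {
    stats::runif(n, -params$angle_range_deg, params$angle_range_deg)
  }
}

# Forward reconstruction of joints from a root, an initial absolute
# direction, per-joint turning angles, and segment lengths.
reconstruct_path <- function(start, dir0_deg, turns_deg, seg_lengths) {
  dirs <- deg2rad(dir0_deg + cumsum(c(0, turns_deg)))
  x <- start[1] + cumsum(c(0, seg_lengths * cos(dirs)))
  y <- start[2] + cumsum(c(0, seg_lengths * sin(dirs)))
  skeletal_path(cbind(x = x, y = y))
}

#' Skeletal path constructor
#'
#' @param joints Numeric matrix with columns x, y (one row per joint).
#' @return Object of class `skeletal_path`.
#' @export
skeletal_path <- function(joints) {
  joints <- as.matrix(joints)
  if (ncol(joints) != 2L || nrow(joints) < 2L)
    stop("`joints` must be an n x 2 matrix with n >= 2", call. = FALSE)
  colnames(joints) <- c("x", "y")
  structure(list(joints = joints), class = "skeletal_path")
}

#' @export
print.skeletal_path <- function(x, ...) {
  cat("<skeletal_path> ", nrow(x$joints), " joints, length ",
      format(sum(segment_lengths(x)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Segment lengths of a skeletal path
#' @param path A `skeletal_path`.
#' @return Numeric vector of length `n_joints - 1`.
#' @export
segment_lengths <- function(path) {
  d <- diff(path$joints)
  sqrt(rowSums(d^2))
}

#' Signed turning angles of a skeletal path
#'
#' The turning angle at an interior joint is the signed angular deviation
#' between the incoming and outgoing segment directions, in degrees;
#' 0 means the segments are collinear.
#'
#' @param path A `skeletal_path`.
#' @return Numeric vector of length `n_joints - 2` in `(-180, 180]`.
#' @export
turning_angles <- function(path) {
  d <- diff(path$joints)
  ang <- atan2(d[, 2], d[, 1])
  if (length(ang) < 2L) return(numeric(0))
  dv <- diff(ang)
  rad2deg(atan2(sin(dv), cos(dv)))
}

#' Grow a stochastic skeletal path
#'
#' From a starting point, the first segment direction deviates from
#' `start_angle_deg` by a random draw within the params' angle range; each
#' subsequent segment direction deviates from the previous one by an
#' independent draw from the same range. Segment lengths are drawn uniformly
#' from `seg_length_range`. This is repeated until `n_joints` joints exist.
#'
#' @param start Numeric length-2 starting point.
#' @param start_angle_deg Reference direction of the first segment (degrees;
#'   90 is straight up).
#' @param params A [growth_params()] object.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is restored afterwards.
#' @return A `skeletal_path` with exactly `params$n_joints` joints.
#' @export
#' @examples
#' p <- grow_path(c(0, 0), 90, growth_params(n_joints = 4), seed = 1)
#' nrow(p$joints)
grow_path <- function(start, start_angle_deg, params, seed = NULL) {
  stopifnot(inherits(params, "growth_params"))
  with_seed(seed, {
    dev <- draw_turns(params$n_joints - 1L, params)
    lens <- stats::runif(params$n_joints - 1L,
                         params$seg_length_range[1], params$seg_length_range[2])
    reconstruct_path(start, start_angle_deg + dev[1],
                     if (length(dev) > 1L) dev[-1] else numeric(0), lens)
  })
}

#' Smooth a skeletal path into a dense polyline
#'
#' Interpolates the joints with a natural cubic spline parameterized by
#' cumulative chord length, so the result passes through every joint exactly
#' and is C1-continuous across segments.
#'
#' @param path A `skeletal_path`.
#' @param samples_per_segment Integer >= 1; the polyline has
#'   `(n_joints - 1) * samples_per_segment + 1` vertices.
#' @return Numeric matrix (vertices x 2) with attribute `"knots"` giving the
#'   row indices of the original joints.
#' @export
smooth_path <- function(path, samples_per_segment = 16L) {
  stopifnot(inherits(path, "skeletal_path"))
  samples_per_segment <- as.integer(samples_per_segment)
  if (samples_per_segment < 1L) stop("`samples_per_segment` must be >= 1", call. = FALSE)
  j <- path$joints
  n <- nrow(j)
  tj <- c(0, cumsum(segment_lengths(path)))
  # dense parameter values: subdivide each chord interval, keep knots exact
  td <- unlist(lapply(seq_len(n - 1L), function(i) {
    seq(tj[i], tj[i + 1L], length.out = samples_per_segment + 1L)[-(samples_per_segment + 1L)]
  }))
  td <- c(td, tj[n])
  if (n == 2L) {
    out <- cbind(x = j[1, 1] + (td - tj[1]) / diff(tj) * diff(j[, 1]),
                 y = j[1, 2] + (td - tj[1]) / diff(tj) * diff(j[, 2]))
  } else {
    sx <- stats::spline(tj, j[, 1], xout = td, method = "natural")$y
    sy <- stats::spline(tj, j[, 2], xout = td, method = "natural")$y
    out <- cbind(x = sx, y = sy)
  }
  # pin the knots to the exact joint coordinates
  knots <- seq(1L, by = samples_per_segment, length.out = n)
  out[knots, ] <- j
  attr(out, "knots") <- knots
  out
}

# Arc-length lookup on a polyline: point and unit tangent at arc-length
# fraction t in [0, 1].
polyline_point <- function(pts, t) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  s <- pmin(pmax(t, 0), 1) * cs[length(cs)]
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg))
  f <- (s - cs[i]) / seg[i]
  p <- pts[i, , drop = FALSE] + f * (pts[i + 1L, , drop = FALSE] - pts[i, , drop = FALSE])
  tg <- (pts[i + 1L, , drop = FALSE] - pts[i, , drop = FALSE]) / seg[i]
  list(point = drop(p), tangent = drop(tg))
}

# Run code with a temporary seed (restoring the caller's RNG state), or with
# the ambient RNG when seed is NULL.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a root seed and a counter; documented scheme so
# that designs are reproducible while shapes stay independent.
child_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 9973) %% 2147483647)
}
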