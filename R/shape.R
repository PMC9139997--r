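# Shapes: a main body plus a tree of parts (first-order limbs on the body,
# second-order sprouts on limbs). Each part stores its growth *realization*
# in a root-local frame -- the deviation of the first segment from the local
# outward direction (dev0), the turning angles, segment lengths and widths --
# so that mirroring, straightening and re-rooting are exact operations on
# numbers rather than on rendered coordinates.

new_limb <- function(id, parent = "body", order = 1L, attach_t, side,
                     dev0_deg, turns_deg, seg_lengths, params, base_width,
                     pair_id = NA_character_, size_scale = NA_real_) {
  if (attach_t < 0 || attach_t > 1) stop("`attach_t` must lie in [0, 1]", call. = FALSE)
  if (order == 2L && identical(parent, "body"))
    stop("second-order parts must have a limb (not the main body) as parent",
         call. = FALSE)
  structure(
    list(id = id, parent = parent, order = as.integer(order),
         attach_t = attach_t, side = side,
         dev0_deg = dev0_deg, turns_deg = turns_deg,
         seg_lengths = seg_lengths, params = params,
         base_width = base_width, pair_id = pair_id,
         size_scale = size_scale),
    class = "limb")
}

limb_length <- function(limb) sum(limb$seg_lengths)

is_empty_limb <- function(limb) {
  !is.na(limb$size_scale) && limb$size_scale == 0
}

#' Create a shape (main body plus parts)
#'
#' @param body A [main_body()] object (default body if missing).
#' @param parts List of limb objects (usually grown via [attach_part()]).
#' @param compose If `TRUE`, realize geometry and compose the silhouette.
#' @return Object of class `shape`.
#' @export
shape <- function(body = main_body(), parts = list(), compose = TRUE) {
  s <- structure(list(body = body, parts = parts, geom = NULL), class = "shape")
  if (compose) compose_shape(s) else s
}

#' @export
print.shape <- function(x, ...) {
  n1 <- sum(vapply(x$parts, function(p) p$order == 1L, TRUE))
  n2 <- sum(vapply(x$parts, function(p) p$order == 2L, TRUE))
  cat("<shape> ", n1, " first-order limb(s), ", n2, " sprout(s)",
      if (!is.null(x$geom)) paste0(", silhouette area ",
                                   format(x$geom$area, digits = 4)) else
        " (not composed)", "\n", sep = "")
  invisible(x)
}

# Absolute root point and outward direction (degrees) for a limb.
root_frame <- function(shp, limb) {
  if (identical(limb$parent, "body")) {
    pp <- perimeter_point(shp$body, limb$attach_t)
    list(point = pp$point, angle = rad2deg(atan2(pp$outward[2], pp$outward[1])))
  } else {
    parent <- shp$parts[[limb$parent]]
    if (is.null(parent)) stop("unknown parent part `", limb$parent, "`", call. = FALSE)
    pg <- shp$geom$paths[[limb$parent]]
    if (is.null(pg)) stop("parent `", limb$parent, "` not realized yet", call. = FALSE)
    pl <- polyline_point(pg, limb$attach_t)
    rot <- if (identical(limb$side, "left")) pi / 2 else -pi / 2
    a <- atan2(pl$tangent[2], pl$tangent[1]) + rot
    list(point = pl$point, angle = rad2deg(a))
  }
}

# Realize a limb: absolute joints, smoothed path, silhouette polygon.
realize_limb <- function(shp, limb, samples_per_segment = 12L) {
  rf <- root_frame(shp, limb)
  path <- reconstruct_path(rf$point, rf$angle + limb$dev0_deg,
                           limb$turns_deg, limb$seg_lengths)
  dense <- smooth_path(path, samples_per_segment)
  poly <- build_silhouette(dense, limb$params, base_width = limb$base_width)
  list(path = dense, joints = path$joints, poly = poly, root = rf$point)
}

#' Attach a new part to a shape
#'
#' The part's root lies at the parent location given by `attach_t` (perimeter
#' arc-length fraction for the main body, skeletal arc-length fraction for a
#' limb) and its start angle is orthogonal to the parent's local tangent,
#' pointing outward on the given side. Segment lengths are drawn uniformly
#' from the params' range and then rescaled so the part's summed length is
#' `rel_length` times the parent's; the part width is `rel_width` times the
#' parent's reference width.
#'
#' @param shp A `shape`.
#' @param parent_id `"body"` or the id of an existing first-order limb.
#' @param attach_t Attachment position, fraction in `[0, 1]`.
#' @param side `"left"` or `"right"`.
#' @param params A [growth_params()] object.
#' @param seed Optional integer seed for the growth draws.
#' @param id Part id (auto-generated if `NULL`).
#' @param pair_id Optional symmetric-pair label shared with a mirrored partner.
#' @param compose Recompose the silhouette afterwards?
#' @return The augmented `shape`.
#' @export
attach_part <- function(shp, parent_id = "body", attach_t, side = "left",
                        params = growth_params(), seed = NULL, id = NULL,
                        pair_id = NA_character_, compose = TRUE) {
  stopifnot(inherits(shp, "shape"))
  if (!identical(parent_id, "body") && is.null(shp$parts[[parent_id]]))
    stop("unknown parent `", parent_id, "`", call. = FALSE)
  order <- if (identical(parent_id, "body")) 1L else 2L
  parent_len <- if (order == 1L) shp$body$height else
    limb_length(shp$parts[[parent_id]])
  parent_width <- if (order == 1L) shp$body$width else
    shp$parts[[parent_id]]$base_width * shp$parts[[parent_id]]$params$rel_width
  limb <- with_seed(seed, {
    dev <- draw_turns(params$n_joints - 1L, params)
    lens <- stats::runif(params$n_joints - 1L,
                         params$seg_length_range[1], params$seg_length_range[2])
    lens <- lens * (params$rel_length * parent_len / sum(lens))
    new_limb(id = if (is.null(id)) paste0("part", length(shp$parts) + 1L) else id,
             parent = parent_id, order = order, attach_t = attach_t,
             side = side, dev0_deg = dev[1],
             turns_deg = if (length(dev) > 1L) dev[-1] else numeric(0),
             seg_lengths = lens, params = params, base_width = parent_width,
             pair_id = pair_id)
  })
  shp$parts[[limb$id]] <- limb
  if (compose) compose_shape(shp) else shp
}

# Union of the current silhouette with one more polygon via Clipper.
union_with <- function(current, poly, part_id) {
  rings <- polyclip::polyclip(list(x = current[, 1], y = current[, 2]),
                              list(x = poly[, 1], y = poly[, 2]),
                              op = "union", eps = 1e-12)
  if (!length(rings)) stop("empty union result", call. = FALSE)
  areas <- vapply(rings, function(r) poly_area(cbind(r$x, r$y)), 0)
  main <- which.max(abs(areas))
  if (length(rings) > 1L) {
    # any extra positive ring not inside the main one means a detached part
    mainpoly <- cbind(rings[[main]]$x, rings[[main]]$y)
    for (k in seq_along(rings)[-main]) {
      v <- cbind(rings[[k]]$x[1], rings[[k]]$y[1])
      if (!points_in_poly(v, mainpoly))
        stop("composition error: part `", part_id,
             "` is detached from the silhouette", call. = FALSE)
    }
  }
  ensure_ccw(cbind(x = rings[[main]]$x, y = rings[[main]]$y))
}

#' Compose a shape's silhouette and segmentation points
#'
#' Realizes every part (parents before sprouts), unions the body polygon with
#' all part polygons into a single simple silhouette, and records one
#' skeleton-intersection point per part (the part root, which lies on the
#' parent's boundary for first-order limbs and on the parent's skeleton for
#' sprouts). Zero-size sprouts contribute a segmentation point but no
#' geometry.
#'
#' @param shp A `shape`.
#' @return The shape with its `geom` field populated: `silhouette` (CCW
#'   polygon), `part_polys`, `paths`, `joints`, `seg_points`, `area`.
#' @export
compose_shape <- function(shp) {
  stopifnot(inherits(shp, "shape"))
  shp$geom <- list(paths = list(), joints = list(), part_polys = list(),
                   seg_points = NULL, silhouette = NULL, area = NA_real_)
  sil <- ensure_ccw(shp$body$silhouette)
  ord <- order(vapply(shp$parts, function(p) p$order, 0L))
  seg <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  for (limb in shp$parts[ord]) {
    if (is_empty_limb(limb)) {
      rf <- root_frame(shp, limb)
      seg <- rbind(seg, rf$point)
      rownames(seg)[nrow(seg)] <- limb$id
      next
    }
    rl <- realize_limb(shp, limb)
    shp$geom$paths[[limb$id]] <- rl$path
    shp$geom$joints[[limb$id]] <- rl$joints
    shp$geom$part_polys[[limb$id]] <- rl$poly
    sil <- union_with(sil, rl$poly, limb$id)
    seg <- rbind(seg, rl$root)
    rownames(seg)[nrow(seg)] <- limb$id
  }
  shp$geom$silhouette <- sil
  shp$geom$seg_points <- seg
  shp$geom$area <- poly_area(sil)
  shp
}

#' Segmentation points of a composed shape
#' @param shp A composed `shape`.
#' @return Matrix (one row per part) of skeleton-intersection points.
#' @export
seg_points <- function(shp) {
  if (is.null(shp$geom)) stop("shape is not composed", call. = FALSE)
  shp$geom$seg_points
}

#' Silhouette polygon of a composed shape
#' @param shp A composed `shape`.
#' @return CCW vertex matrix of the unioned silhouette.
#' @export
silhouette <- function(shp) {
  if (is.null(shp$geom)) stop("shape is not composed", call. = FALSE)
  shp$geom$silhouette
}

first_order_ids <- function(shp)
  names(Filter(function(p) p$order == 1L, shp$parts))

sprout_ids <- function(shp)
  names(Filter(function(p) p$order == 2L, shp$parts))
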