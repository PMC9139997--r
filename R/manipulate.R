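# The three part-structure manipulations: symmetry displacement of limb
# pairs, curvedness straightening, and sprouting (by transplantation of
# first-order limbs or by growing sprouts directly).

# Lateral attachment zones (perimeter fractions) that keep limb roots off
# the body's top/bottom cap regions; left flank is t in (0, 0.5).
ZONE_LEFT <- c(0.06, 0.44)

zone_for_side <- function(side) {
  if (identical(side, "left")) ZONE_LEFT else sort(1 - ZONE_LEFT)
}

#' Displacement specification for symmetry breaking
#'
#' @param fraction Perimeter fraction to shift the limb root by; the
#'   experiment levels are 0.025, 0.05, 0.075, 0.10 and 0.125.
#' @param direction `"up"`, `"down"` or `"random"` (Bernoulli 0.5).
#' @return Object of class `displacement_spec`.
#' @export
displacement_spec <- function(fraction, direction = "random") {
  if (fraction <= 0 || fraction > 0.5)
    stop("`fraction` must lie in (0, 0.5]", call. = FALSE)
  direction <- match.arg(direction, c("up", "down", "random"))
  structure(list(fraction = fraction, direction = direction),
            class = "displacement_spec")
}

#' Straightening specification
#'
#' @param factor Multiplier in `(0, 1]` applied to every turning angle;
#'   experiment levels are 0.05 to 0.25 in steps of 0.05.
#' @return Object of class `straighten_spec`.
#' @export
straighten_spec <- function(factor) {
  if (factor <= 0 || factor > 1) stop("`factor` must lie in (0, 1]", call. = FALSE)
  structure(list(factor = factor), class = "straighten_spec")
}

#' Sprout specification
#'
#' @param size_scale Sprout length as a fraction of the parent limb length,
#'   in `[0, 1]`. Zero is a valid "non-existent" sprout that contributes no
#'   geometry but is recorded in the part list.
#' @param placement `"random"` (uniform skeletal fraction in `[0.3, 0.8]`)
#'   or a fixed numeric fraction in `[0, 1]`.
#' @param symmetric_pairing If `TRUE` and the parent limb has a mirrored
#'   partner, an identical mirrored sprout is added to the partner.
#' @param count_per_parent Number of sprouts to add per parent.
#' @return Object of class `sprout_spec`.
#' @export
sprout_spec <- function(size_scale, placement = "random",
                        symmetric_pairing = FALSE, count_per_parent = 1L) {
  if (size_scale < 0 || size_scale > 1)
    stop("`size_scale` must lie in [0, 1]", call. = FALSE)
  if (is.numeric(placement) && (placement < 0 || placement > 1))
    stop("fixed `placement` must lie in [0, 1]", call. = FALSE)
  structure(list(size_scale = size_scale, placement = placement,
                 symmetric_pairing = isTRUE(symmetric_pairing),
                 count_per_parent = as.integer(count_per_parent)),
            class = "sprout_spec")
}

#' Mirror a first-order limb about the body axis
#'
#' Returns the symmetric counterpart of a limb attached to the main body:
#' attached at the mirrored perimeter position (`1 - attach_t`) on the
#' opposite side, with identical segment lengths and widths and
#' sign-flipped angular deviations, so its skeletal path is the exact
#' reflection of the input about the vertical body axis.
#'
#' @param limb A first-order limb (element of `shape$parts`).
#' @param id Id for the mirrored limb (default: original id + `"_m"`).
#' @return The mirrored limb object.
#' @export
mirror_limb <- function(limb, id = paste0(limb$id, "_m")) {
  if (limb$order != 1L || !identical(limb$parent, "body"))
    stop("only first-order limbs attached to the main body can be mirrored",
         call. = FALSE)
  out <- limb
  out$id <- id
  out$attach_t <- 1 - limb$attach_t
  out$side <- if (identical(limb$side, "left")) "right" else "left"
  out$dev0_deg <- -limb$dev0_deg
  out$turns_deg <- -limb$turns_deg
  out
}

#' Displace one limb of a symmetric pair along the body perimeter
#'
#' Shifts the target limb's attachment by `spec$fraction` of the total
#' perimeter arc length, up or down the body, leaving the limb's own
#' geometry (path, widths) unchanged, and recomposes the shape. Shifts that
#' would carry the root into the body's top/bottom cap region are clamped
#' with a warning.
#'
#' @param shp A composed `shape`.
#' @param part_id Id of the limb to displace.
#' @param spec A [displacement_spec()].
#' @param seed Optional seed (used when `direction = "random"`).
#' @param compose Recompose the silhouette afterwards?
#' @return The modified shape.
#' @export
displace_limb <- function(shp, part_id, spec, seed = NULL, compose = TRUE) {
  stopifnot(inherits(shp, "shape"), inherits(spec, "displacement_spec"))
  limb <- shp$parts[[part_id]]
  if (is.null(limb)) stop("unknown part `", part_id, "`", call. = FALSE)
  if (limb$order != 1L)
    stop("only first-order limbs can be displaced along the perimeter", call. = FALSE)
  dirn <- spec$direction
  if (dirn == "random")
    dirn <- with_seed(seed, sample(c("up", "down"), 1L))
  # CCW from the top: on the left flank increasing t moves down the body,
  # on the right flank increasing t moves up.
  sgn <- if (identical(limb$side, "left")) {
    if (dirn == "down") 1 else -1
  } else {
    if (dirn == "down") -1 else 1
  }
  zone <- zone_for_side(limb$side)
  t_new <- limb$attach_t + sgn * spec$fraction
  if (t_new < zone[1] || t_new > zone[2]) {
    t_new <- min(max(t_new, zone[1]), zone[2])
    warning("displacement clamped at the body cap region for `", part_id, "`",
            call. = FALSE)
  }
  shp$parts[[part_id]]$attach_t <- t_new
  if (compose) compose_shape(shp) else shp
}

#' Straighten a limb by scaling its turning angles
#'
#' Every turning angle is multiplied by `spec$factor` while every segment
#' length is preserved exactly; the joints are repositioned by forward
#' reconstruction from the root. A factor of 0.25 applied to a 100-degree
#' joint angle yields 25 degrees.
#'
#' @param limb A limb object (any order).
#' @param spec A [straighten_spec()] (or a bare numeric factor).
#' @return The straightened limb.
#' @export
straighten_limb <- function(limb, spec) {
  if (is.numeric(spec)) spec <- straighten_spec(spec)
  stopifnot(inherits(spec, "straighten_spec"))
  limb$turns_deg <- limb$turns_deg * spec$factor
  limb
}

#' Apply straightening to parts of a shape
#'
#' @param shp A `shape`.
#' @param factor Straightening factor in `(0, 1]`.
#' @param which Part ids to straighten (default: all parts).
#' @param compose Recompose afterwards?
#' @return The modified shape.
#' @export
straighten_shape <- function(shp, factor, which = names(shp$parts),
                             compose = TRUE) {
  spec <- straighten_spec(factor)
  for (id in which) shp$parts[[id]] <- straighten_limb(shp$parts[[id]], spec)
  if (compose) compose_shape(shp) else shp
}

#' Growth parameters for a highly curved limb
#'
#' Returns [growth_params()] whose turning-angle magnitudes are drawn
#' uniformly in 50--100 degrees with random sign -- the curved member of
#' each curvedness pair.
#'
#' @param seed Optional seed for the joint-count draw.
#' @param n_joints Number of joints; by default drawn uniformly from 3--5.
#' @param ... Further arguments passed to [growth_params()].
#' @return A `growth_params` object with `angle_min_deg = 50`,
#'   `angle_range_deg = 100`.
#' @export
curved_limb_params <- function(seed = NULL, n_joints = NULL, ...) {
  if (is.null(n_joints))
    n_joints <- with_seed(seed, sample(3:5, 1L))
  growth_params(angle_range_deg = 100, angle_min_deg = 50,
                n_joints = n_joints, ...)
}

#' Transplant a pair of first-order limbs onto another pair
#'
#' Detaches the donor pair from the main body and re-roots each donor limb
#' at a random skeletal fraction (uniform in `[0.3, 0.8]`) of a host limb,
#' turning the donors into second-order (sprouting) parts while preserving
#' their path geometry up to the new root frame. Total part count is
#' unchanged; the result imitates the part structure of a tree-like plant.
#'
#' @param shp A composed `shape`.
#' @param donor_pair Character vector of two first-order limb ids to detach.
#' @param host_pair Character vector of two first-order limb ids to host
#'   them (donor `i` goes to host `i`).
#' @param seed Optional seed for the re-rooting positions.
#' @param compose Recompose afterwards?
#' @return The modified shape.
#' @export
transplant_limbs <- function(shp, donor_pair, host_pair, seed = NULL,
                             compose = TRUE) {
  stopifnot(inherits(shp, "shape"))
  if (length(donor_pair) != 2L || length(host_pair) != 2L)
    stop("`donor_pair` and `host_pair` must each name two limbs", call. = FALSE)
  if (any(donor_pair %in% host_pair))
    stop("donor and host pairs must be distinct limbs", call. = FALSE)
  for (id in c(donor_pair, host_pair)) {
    limb <- shp$parts[[id]]
    if (is.null(limb) || limb$order != 1L)
      stop("`", id, "` is not a first-order limb of the shape", call. = FALSE)
  }
  ts <- with_seed(seed, stats::runif(2L, 0.3, 0.8))
  for (i in 1:2) {
    limb <- shp$parts[[donor_pair[i]]]
    limb$parent <- host_pair[i]
    limb$order <- 2L
    limb$attach_t <- ts[i]
    # keep the donor on the outer side of its host so branches spread
    limb$side <- shp$parts[[host_pair[i]]]$side
    shp$parts[[donor_pair[i]]] <- limb
  }
  if (compose) compose_shape(shp) else shp
}

#' Add sprouting second-order limbs to a first-order limb
#'
#' Adds order-2 part(s) rooted at random (or fixed) skeletal fractions of
#' the parent, with summed length `size_scale` times the parent length. If
#' `symmetric_pairing` is `TRUE` and the parent has a mirrored partner
#' (shared `pair_id`), an identical mirrored sprout is added to the partner
#' at the mirrored position. A `size_scale` of 0 records the sprout in the
#' part list without emitting geometry.
#'
#' @param shp A composed `shape`.
#' @param parent_part_id Id of the first-order parent limb.
#' @param spec A [sprout_spec()].
#' @param seed Optional seed for placement and articulation draws.
#' @param params Growth parameters for the sprout (defaults to a thinner,
#'   shorter relative of the parent's own parameters).
#' @param compose Recompose afterwards?
#' @return The modified shape.
#' @export
add_sprout <- function(shp, parent_part_id, spec, seed = NULL,
                       params = NULL, compose = TRUE) {
  stopifnot(inherits(shp, "shape"), inherits(spec, "sprout_spec"))
  parent <- shp$parts[[parent_part_id]]
  if (is.null(parent) || parent$order != 1L)
    stop("`", parent_part_id, "` is not a first-order limb", call. = FALSE)
  if (is.null(params)) {
    params <- parent$params
    params$n_joints <- 3L
    params$width_profile <- rep(1, 3L)
    params$rel_width <- 0.7
    params$rel_length <- max(spec$size_scale, 1e-9)
  } else {
    params$rel_length <- max(spec$size_scale, 1e-9)
  }
  partner_id <- NULL
  if (spec$symmetric_pairing && !is.na(parent$pair_id)) {
    cand <- Filter(function(p) identical(p$pair_id, parent$pair_id) &&
                     p$id != parent$id && p$order == 1L, shp$parts)
    if (length(cand)) partner_id <- cand[[1]]$id
  }
  for (k in seq_len(spec$count_per_parent)) {
    draws <- with_seed(if (is.null(seed)) NULL else child_seed(seed, k), {
      at <- if (is.numeric(spec$placement)) spec$placement else
        stats::runif(1L, 0.3, 0.8)
      side <- sample(c("left", "right"), 1L)
      dev <- draw_turns(params$n_joints - 1L, params)
      lens <- stats::runif(params$n_joints - 1L,
                           params$seg_length_range[1], params$seg_length_range[2])
      list(at = at, side = side, dev = dev, lens = lens)
    })
    lens <- draws$lens *
      (params$rel_length * limb_length(parent) / sum(draws$lens))
    sp_id <- paste0(parent_part_id, "_s", k)
    shp$parts[[sp_id]] <- new_limb(
      id = sp_id, parent = parent_part_id, order = 2L,
      attach_t = draws$at, side = draws$side,
      dev0_deg = draws$dev[1],
      turns_deg = if (length(draws$dev) > 1L) draws$dev[-1] else numeric(0),
      seg_lengths = lens, params = params,
      base_width = parent$base_width * parent$params$rel_width,
      size_scale = spec$size_scale)
    if (!is.null(partner_id)) {
      mp_id <- paste0(partner_id, "_s", k)
      partner <- shp$parts[[partner_id]]
      mlens <- draws$lens *
        (params$rel_length * limb_length(partner) / sum(draws$lens))
      shp$parts[[mp_id]] <- new_limb(
        id = mp_id, parent = partner_id, order = 2L,
        attach_t = draws$at,
        side = if (identical(draws$side, "left")) "right" else "left",
        dev0_deg = -draws$dev[1],
        turns_deg = if (length(draws$dev) > 1L) -draws$dev[-1] else numeric(0),
        seg_lengths = mlens, params = params,
        base_width = partner$base_width * partner$params$rel_width,
        size_scale = spec$size_scale)
    }
  }
  if (compose) compose_shape(shp) else shp
}

#' Set the size of an existing sprout
#'
#' Rescales a sprout's segment lengths so its summed length is `size_scale`
#' times its parent's, preserving its articulation. Used by the morphing
#' engine's growing-sprout schedule; a `size_scale` of 0 removes the
#' geometry but keeps the part recorded.
#'
#' @param shp A `shape`.
#' @param sprout_id Id of an order-2 part.
#' @param size_scale New length fraction of the parent, in `[0, 1]`.
#' @param compose Recompose afterwards?
#' @return The modified shape.
#' @export
set_sprout_size <- function(shp, sprout_id, size_scale, compose = TRUE) {
  limb <- shp$parts[[sprout_id]]
  if (is.null(limb) || limb$order != 2L)
    stop("`", sprout_id, "` is not a sprout", call. = FALSE)
  if (size_scale < 0 || size_scale > 1)
    stop("`size_scale` must lie in [0, 1]", call. = FALSE)
  parent_len <- limb_length(shp$parts[[limb$parent]])
  cur <- sum(limb$seg_lengths)
  target <- size_scale * parent_len
  limb$seg_lengths <- if (cur > 0) limb$seg_lengths * (target / cur) else
    rep(target / length(limb$seg_lengths), length(limb$seg_lengths))
  limb$size_scale <- size_scale
  shp$parts[[sprout_id]] <- limb
  if (compose) compose_shape(shp) else shp
}
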