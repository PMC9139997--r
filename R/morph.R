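# Five-step animal-to-plant morph sequences. Three cues co-vary along the
# sequence: symmetric limb pairs are increasingly displaced, all parts get
# continuously straighter, and sprouting second-order limbs either grow from
# non-existent to large ("growing" condition) or keep a fixed size while
# forming symmetrical pairs where possible ("symmetrical" condition).

#' Morph-sequence specification
#'
#' @param n_first_order Number of first-order limbs, 2--6 (held constant
#'   along the sequence; an odd count leaves one limb unpaired).
#' @param condition `"growing"` (sprouts at random points, articulated
#'   independently, growing from non-existent to `sprout_size_endpoints[2]`)
#'   or `"symmetrical"` (sprouts form symmetric pairs where the parent does
#'   and keep the same size throughout).
#' @param max_displacement Displacement fraction reached at step 5 (step 1
#'   is always 0).
#' @param straighten_endpoints Straightening factors at steps 1 and 5
#'   (default fully curved 1.0 down to 0.05).
#' @param sprout_size_endpoints Sprout sizes (fractions of parent length) at
#'   steps 1 and 5 for the growing condition; the symmetrical condition uses
#'   the step-5 value throughout.
#' @param seed Integer seed; the whole sequence is reproducible from it.
#' @param n_steps Number of morph steps (5 in the experiments).
#' @return Object of class `morph_spec`.
#' @export
morph_spec <- function(n_first_order, condition = c("growing", "symmetrical"),
                       max_displacement = 0.125,
                       straighten_endpoints = c(1, 0.05),
                       sprout_size_endpoints = c(0, 0.6),
                       seed = 1L, n_steps = 5L) {
  n_first_order <- as.integer(n_first_order)
  if (n_first_order < 2L || n_first_order > 6L)
    stop("`n_first_order` must lie in 2..6", call. = FALSE)
  condition <- match.arg(condition)
  if (sprout_size_endpoints[1] != 0 && condition == "growing")
    stop("growing sprouts must start at size 0 (step 1)", call. = FALSE)
  structure(
    list(n_first_order = n_first_order, condition = condition,
         max_displacement = max_displacement,
         straighten_endpoints = straighten_endpoints,
         sprout_size_endpoints = sprout_size_endpoints,
         seed = as.integer(seed), n_steps = as.integer(n_steps)),
    class = "morph_spec")
}

#' Per-step morph parameters
#'
#' Deterministic linear schedules: displacement runs from 0 (step 1) to
#' `max_displacement` (step `n_steps`); the straightening factor runs
#' linearly between its endpoints; the sprout size runs from 0 to its
#' maximum in the growing condition and is constant in the symmetrical
#' condition.
#'
#' @param spec A [morph_spec()].
#' @param step Integer step in `1..n_steps`.
#' @return List with `displacement`, `straighten`, `sprout_size`.
#' @export
morph_step_params <- function(spec, step) {
  stopifnot(inherits(spec, "morph_spec"))
  step <- as.integer(step)
  if (step < 1L || step > spec$n_steps)
    stop("`step` must lie in 1..", spec$n_steps, call. = FALSE)
  f <- (step - 1) / (spec$n_steps - 1)
  list(
    displacement = f * spec$max_displacement,
    straighten = spec$straighten_endpoints[1] +
      f * diff(spec$straighten_endpoints),
    sprout_size = if (spec$condition == "growing")
      spec$sprout_size_endpoints[1] + f * diff(spec$sprout_size_endpoints)
    else spec$sprout_size_endpoints[2])
}

# Base (step-independent) realization of a morph sequence: mirrored limb
# pairs at fully curved articulation, one sprout per first-order limb, and a
# per-pair displacement plan (which member moves, and in which direction).
morph_base_shape <- function(spec) {
  seed <- spec$seed
  body <- main_body()
  shp <- shape(body, compose = FALSE)
  n <- spec$n_first_order
  k <- n %/% 2L
  # left-flank attachment slots: evenly partition the zone, jitter inside
  zone <- ZONE_LEFT
  slots <- seq(zone[1], zone[2], length.out = k + 2L)[2:(k + 1L)]
  slot_w <- diff(zone) / (k + 2L)
  pair_ids <- character(0)
  for (i in seq_len(k)) {
    s_i <- child_seed(seed, i)
    t_left <- with_seed(s_i, slots[i] + stats::runif(1, -0.3, 0.3) * slot_w)
    params <- curved_limb_params(seed = child_seed(s_i, 91L))
    pid <- paste0("pair", i)
    shp <- attach_part(shp, "body", t_left, "left", params,
                       seed = child_seed(s_i, 7L),
                       id = paste0("L", i), pair_id = pid, compose = FALSE)
    shp$parts[[paste0("R", i)]] <- mirror_limb(shp$parts[[paste0("L", i)]],
                                               id = paste0("R", i))
    pair_ids <- c(pair_ids, pid)
  }
  if (n %% 2L == 1L) {
    s_o <- child_seed(seed, 77L)
    odd <- with_seed(s_o, {
      side <- sample(c("left", "right"), 1L)
      list(side = side,
           t = stats::runif(1, zone[1] + 0.02, zone[2] - 0.02))
    })
    t_odd <- if (identical(odd$side, "left")) odd$t else 1 - odd$t
    params <- curved_limb_params(seed = child_seed(s_o, 91L))
    shp <- attach_part(shp, "body", t_odd, odd$side, params,
                       seed = child_seed(s_o, 7L), id = "O1", compose = FALSE)
  }
  # displacement plan: one limb of each pair, random member and direction,
  # constrained so the full max_displacement stays inside the flank zone
  plan <- lapply(seq_len(k), function(i) {
    with_seed(child_seed(seed, 1000L + i), {
      member <- sample(c(paste0("L", i), paste0("R", i)), 1L)
      limb <- shp$parts[[member]]
      zn <- zone_for_side(limb$side)
      dirs <- c("up", "down")[c(
        displaced_t(limb, "up", spec$max_displacement, zn, check = TRUE),
        displaced_t(limb, "down", spec$max_displacement, zn, check = TRUE))]
      dirn <- if (length(dirs)) sample(rep(dirs, 2L), 1L) else "down"
      list(member = member, direction = dirn)
    })
  })
  # sprouts: one per first-order limb
  base_sprout <- if (spec$condition == "growing") 1e-9 else
    spec$sprout_size_endpoints[2]
  fo <- first_order_ids(shp)
  shp <- compose_shape(shp)
  if (spec$condition == "symmetrical") {
    done <- character(0)
    for (i in seq_len(k)) {
      shp <- add_sprout(shp, paste0("L", i),
                        sprout_spec(base_sprout, symmetric_pairing = TRUE),
                        seed = child_seed(seed, 2000L + i), compose = FALSE)
      done <- c(done, paste0("L", i), paste0("R", i))
    }
    for (id in setdiff(fo, done))
      shp <- add_sprout(shp, id, sprout_spec(base_sprout),
                        seed = child_seed(seed, 2999L), compose = FALSE)
  } else {
    for (j in seq_along(fo))
      shp <- add_sprout(shp, fo[j], sprout_spec(base_sprout),
                        seed = child_seed(seed, 3000L + j), compose = FALSE)
  }
  list(shape = shp, plan = plan)
}

# Signed shift applied to a limb's attach_t for a given direction; with
# check = TRUE just reports whether the shift stays inside the zone.
displaced_t <- function(limb, direction, fraction, zone, check = FALSE) {
  sgn <- if (identical(limb$side, "left")) {
    if (direction == "down") 1 else -1
  } else {
    if (direction == "down") -1 else 1
  }
  t_new <- limb$attach_t + sgn * fraction
  if (check) return(t_new >= zone[1] && t_new <= zone[2])
  t_new
}

#' Build a five-step animal-to-plant morph sequence
#'
#' Generates one base shape (vertical main body, `n_first_order` mirrored
#' first-order limbs -- an odd limb stays unpaired -- and one sprout per
#' limb), then applies the per-step parameter schedule: step 1 has fully
#' symmetric pairs, full curvedness and (in the growing condition)
#' non-existent sprouts; step `n_steps` has maximal displacement, nearly
#' straight parts and full-size sprouts. Part identity (ids, count, parent
#' topology) is constant across steps.
#'
#' @param spec A [morph_spec()].
#' @return Object of class `morph_sequence`: list with `spec`, `steps`
#'   (list of composed shapes) and `schedule` (data frame of per-step
#'   parameter values).
#' @export
build_morph_sequence <- function(spec) {
  stopifnot(inherits(spec, "morph_spec"))
  base <- morph_base_shape(spec)
  steps <- vector("list", spec$n_steps)
  sched <- data.frame(step = seq_len(spec$n_steps), displacement = NA_real_,
                      straighten = NA_real_, sprout_size = NA_real_)
  for (st in seq_len(spec$n_steps)) {
    pars <- morph_step_params(spec, st)
    sched[st, 2:4] <- c(pars$displacement, pars$straighten, pars$sprout_size)
    shp <- base$shape
    # straighten every part (first-order limbs and sprouts alike)
    shp <- straighten_shape(shp, pars$straighten, compose = FALSE)
    # displace one member of each pair
    if (pars$displacement > 0) {
      for (pl in base$plan) {
        limb <- shp$parts[[pl$member]]
        zn <- zone_for_side(limb$side)
        shp$parts[[pl$member]]$attach_t <-
          min(max(displaced_t(limb, pl$direction, pars$displacement, zn),
                  zn[1]), zn[2])
      }
    }
    # sprout sizes per the condition schedule
    if (spec$condition == "growing") {
      for (sid in sprout_ids(shp))
        shp <- set_sprout_size(shp, sid, pars$sprout_size, compose = FALSE)
    }
    steps[[st]] <- compose_shape(shp)
  }
  structure(list(spec = spec, steps = steps, schedule = sched),
            class = "morph_sequence")
}

#' @export
print.morph_sequence <- function(x, ...) {
  cat("<morph_sequence> ", x$spec$n_first_order, " first-order limbs, ",
      x$spec$condition, " sprouting, ", length(x$steps), " steps\n", sep = "")
  invisible(x)
}
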