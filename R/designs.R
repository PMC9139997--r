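# Stimulus designs of the three experiments: factor crossings, counts,
# seeded randomization, and trial tables.
#
# Experiment 1: pairs differing only in symmetry of part pairs (one limb of
#   each pair displaced by 2.5-12.5% of the body perimeter) or only in
#   curvedness (turning angles scaled by a factor 0.05-0.25), crossed with
#   limb counts 2-5, 20 replicates: 20 x 4 x 5 = 400 pairs per condition.
# Experiment 2: pairs differing in the presence of second-order limbs (one
#   set of first-order limbs transplanted onto the other), crossed with
#   symmetrical/asymmetrical x curved/straight: 4 x 125 = 500 pairs.
# Experiment 3: 110 five-step morph sequences (limb counts 2-6 x two
#   sprouting conditions x 11 replicates) = 550 shapes.

EXP1_DISPLACEMENTS <- c(0.025, 0.05, 0.075, 0.10, 0.125)
EXP1_STRAIGHTEN <- c(0.05, 0.10, 0.15, 0.20, 0.25)

# Random displacement direction among those that keep the shifted root
# inside the lateral flank zone (so the nominal fraction is realized
# exactly, without cap clamping).
feasible_direction <- function(limb, fraction, seed = NULL) {
  zn <- zone_for_side(limb$side)
  ok <- c("up", "down")[c(displaced_t(limb, "up", fraction, zn, check = TRUE),
                          displaced_t(limb, "down", fraction, zn, check = TRUE))]
  if (!length(ok)) return("down")
  with_seed(seed, sample(rep(ok, 2L), 1L))
}

# A base animal-like shape: body plus k mirrored limb pairs (and optionally
# one unpaired limb), with the given growth params factory.
base_paired_shape <- function(n_limbs, seed, params_fun, compose = TRUE) {
  shp <- shape(main_body(), compose = FALSE)
  k <- n_limbs %/% 2L
  zone <- ZONE_LEFT
  slots <- seq(zone[1], zone[2], length.out = k + 2L)[seq_len(k) + 1L]
  slot_w <- diff(zone) / (k + 2L)
  for (i in seq_len(k)) {
    s_i <- child_seed(seed, i)
    t_left <- with_seed(s_i, slots[i] + stats::runif(1, -0.3, 0.3) * slot_w)
    shp <- attach_part(shp, "body", t_left, "left",
                       params_fun(child_seed(s_i, 91L)),
                       seed = child_seed(s_i, 7L), id = paste0("L", i),
                       pair_id = paste0("pair", i), compose = FALSE)
    shp$parts[[paste0("R", i)]] <- mirror_limb(shp$parts[[paste0("L", i)]],
                                               id = paste0("R", i))
  }
  if (n_limbs %% 2L == 1L) {
    s_o <- child_seed(seed, 55L)
    odd <- with_seed(s_o, list(side = sample(c("left", "right"), 1L),
                               t = stats::runif(1, zone[1] + 0.02, zone[2] - 0.02)))
    t_odd <- if (identical(odd$side, "left")) odd$t else 1 - odd$t
    shp <- attach_part(shp, "body", t_odd, odd$side,
                       params_fun(child_seed(s_o, 91L)),
                       seed = child_seed(s_o, 7L), id = "O1", compose = FALSE)
  }
  if (compose) compose_shape(shp) else shp
}

new_shape_pair <- function(a, b, condition, level, n_limbs, pair_id, swapped) {
  structure(list(a = a, b = b, condition = condition, level = level,
                 n_limbs = n_limbs, pair_id = pair_id,
                 placement_swapped = swapped),
            class = "shape_pair")
}

#' @export
print.shape_pair <- function(x, ...) {
  cat("<shape_pair> ", x$pair_id, ": ", x$condition, " level ", x$level,
      ", ", x$n_limbs, " limbs\n", sep = "")
  invisible(x)
}

#' Build the Experiment 1 stimulus set
#'
#' Crosses limb counts 2--5 with five manipulation levels and 20 replicates
#' (400 pairs per condition). In the symmetry condition member A has exact
#' mirror-symmetric limb pairs and member B has one limb of each pair
#' displaced up or down the perimeter by the level fraction. In the
#' curvedness condition member A has highly curved limbs (turning-angle
#' magnitudes 50--100 degrees) and member B is the same shape with every
#' turning angle scaled by the level factor; attachment positions and
#' segment lengths are identical within a pair.
#'
#' @param condition `"symmetry"` or `"curvedness"`.
#' @param seed Integer seed; the whole design is reproducible from it.
#' @param n_reps Replicates per cell (20 in the experiment).
#' @param limb_counts Numbers of first-order limbs (2--5 in the experiment).
#' @param compose Compose silhouettes (needed for rendering/cue
#'   measurement); `FALSE` returns uncomposed shapes quickly.
#' @return List of `shape_pair` objects.
#' @export
build_experiment1 <- function(condition = c("symmetry", "curvedness"),
                              seed = 1L, n_reps = 20L, limb_counts = 2:5,
                              compose = TRUE) {
  condition <- match.arg(condition)
  levels <- if (condition == "symmetry") EXP1_DISPLACEMENTS else EXP1_STRAIGHTEN
  pairs <- list()
  idx <- 0L
  for (nl in limb_counts) for (lv in levels) for (r in seq_len(n_reps)) {
    idx <- idx + 1L
    s <- child_seed(seed, idx * 17L)
    if (condition == "symmetry") {
      a <- base_paired_shape(nl, s, function(sd) growth_params(
        n_joints = with_seed(sd, sample(3:5, 1L))), compose = compose)
      b <- a
      for (i in seq_len(nl %/% 2L)) {
        pick <- with_seed(child_seed(s, 500L + i),
                          sample(c(paste0("L", i), paste0("R", i)), 1L))
        dirn <- feasible_direction(b$parts[[pick]], lv,
                                   seed = child_seed(s, 600L + i))
        b <- displace_limb(b, pick, displacement_spec(lv, dirn),
                           compose = FALSE)
      }
      if (compose) b <- compose_shape(b)
    } else {
      a <- base_paired_shape(nl, s, function(sd) curved_limb_params(seed = sd),
                             compose = compose)
      b <- straighten_shape(a, lv, compose = compose)
    }
    swapped <- with_seed(child_seed(s, 999L), sample(c(TRUE, FALSE), 1L))
    pairs[[idx]] <- new_shape_pair(a, b, condition, lv, nl,
                                   sprintf("e1_%s_%03d", condition, idx), swapped)
  }
  pairs
}

#' Build the Experiment 2 stimulus set
#'
#' Four stimulus types (symmetrical/asymmetrical x curved/straight limbs)
#' with 125 pairs each (500 pairs). Member A is a main body with two
#' symmetric pairs of first-order limbs (insect-like); member B has one pair
#' transplanted onto the other (tree-like, two second-order parts). The
#' symmetry and curvedness factors are applied identically to both members
#' before transplantation.
#'
#' @param seed Integer seed.
#' @param n_per_type Pairs per stimulus type (125 in the experiment).
#' @param asym_fraction Displacement used for the asymmetrical types (the
#'   middle Experiment 1 level).
#' @param straight_factor Straightening factor for the straight types (the
#'   middle Experiment 1 level).
#' @param compose Compose silhouettes?
#' @return List of `shape_pair` objects with `condition = "sprouting"` and
#'   `level` one of `"sym_curved"`, `"sym_straight"`, `"asym_curved"`,
#'   `"asym_straight"`.
#' @export
build_experiment2 <- function(seed = 1L, n_per_type = 125L,
                              asym_fraction = 0.075, straight_factor = 0.15,
                              compose = TRUE) {
  types <- expand.grid(sym = c("sym", "asym"), curv = c("curved", "straight"),
                       stringsAsFactors = FALSE)
  pairs <- list()
  idx <- 0L
  for (ty in seq_len(nrow(types))) for (r in seq_len(n_per_type)) {
    idx <- idx + 1L
    s <- child_seed(seed, idx * 29L)
    a <- base_paired_shape(4L, s, function(sd) curved_limb_params(seed = sd),
                           compose = FALSE)
    if (types$curv[ty] == "straight")
      a <- straighten_shape(a, straight_factor, compose = FALSE)
    if (types$sym[ty] == "asym") {
      for (i in 1:2) {
        pick <- with_seed(child_seed(s, 500L + i),
                          sample(c(paste0("L", i), paste0("R", i)), 1L))
        dirn <- feasible_direction(a$parts[[pick]], asym_fraction,
                                   seed = child_seed(s, 600L + i))
        a <- displace_limb(a, pick, displacement_spec(asym_fraction, dirn),
                           compose = FALSE)
      }
    }
    b <- transplant_limbs(a, donor_pair = c("L1", "R1"),
                          host_pair = c("L2", "R2"),
                          seed = child_seed(s, 700L), compose = compose)
    if (compose) a <- compose_shape(a)
    swapped <- with_seed(child_seed(s, 999L), sample(c(TRUE, FALSE), 1L))
    level <- paste(types$sym[ty], types$curv[ty], sep = "_")
    pairs[[idx]] <- new_shape_pair(a, b, "sprouting", level, 4L,
                                   sprintf("e2_%s_%03d", level, r), swapped)
  }
  pairs
}

#' Build pairs differing only in sprout presence and size
#'
#' Calibration pairs for cue-weight identification: member A is a body with
#' mirrored curved limb pairs, member B is the same shape with one sprout
#' per first-order limb, the sprout size drawn uniformly from `size_range`.
#' Asymmetry and curvedness are identical within a pair, so these pairs
#' isolate the sprout-prominence cue across a wide range of values.
#'
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param size_range Range of sprout sizes (fraction of parent length).
#' @param limb_counts First-order limb counts to draw from.
#' @param sprouts_per_limb Sprouts added per first-order limb (2 spreads the
#'   sprout-prominence cue over a wide range).
#' @return List of `shape_pair` objects with `condition = "sprouting"` and
#'   `level` the drawn sprout size.
#' @export
build_sprouting_pairs <- function(n = 100L, seed = 1L,
                                  size_range = c(0.3, 1.0),
                                  limb_counts = 2:5,
                                  sprouts_per_limb = 2L) {
  lapply(seq_len(n), function(i) {
    s <- child_seed(seed, i * 31L)
    nl <- with_seed(s, sample(limb_counts, 1L))
    a <- base_paired_shape(nl, s, function(sd) curved_limb_params(seed = sd))
    b <- a
    sz <- with_seed(child_seed(s, 5L),
                    stats::runif(1, size_range[1], size_range[2]))
    fo <- first_order_ids(b)
    for (j in seq_along(fo))
      b <- add_sprout(b, fo[j],
                      sprout_spec(sz, count_per_parent = sprouts_per_limb),
                      seed = child_seed(s, 10L + j), compose = FALSE)
    b <- compose_shape(b)
    swapped <- with_seed(child_seed(s, 999L), sample(c(TRUE, FALSE), 1L))
    new_shape_pair(a, b, "sprouting", sz, nl, sprintf("spr_%03d", i), swapped)
  })
}

#' Build the Experiment 3 stimulus set
#'
#' 110 five-step morph sequences: limb counts 2--6 crossed with the two
#' sprouting conditions and 11 replicates, 550 shapes in total, plus the
#' flattened randomized presentation order (so the sequences are not
#' apparent to the viewer).
#'
#' @param seed Integer seed.
#' @param n_reps Replicates per limb-count x condition cell (11).
#' @param limb_counts First-order limb counts (2--6).
#' @return List with `sequences` (list of [build_morph_sequence()] results)
#'   and `presentation` (data frame: trial, seq_id, step, condition,
#'   n_limbs, stim_id) in randomized order.
#' @export
build_experiment3 <- function(seed = 1L, n_reps = 11L, limb_counts = 2:6) {
  cells <- expand.grid(n = limb_counts, cond = c("growing", "symmetrical"),
                       rep = seq_len(n_reps), stringsAsFactors = FALSE)
  sequences <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sequences[[i]] <- build_morph_sequence(morph_spec(
      n_first_order = cells$n[i], condition = cells$cond[i],
      seed = child_seed(seed, i * 13L)))
  }
  names(sequences) <- sprintf("seq%03d", seq_len(nrow(cells)))
  stim <- do.call(rbind, lapply(seq_along(sequences), function(i) {
    data.frame(seq_id = names(sequences)[i],
               step = seq_len(length(sequences[[i]]$steps)),
               condition = cells$cond[i], n_limbs = cells$n[i])
  }))
  stim$stim_id <- paste0(stim$seq_id, "_s", stim$step)
  ord <- with_seed(child_seed(seed, 424243L), sample(nrow(stim)))
  pres <- stim[ord, , drop = FALSE]
  pres$trial <- seq_len(nrow(pres))
  rownames(pres) <- NULL
  list(sequences = sequences,
       presentation = pres[, c("trial", "seq_id", "step", "condition",
                               "n_limbs", "stim_id")])
}

#' Trial table for a list of shape pairs
#'
#' One row per pair in a seeded random order with randomized left/right
#' placement (member B of the pair is shown left when
#' `placement_swapped`).
#'
#' @param pairs List of `shape_pair` objects.
#' @param seed Integer seed for the presentation order.
#' @return Data frame: trial, pair_id, condition, level, n_limbs, left,
#'   right, placement_swapped.
#' @export
trial_table <- function(pairs, seed = 1L) {
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(pair_id = p$pair_id, condition = p$condition,
               level = as.character(p$level), n_limbs = p$n_limbs,
               left = if (p$placement_swapped) "b" else "a",
               right = if (p$placement_swapped) "a" else "b",
               placement_swapped = p$placement_swapped)
  }))
  ord <- with_seed(seed, sample(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df$trial <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("trial", "pair_id", "condition", "level", "n_limbs", "left",
         "right", "placement_swapped")]
}
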