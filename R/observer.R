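# Cue measurement and the synthetic observer. Three cues operationalize the
# manipulated aspects of part structure:
#   asymmetry        -- mean attachment offset of nominal limb pairs, as a
#                       perimeter fraction (0 for exact mirror pairs);
#   curvedness       -- mean unsigned turning angle (degrees) pooled over
#                       first-order limbs;
#   sprout_prominence-- summed second-order silhouette area divided by the
#                       total silhouette area.
# The observer maps (weighted) cues through a logistic link with lapses:
# plant-positive weights make asymmetric, straight, sprouting shapes look
# more plant-like, mirroring the direction of the human effects.

#' Measure the three part-structure cues of a shape
#'
#' @param shp A composed `shape`.
#' @return List of class `cue_vector` with `asymmetry` (perimeter fraction;
#'   `NA` when the shape has no nominal pairs), `curvedness` (degrees) and
#'   `sprout_prominence` (area fraction in `[0, 1)`).
#' @export
measure_cues <- function(shp) {
  stopifnot(inherits(shp, "shape"))
  if (is.null(shp$geom)) shp <- compose_shape(shp)
  fo <- Filter(function(p) p$order == 1L, shp$parts)
  pair_ids <- unique(stats::na.omit(vapply(fo, function(p) p$pair_id, "")))
  asym <- if (!length(pair_ids)) NA_real_ else {
    mean(vapply(pair_ids, function(pid) {
      members <- Filter(function(p) identical(p$pair_id, pid), fo)
      if (length(members) != 2L) return(NA_real_)
      ts <- vapply(members, function(p) p$attach_t, 0)
      sides <- vapply(members, function(p) p$side, "")
      tl <- ts[sides == "left"]; tr <- ts[sides == "right"]
      if (length(tl) != 1L) abs(diff(ts)) else abs(tl - (1 - tr))
    }, 0))
  }
  curv <- if (!length(fo)) NA_real_ else {
    angs <- unlist(lapply(fo, function(p) p$turns_deg))
    if (!length(angs)) 0 else mean(abs(angs))
  }
  sprouts <- Filter(function(p) p$order == 2L && !is_empty_limb(p), shp$parts)
  sp_area <- sum(vapply(names(sprouts), function(id) {
    poly <- shp$geom$part_polys[[id]]
    if (is.null(poly)) 0 else abs(poly_area(poly))
  }, 0))
  structure(list(asymmetry = asym, curvedness = curv,
                 sprout_prominence = sp_area / shp$geom$area,
                 n_pairs = length(pair_ids), n_first_order = length(fo)),
            class = "cue_vector")
}

#' @export
print.cue_vector <- function(x, ...) {
  cat(sprintf("<cue_vector> asymmetry %.4f, curvedness %.1f deg, sprouts %.3f\n",
              x$asymmetry, x$curvedness, x$sprout_prominence))
  invisible(x)
}

#' Synthetic observer model
#'
#' A cue-weighting decision model: the plant evidence of a shape is
#' `w_asym * asymmetry + w_curv * curvedness + w_sprout * sprout_prominence
#' + bias`. In the 2-AFC task the probability of choosing member B as the
#' plant is a lapse-adjusted logistic of the evidence difference; in the
#' slider task the rating is a logistic of the evidence plus Gaussian noise
#' on the logit. Plant-positive settings (positive asymmetry/sprout weights,
#' negative curvedness weight) reproduce the direction of the human effects.
#'
#' @param w_asym Weight on the asymmetry cue (per perimeter fraction).
#' @param w_curv Weight on curvedness (per degree); negative values make
#'   straighter shapes more plant-like.
#' @param w_sprout Weight on sprout prominence (per area fraction).
#' @param bias Additive bias on the plant evidence.
#' @param noise Gaussian standard deviation added on the logit in the
#'   slider task (ignored in 2-AFC, where the logistic provides the noise).
#' @param lapse Lapse rate in `[0, 0.5)`: probability of an attention lapse;
#'   a lapsed 2-AFC response is random, a lapsed rating is uniform.
#' @param pooling How per-part evidence aggregates: `"sum"` (default)
#'   multiplies the mean asymmetry cue by the number of pairs and the mean
#'   curvedness cue by the number of first-order limbs, so shapes with more
#'   parts carry more evidence (probability summation across parts --
#'   this is what makes psychometric slopes grow with limb count);
#'   `"mean"` uses the raw mean cues.
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(w_asym = 12, w_curv = -0.012, w_sprout = 8,
                           bias = 0.55, noise = 0.8, lapse = 0.02,
                           pooling = c("sum", "mean")) {
  if (noise < 0) stop("`noise` must be >= 0", call. = FALSE)
  if (lapse < 0 || lapse >= 0.5) stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  structure(list(w_asym = w_asym, w_curv = w_curv, w_sprout = w_sprout,
                 bias = bias, noise = noise, lapse = lapse,
                 pooling = match.arg(pooling)),
            class = "observer_model")
}

# Effective cue values entering the observer's evidence: under "sum"
# pooling the mean cues are scaled by their part multiplicities.
effective_cues <- function(model, cv) {
  a <- if (is.na(cv$asymmetry)) 0 else cv$asymmetry
  cu <- if (is.na(cv$curvedness)) 0 else cv$curvedness
  if (identical(model$pooling, "sum")) {
    a <- a * cv$n_pairs
    cu <- cu * cv$n_first_order
  }
  c(asymmetry = a, curvedness = cu, sprout_prominence = cv$sprout_prominence)
}

plant_evidence <- function(model, cues) {
  v <- effective_cues(model, cues)
  model$w_asym * v[["asymmetry"]] + model$w_curv * v[["curvedness"]] +
    model$w_sprout * v[["sprout_prominence"]] + model$bias
}

#' Simulate 2-AFC plant choices over shape pairs
#'
#' For each trial the probability of choosing member B as the plant is
#' `lapse + (1 - 2 * lapse) * plogis(evidence(B) - evidence(A))`, so an
#' infinitely strong cue difference is chosen with probability
#' `1 - lapse`. Choices are sampled independently per participant and pair.
#'
#' @param pairs List of `shape_pair` objects (composed).
#' @param model An [observer_model()].
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @return Data frame of class `response_table`: participant, pair_id,
#'   condition, level, n_limbs, the three cue differences (B minus A),
#'   `chose_b`, and `choice` (`"left"`/`"right"` under the pair's
#'   placement).
#' @export
simulate_2afc <- function(pairs, model, n_participants = 13L, seed = 1L) {
  stopifnot(inherits(model, "observer_model"))
  meta <- do.call(rbind, lapply(pairs, function(p) {
    ca <- effective_cues(model, measure_cues(p$a))
    cb <- effective_cues(model, measure_cues(p$b))
    d <- cb - ca
    data.frame(pair_id = p$pair_id, condition = p$condition,
               level = as.character(p$level), n_limbs = p$n_limbs,
               d_asym = d[["asymmetry"]], d_curv = d[["curvedness"]],
               d_sprout = d[["sprout_prominence"]],
               placement_swapped = p$placement_swapped)
  }))
  eta <- model$w_asym * meta$d_asym + model$w_curv * meta$d_curv +
    model$w_sprout * meta$d_sprout
  p_b <- model$lapse + (1 - 2 * model$lapse) * stats::plogis(eta)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_participants), function(pp) {
      chose_b <- stats::rbinom(nrow(meta), 1L, p_b) == 1L
      cbind(data.frame(participant = pp), meta, chose_b = chose_b)
    }))
  })
  out$choice <- ifelse(out$chose_b != out$placement_swapped, "right", "left")
  rownames(out) <- NULL
  class(out) <- c("response_table", class(out))
  out
}

#' Simulate slider ratings over shapes
#'
#' The rating of a shape is `plogis(evidence + rnorm(1, 0, noise))`, which
#' stays in `[0, 1]` by construction; with probability `lapse` the rating is
#' uniform on `[0, 1]`.
#'
#' @param stimuli Data frame with one row per presented shape (e.g.
#'   `build_experiment3()$presentation`) carrying `stim_id`, `condition`,
#'   `n_limbs`, `step`, plus numeric cue columns `asymmetry`, `curvedness`,
#'   `sprout_prominence` (see [stimulus_cues()]).
#' @param model An [observer_model()].
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @return Data frame of class `response_table`: participant, stim_id,
#'   condition, n_limbs, step, rating in `[0, 1]`.
#' @export
simulate_slider <- function(stimuli, model, n_participants = 14L, seed = 1L) {
  stopifnot(inherits(model, "observer_model"))
  need <- c("stim_id", "step", "asymmetry", "curvedness", "sprout_prominence",
            "n_pairs", "n_first_order")
  if (!all(need %in% names(stimuli)))
    stop("`stimuli` must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  pooled <- identical(model$pooling, "sum")
  a <- stimuli$asymmetry * if (pooled) stimuli$n_pairs else 1
  cu <- stimuli$curvedness * if (pooled) stimuli$n_first_order else 1
  eta <- model$w_asym * a + model$w_curv * cu +
    model$w_sprout * stimuli$sprout_prominence + model$bias
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_participants), function(pp) {
      rating <- stats::plogis(eta + stats::rnorm(length(eta), 0, model$noise))
      lapsed <- stats::runif(length(eta)) < model$lapse
      rating[lapsed] <- stats::runif(sum(lapsed))
      data.frame(participant = pp, stim_id = stimuli$stim_id,
                 condition = stimuli$condition, n_limbs = stimuli$n_limbs,
                 step = stimuli$step, rating = rating)
    }))
  })
  rownames(out) <- NULL
  class(out) <- c("response_table", class(out))
  out
}

#' Cue table for an Experiment 3 stimulus set
#'
#' Measures the three cues of every shape in a set of morph sequences and
#' joins them onto the presentation table.
#'
#' @param exp3 Result of [build_experiment3()].
#' @return The presentation data frame with cue columns appended.
#' @export
stimulus_cues <- function(exp3) {
  cue_rows <- do.call(rbind, lapply(names(exp3$sequences), function(sid) {
    sq <- exp3$sequences[[sid]]
    do.call(rbind, lapply(seq_along(sq$steps), function(st) {
      cv <- measure_cues(sq$steps[[st]])
      data.frame(stim_id = paste0(sid, "_s", st),
                 asymmetry = if (is.na(cv$asymmetry)) 0 else cv$asymmetry,
                 curvedness = cv$curvedness,
                 sprout_prominence = cv$sprout_prominence,
                 n_pairs = cv$n_pairs, n_first_order = cv$n_first_order)
    }))
  }))
  merge(exp3$presentation, cue_rows, by = "stim_id", sort = FALSE)
}

#' Recover observer cue weights from simulated 2-AFC responses
#'
#' Fits a logistic regression of the plant choice on the three cue
#' differences (maximum likelihood, no-lapse model) and returns the
#' coefficient estimates.
#'
#' @param responses A `response_table` from [simulate_2afc()].
#' @return Named numeric: `bias` (intercept), `w_asym`, `w_curv`, `w_sprout`.
#' @export
fit_observer_weights <- function(responses) {
  fit <- stats::glm(chose_b ~ d_asym + d_curv + d_sprout,
                    family = stats::binomial(), data = responses)
  co <- stats::coef(fit)
  c(bias = unname(co[1]), w_asym = unname(co["d_asym"]),
    w_curv = unname(co["d_curv"]), w_sprout = unname(co["d_sprout"]))
}
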