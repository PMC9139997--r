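# Shared fixtures, built once per test run and cached (several test files
# reuse the same expensive design builds).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# A hand-built limb with known turning angles, for manipulation tests.
fixed_limb <- function(turns = c(100, -60), dev0 = 15,
                       lens = c(0.12, 0.1, 0.11), attach_t = 0.25,
                       side = "left", id = "L1", pair_id = "pair1") {
  skelmorph:::new_limb(
    id = id, parent = "body", order = 1L, attach_t = attach_t, side = side,
    dev0_deg = dev0, turns_deg = turns, seg_lengths = lens,
    params = growth_params(n_joints = length(lens) + 1L),
    base_width = 0.34, pair_id = pair_id)
}

# A simple composed shape: body + one mirrored curved pair.
paired_shape_fixture <- function(seed = 42) {
  cached_fixture(paste0("paired_", seed), function() {
    shp <- shape(main_body(), compose = FALSE)
    shp <- attach_part(shp, "body", 0.22, "left",
                       curved_limb_params(seed = seed, n_joints = 4L),
                       seed = seed + 1L, id = "L1", pair_id = "pair1",
                       compose = FALSE)
    shp$parts[["R1"]] <- mirror_limb(shp$parts[["L1"]], id = "R1")
    compose_shape(shp)
  })
}

# Full experiment builds (shared between design and acceptance tests).
exp1_symmetry_full <- function()
  cached_fixture("e1_sym", function() build_experiment1("symmetry", seed = 101))
exp1_curvedness_full <- function()
  cached_fixture("e1_curv", function() build_experiment1("curvedness", seed = 102))
exp2_full <- function()
  cached_fixture("e2", function() build_experiment2(seed = 103))
exp3_full <- function()
  cached_fixture("e3", function() build_experiment3(seed = 104))
exp3_cues <- function()
  cached_fixture("e3_cues", function() stimulus_cues(exp3_full()))

# Balanced cue-recovery pool: symmetry, curvedness and sprouting pairs.
recovery_pool <- function()
  cached_fixture("recovery_pool", function() {
    c(build_experiment1("symmetry", seed = 111, n_reps = 5),
      build_experiment1("curvedness", seed = 112, n_reps = 5),
      build_sprouting_pairs(200, seed = 113))
  })

# Symmetric Hausdorff distance between closed polygon boundaries, measured
# vertex-to-edge (vertex sets alone are not comparable: the polygon clipper
# prunes exactly-collinear vertices).
hausdorff_dist <- function(a, b) {
  pts_to_poly <- function(p, q) {
    qc <- rbind(q, q[1, ])
    p1x <- qc[-nrow(qc), 1]; p1y <- qc[-nrow(qc), 2]
    dxs <- diff(qc[, 1]); dys <- diff(qc[, 2])
    len2 <- pmax(dxs^2 + dys^2, 1e-300)
    vx <- outer(p[, 1], p1x, "-"); vy <- outer(p[, 2], p1y, "-")
    t <- sweep(sweep(vx, 2, dxs, "*") + sweep(vy, 2, dys, "*"), 2, len2, "/")
    t <- pmin(pmax(t, 0), 1)
    ex <- vx - sweep(t, 2, dxs, "*"); ey <- vy - sweep(t, 2, dys, "*")
    max(apply(sqrt(ex^2 + ey^2), 1, min))
  }
  max(pts_to_poly(a, b), pts_to_poly(b, a))
}

reflect_x <- function(pts) cbind(-pts[, 1], pts[, 2])
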