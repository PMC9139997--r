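# Part-structure manipulations: mirroring, displacement, straightening,
# curved growth parameters, transplantation, sprouting.

test_that("mirroring is an involution and attaches at mirrored height", {
  l <- fixed_limb()
  m <- mirror_limb(l)
  mm <- mirror_limb(m, id = l$id)
  expect_equal(mm[setdiff(names(mm), "id")], l[setdiff(names(l), "id")],
               tolerance = 1e-12)
  b <- main_body()
  hl <- perimeter_point(b, l$attach_t)$point[2]
  hr <- perimeter_point(b, m$attach_t)$point[2]
  expect_lt(abs(hl - hr), 1e-9)
})

test_that("a mirrored pair composes to a mirror-symmetric silhouette", {
  shp <- paired_shape_fixture()
  sil <- silhouette(shp)
  expect_lt(hausdorff_dist(sil, reflect_x(sil)), 1e-6 * shp$body$height)
  # realized joints reflect exactly (oracle: explicit coordinate reflection)
  expect_equal(reflect_x(shp$geom$joints$L1), unname(shp$geom$joints$R1),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("displacement moves the root by the exact arc length and inverts", {
  shp <- paired_shape_fixture()
  t0 <- shp$parts$L1$attach_t
  d <- displace_limb(shp, "L1", displacement_spec(0.05, "down"))
  expect_equal(abs(d$parts$L1$attach_t - t0), 0.05, tolerance = 1e-12)
  # oracle: high-resolution cumulative arc length between old and new roots
  probe <- seq(t0, d$parts$L1$attach_t, length.out = 4001)
  pts <- t(vapply(probe, function(t) perimeter_point(shp$body, t)$point, c(0, 0)))
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  expect_equal(arc, 0.05 * unname(shp$body$perimeter), tolerance = 1e-4)
  # limb geometry untouched
  expect_equal(d$parts$L1$turns_deg, shp$parts$L1$turns_deg)
  expect_equal(d$parts$L1$seg_lengths, shp$parts$L1$seg_lengths)
  # inverse shift restores the original attachment
  back <- displace_limb(d, "L1", displacement_spec(0.05, "up"), compose = FALSE)
  expect_equal(back$parts$L1$attach_t, t0, tolerance = 1e-12)
})

test_that("a vanishing displacement leaves the silhouette unchanged", {
  shp <- paired_shape_fixture()
  d <- displace_limb(shp, "L1", displacement_spec(1e-9, "down"))
  expect_lt(hausdorff_dist(silhouette(d), silhouette(shp)), 1e-6)
})

test_that("displacement clamps (with a warning) at the body cap region", {
  shp <- paired_shape_fixture()
  shp$parts$L1$attach_t <- 0.42
  expect_warning(d <- displace_limb(shp, "L1", displacement_spec(0.125, "down"),
                                    compose = FALSE), "clamped")
  expect_equal(d$parts$L1$attach_t, skelmorph:::ZONE_LEFT[2])
})

test_that("straightening scales angles and preserves segment lengths exactly", {
  l <- fixed_limb(turns = c(100, -72), lens = c(0.1, 0.12, 0.09))
  s <- straighten_limb(l, straighten_spec(0.25))
  expect_identical(s$turns_deg, c(25, -18))
  expect_identical(s$seg_lengths, l$seg_lengths)
  # oracle: pairwise joint distances recomputed after reconstruction
  for (limb in list(l, s)) {
    j <- skelmorph:::reconstruct_path(c(0, 0), 90 + limb$dev0_deg,
                                      limb$turns_deg, limb$seg_lengths)$joints
    expect_equal(sqrt(rowSums(diff(j)^2)), limb$seg_lengths, tolerance = 1e-12)
  }
  expect_equal(straighten_limb(l, straighten_spec(1)), l, tolerance = 1e-12)
})

test_that("straightening is a multiplicative semigroup", {
  l <- fixed_limb(turns = c(80, -55, 30), lens = c(0.1, 0.1, 0.1, 0.1))
  ab <- straighten_limb(straighten_limb(l, 0.5), 0.4)
  once <- straighten_limb(l, 0.2)
  expect_equal(ab$turns_deg, once$turns_deg, tolerance = 1e-9)
})

test_that("curved limb params draw magnitudes uniformly in 50-100 degrees", {
  draws <- unlist(lapply(1:500, function(i) {
    p <- curved_limb_params(seed = i, n_joints = 5L)
    path <- grow_path(c(0, 0), 90, p, seed = i + 7)
    turning_angles(path)
  }))
  expect_true(all(abs(draws) >= 50 - 1e-9 & abs(draws) <= 100 + 1e-9))
  expect_gte(min(abs(draws)), 50)
  big <- skelmorph:::with_seed(1, skelmorph:::draw_turns(1e4,
    curved_limb_params(n_joints = 3L)))
  expect_equal(mean(abs(big)), 75, tolerance = 2 / 75)
})

test_that("transplantation conserves parts and re-roots on host skeletons", {
  shp <- skelmorph:::base_paired_shape(4L, 31L,
    function(sd) curved_limb_params(seed = sd))
  tr <- transplant_limbs(shp, c("L1", "R1"), c("L2", "R2"), seed = 9)
  expect_equal(length(tr$parts), length(shp$parts))
  orders <- vapply(tr$parts, function(p) p$order, 0L)
  expect_equal(sum(orders == 2L), 2L)
  expect_identical(sort(names(which(orders == 2L))), c("L1", "R1"))
  # oracle: donor roots lie on the host skeletal polylines
  for (d in c("L1", "R1")) {
    root <- seg_points(tr)[d, ]
    host <- tr$geom$paths[[tr$parts[[d]]$parent]]
    # oracle: point-to-polyline (segmentwise projection) distance
    seg_d <- vapply(seq_len(nrow(host) - 1L), function(i) {
      p1 <- host[i, ]; dseg <- host[i + 1L, ] - p1
      t <- sum((root - p1) * dseg) / sum(dseg^2)
      sqrt(sum((root - p1 - min(max(t, 0), 1) * dseg)^2))
    }, 0)
    expect_lt(min(seg_d), 1e-6)
    pl <- skelmorph:::polyline_point(host, tr$parts[[d]]$attach_t)
    expect_equal(unname(pl$point), unname(root), tolerance = 1e-9)
  }
  expect_error(transplant_limbs(shp, c("L1", "R1"), c("R1", "L2")), "distinct")
})

test_that("zero-size sprouts leave geometry untouched but are recorded", {
  shp <- paired_shape_fixture()
  s0 <- add_sprout(shp, "L1", sprout_spec(0), seed = 4)
  expect_equal(length(s0$parts), length(shp$parts) + 1L)
  expect_lt(hausdorff_dist(silhouette(s0), silhouette(shp)), 1e-9)
  expect_equal(nrow(seg_points(s0)), 3L)
})

test_that("symmetric sprout pairing mirrors the sprout root", {
  shp <- paired_shape_fixture()
  s <- add_sprout(shp, "L1", sprout_spec(0.5, symmetric_pairing = TRUE),
                  seed = 6)
  expect_true(all(c("L1_s1", "R1_s1") %in% names(s$parts)))
  r1 <- seg_points(s)["L1_s1", ]
  r2 <- seg_points(s)["R1_s1", ]
  expect_equal(unname(r1[1]), -unname(r2[1]), tolerance = 1e-6)
  expect_equal(unname(r1[2]), unname(r2[2]), tolerance = 1e-6)
})

test_that("asymmetry rises with displacement level; curvedness falls with straightening", {
  shp <- paired_shape_fixture()
  asym <- vapply(c(0.025, 0.05, 0.075, 0.10, 0.125), function(f)
    measure_cues(displace_limb(shp, "L1", displacement_spec(f, "down"),
                               compose = FALSE))$asymmetry, 0)
  expect_true(all(diff(asym) > 0))
  curv <- vapply(c(1, 0.25, 0.2, 0.15, 0.1, 0.05), function(f)
    measure_cues(straighten_shape(shp, f, compose = FALSE))$curvedness, 0)
  expect_true(all(diff(curv) < 0))
})
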