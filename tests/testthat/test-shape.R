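# Attachment, composition, and the silhouette union.

test_that("attached part starts orthogonal to the parent and honors scale", {
  shp <- shape(main_body(), compose = FALSE)
  par0 <- growth_params(angle_range_deg = 0, n_joints = 3L, rel_length = 0.5)
  shp <- attach_part(shp, "body", 0.25, "left", par0, seed = 1, id = "L1")
  limb <- shp$parts$L1
  expect_equal(sum(limb$seg_lengths), 0.5 * shp$body$height, tolerance = 1e-6)
  j <- shp$geom$joints$L1
  d1 <- j[2, ] - j[1, ]
  out <- perimeter_point(shp$body, 0.25)$outward
  expect_equal(unname(d1 / sqrt(sum(d1^2))), unname(out), tolerance = 1e-9)
  expect_lt(j[1, 1], 0)  # root on the left flank
})

test_that("sprout scale is relative to its parent limb", {
  shp <- paired_shape_fixture()
  shp <- add_sprout(shp, "L1", sprout_spec(0.6, placement = 0.5), seed = 5)
  sp <- shp$parts[["L1_s1"]]
  expect_equal(sum(sp$seg_lengths), 0.6 * sum(shp$parts$L1$seg_lengths),
               tolerance = 1e-6)
  # oracle: arc length recomputed from realized joint positions
  j <- shp$geom$joints[["L1_s1"]]
  expect_equal(sum(sqrt(rowSums(diff(j)^2))),
               0.6 * sum(shp$parts$L1$seg_lengths), tolerance = 1e-6)
})

test_that("unknown parents and invalid attachments error", {
  shp <- shape(main_body(), compose = FALSE)
  expect_error(attach_part(shp, "nope", 0.5, "left"), "unknown parent")
  expect_error(attach_part(shp, "body", 1.5, "left"), "attach_t")
})

test_that("a bodiless composition is the identity", {
  shp <- shape(main_body())
  expect_equal(silhouette(shp), skelmorph:::ensure_ccw(shp$body$silhouette),
               tolerance = 0, ignore_attr = TRUE)
  expect_equal(nrow(seg_points(shp)), 0L)
})

test_that("composition yields one seg point per part and a simple polygon", {
  shp <- paired_shape_fixture()
  expect_equal(nrow(seg_points(shp)), 2L)
  expect_identical(sort(rownames(seg_points(shp))), c("L1", "R1"))
  expect_false(skelmorph:::has_self_intersection(silhouette(shp)))
})

test_that("union area is bounded by the component areas and matches a raster oracle", {
  shp <- paired_shape_fixture()
  areas <- c(poly_area(shp$body$silhouette),
             vapply(shp$geom$part_polys, function(p) abs(poly_area(p)), 0))
  u <- shp$geom$area
  expect_lte(u, sum(areas) + 1e-9)
  expect_gte(u, max(areas) - 1e-9)
  # oracle: rasterized pixel-count union on a 1000^2 grid
  sil <- silhouette(shp)
  polys <- c(list(skelmorph:::ensure_ccw(shp$body$silhouette)),
             shp$geom$part_polys)
  bb <- apply(sil, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = 1000)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = 1000)
  grid <- cbind(rep(gx, times = 1000), rep(gy, each = 1000))
  inside <- Reduce(`|`, lapply(polys, function(p)
    skelmorph:::points_in_poly(grid, p)))
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  expect_equal(sum(inside) * cell, u, tolerance = 0.01 * u)
})

test_that("a disjoint part polygon is a composition error", {
  sq <- function(ox) cbind(x = c(0, 1, 1, 0) + ox, y = c(0, 0, 1, 1))
  expect_error(skelmorph:::union_with(sq(0), sq(5), "p1"), "detached")
  # overlapping polygons union fine
  u <- skelmorph:::union_with(sq(0), sq(0.5), "p1")
  expect_equal(poly_area(u), 1.5, tolerance = 1e-6)
})
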