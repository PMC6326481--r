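# Measurement primitives, hulls, overlay and the MMU filter.

test_that("area, perimeter and node count follow closed forms", {
  sq <- unit_square(10)
  expect_equal(area(sq), 100)
  expect_equal(perimeter(sq), 40)
  expect_equal(node_count(sq), 4L)

  holed <- patch_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                         holes = list(cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))))
  expect_equal(area(holed), 96)      # 100 - 4
  expect_equal(perimeter(holed), 48) # 40 + 8: hole rings count
  expect_equal(node_count(holed), 8L)
  expect_equal(node_count(holed, exterior_only = TRUE), 4L)

  pp <- plus_pentomino()
  expect_equal(area(pp), 5)
  expect_equal(perimeter(pp), 12)
  expect_equal(node_count(pp), 12L)

  tri <- patch_polygon(cbind(c(0, 4, 0), c(0, 0, 3)))
  expect_equal(node_count(tri), 3L)
  expect_equal(area(tri), 6)
})

test_that("closed rings and duplicate consecutive vertices are cleaned at ingest", {
  closed <- patch_polygon(cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)))
  expect_equal(node_count(closed), 4L)
  dup <- patch_polygon(cbind(c(0, 0, 10, 10, 10, 0), c(0, 0, 0, 0, 10, 10)))
  expect_equal(node_count(dup), 4L)
  expect_equal(area(dup), 100)
})

test_that("degenerate and invalid rings are refused", {
  expect_error(patch_polygon(cbind(c(0, 1), c(0, 0))), "invalid geometry")
  expect_error(patch_polygon(cbind(c(0, 1, 2), c(0, 0, 0))), "invalid geometry")
  # crossing (bow-tie-like) boundary
  expect_error(patch_polygon(cbind(c(0, 8, 0, 4), c(0, 0, 4, 6))),
               "self-intersecting")
  # hole outside the exterior
  expect_error(patch_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                             holes = list(cbind(c(20, 21, 21, 20),
                                                c(0, 0, 1, 1)))),
               "hole")
  expect_error(patch_polygon(cbind(c(0, 1, 2), c(0, 1, 2))), "invalid")
})

test_that("convex hull is idempotent on convex input and dominates the pentomino", {
  sq <- unit_square(10)
  h <- convex_hull(sq)
  expect_equal(sort(h$exterior[, 1]), sort(sq$exterior[, 1]))
  expect_equal(area(h), area(sq))
  expect_equal(perimeter(h), perimeter(sq))

  pp <- plus_pentomino()
  hp <- convex_hull(pp)
  expect_equal(area(hp), 7)
  expect_equal(perimeter(hp), 4 + 4 * sqrt(2), tolerance = 1e-12)

  star <- patch_polygon(cbind(c(0, 4, 5, 6, 10, 6, 5, 4),
                              c(0, 3, 10, 3, 0, 1, 4, 1)), check = FALSE)
  expect_gt(area(convex_hull(star)), area(star))
})

test_that("hull monotonicity and the isoperimetric bound hold on random stars", {
  set.seed(42)
  for (i in 1:60) {
    p <- random_star(k = sample(5:25, 1), rough = runif(1, 0, 0.6))
    expect_gte(perimeter(p)^2, 4 * pi * area(p) - 1e-9)
    h <- convex_hull(p)
    expect_gte(area(h), area(p) - 1e-9)
    expect_lte(perimeter(h), perimeter(p) + 1e-9)
  }
})

test_that("traced rectilinear polygons agree with cell/edge/corner oracles", {
  set.seed(7)
  for (i in 1:25) {
    occ <- random_blob(n_cells = sample(10:60, 1))
    layer <- raster_to_patches(occ, TRUE, origin = c(0, nrow(occ)), res = 1,
                               mmu = 1e-9)
    expect_length(layer$patches, 1L)
    p <- layer$patches[[1L]]
    expect_equal(area(p), sum(occ))
    expect_equal(perimeter(p), blob_perimeter(occ))
    expect_equal(node_count(p), blob_corners(occ))
  }
})

test_that("mmu filter keeps the inclusive boundary and preserves input", {
  layer <- square_layer(list(c(0, 0, sqrt(5)), c(50, 0, sqrt(10)),
                             c(100, 0, sqrt(50))))
  out <- mmu_filter(layer, 10)
  expect_length(out$patches, 2L)   # 10 m2 kept, 5 m2 dropped
  expect_length(layer$patches, 3L) # input unmodified
  expect_length(mmu_filter(patch_layer(list()), 10)$patches, 0L)
  all_big <- square_layer(list(c(0, 0, 10), c(50, 0, 20)))
  expect_equal(length(mmu_filter(all_big, 10)$patches), 2L)
})

test_that("intersection areas are exact on constructed overlaps", {
  a <- unit_square(10)
  expect_equal(intersection_area(a, a), 100)
  expect_equal(intersection_area(a, translate_patch(a, c(5, 5))), 25)
  expect_equal(intersection_area(a, translate_patch(a, c(20, 0))), 0)
  expect_equal(intersection_area(a, translate_patch(a, c(10, 0))), 0)
  # commutativity on irregular shapes
  p <- plus_pentomino()
  q <- translate_patch(unit_square(2), c(0.5, 0.5))
  expect_equal(intersection_area(p, q), intersection_area(q, p))
  # holes subtract from the overlap
  holed <- patch_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                         holes = list(cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))))
  expect_equal(intersection_area(holed, a), 96)
  # grid-count oracle on a non-convex overlap
  set.seed(1)
  s1 <- random_star(k = 14, rough = 0.5, r0 = 10)
  s2 <- random_star(k = 14, rough = 0.5, r0 = 10, at = c(6, 3))
  g <- as.matrix(expand.grid(x = seq(-16, 22, by = 0.05),
                             y = seq(-16, 19, by = 0.05)))
  mc <- mean(points_in_patch(g, s1) & points_in_patch(g, s2)) * (38 * 35)
  expect_equal(intersection_area(s1, s2), mc, tolerance = 0.02)
})

test_that("patch distance is zero on contact and Euclidean otherwise", {
  a <- unit_square(10)
  expect_equal(patch_distance(a, translate_patch(a, c(25, 0))), 15)
  expect_equal(patch_distance(a, translate_patch(a, c(5, 0))), 0)
  expect_equal(patch_distance(a, translate_patch(a, c(15, 15))),
               sqrt(50), tolerance = 1e-12)
  inner <- translate_patch(unit_square(2), c(4, 4))
  expect_equal(patch_distance(a, inner), 0)  # containment
})

test_that("point-in-polygon counts boundaries as inside", {
  a <- unit_square(10)
  pts <- rbind(c(5, 5), c(0, 5), c(10, 10), c(10.001, 5), c(-1, -1))
  expect_equal(points_in_patch(pts, a), c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("layer distance and membership treat multiple patches correctly", {
  layer <- square_layer(list(c(0, 0, 10), c(100, 0, 10)))
  pts <- rbind(c(5, 5), c(50, 0), c(95, 5))
  expect_equal(points_in_layer(pts, layer), c(TRUE, FALSE, FALSE))
  expect_equal(distance_to_layer(pts, layer), c(0, 40, 5))
})
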