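# Planar geometry primitives against hand-computed values and the
# independent oracles.

test_that("polygon areas match the shoelace formula by hand", {
  expect_equal(polygon_area(ps_rect(0, 0, 1, 1)), 1.0)
  sq <- ps_polygon(c(0, 100, 100, 0), c(0, 0, 100, 100),
                   holes = list(list(x = c(10, 20, 20, 10),
                                     y = c(10, 10, 20, 20))))
  expect_equal(polygon_area(sq), 9900)
  tri <- ps_polygon(c(0, 4, 0), c(0, 0, 3))
  expect_equal(polygon_area(tri), 6.0)
})

test_that("degenerate rings are rejected", {
  expect_error(polygon_area(list(list(x = c(0, 1, 2), y = c(0, 1, 2)))),
               "degenerate")
  expect_error(polygon_area(list(list(x = c(0, 1), y = c(0, 0)))),
               "degenerate")
})

test_that("polygon area is invariant under rigid motion", {
  set.seed(7)
  x <- runif(6, 0, 100); y <- runif(6, 0, 100)
  hull <- chull(x, y)
  poly <- ps_polygon(x[hull], y[hull])
  a0 <- polygon_area(poly)
  th <- 0.7
  rot <- ps_polygon(cos(th) * x[hull] - sin(th) * y[hull] + 1234,
                    sin(th) * x[hull] + cos(th) * y[hull] - 987)
  expect_lt(abs(polygon_area(rot) - a0) / a0, 1e-9)
})

test_that("buffering a square matches the closed-form dilation area", {
  b <- buffer_region(polygons = ps_rect(0, 0, 100, 100), distance = 50)
  expect_length(b, 1)
  want <- 10000 + 4 * 100 * 50 + pi * 50^2
  expect_lt(abs(polygon_area(b) - want) / want, 0.01)
})

test_that("buffers merge or stay disjoint as the geometry dictates", {
  two_far <- buffer_region(polygons = c(ps_rect(0, 0, 100, 100),
                                        ps_rect(1100, 0, 1200, 100)),
                           distance = 50)
  expect_length(two_far, 2)
  abutting <- buffer_region(polygons = c(ps_rect(0, 0, 100, 100),
                                         ps_rect(100, 0, 200, 100)),
                            distance = 50)
  expect_length(abutting, 1)
})

test_that("buffer area grows with the input and with distance", {
  sq <- ps_rect(0, 0, 100, 100)
  a50 <- polygon_area(buffer_region(polygons = sq, distance = 50))
  a80 <- polygon_area(buffer_region(polygons = sq, distance = 80))
  expect_gt(a50, polygon_area(sq))
  expect_gt(a80, a50)
})

test_that("non-positive buffer distance is a parameter error", {
  expect_error(buffer_region(polygons = ps_rect(0, 0, 1, 1), distance = 0),
               "parameter error")
  expect_error(buffer_region(polygons = ps_rect(0, 0, 1, 1), distance = -5),
               "parameter error")
})

test_that("shared border length counts different-class edges once", {
  win <- ps_rect(0, 0, 2, 1)
  m <- list(land_patch(ps_rect(0, 0, 1, 1), "cropland"),
            land_patch(ps_rect(1, 0, 2, 1), "forest"))
  expect_equal(shared_border_length(m, win), 1.0)
  m3 <- list(land_patch(ps_rect(0, 0, 1, 1), "cropland"),
             land_patch(ps_rect(1, 0, 2, 1), "forest"),
             land_patch(ps_rect(2, 0, 3, 1), "cropland"))
  expect_equal(shared_border_length(m3, ps_rect(0, 0, 3, 1)), 2.0)
  expect_equal(shared_border_length(m3[1], ps_rect(0, 0, 3, 1)), 0.0)
})

test_that("same-class borders and window-boundary edges are not counted", {
  m <- list(land_patch(ps_rect(0, 0, 1, 1), "cropland"),
            land_patch(ps_rect(1, 0, 2, 1), "cropland"))
  expect_equal(shared_border_length(m, ps_rect(0, 0, 2, 1)), 0.0)
  # clipping the window through the middle of two patches adds no length
  m2 <- list(land_patch(ps_rect(0, 0, 1, 2), "cropland"),
             land_patch(ps_rect(1, 0, 2, 2), "forest"))
  expect_equal(shared_border_length(m2, ps_rect(0, 0, 2, 1)), 1.0)
})

test_that("shared border length is symmetric and scales linearly", {
  set.seed(11)
  m <- list(land_patch(ps_rect(0, 0, 3, 2), "cropland"),
            land_patch(ps_rect(3, 0, 5, 2), "forest"),
            land_patch(ps_rect(0, 2, 5, 4), "water"))
  win <- ps_rect(0, 0, 5, 4)
  l1 <- shared_border_length(m, win)
  l2 <- shared_border_length(rev(m), win)
  expect_equal(l1, l2)
  dbl <- lapply(m, function(p) {
    land_patch(lapply(p$geometry, function(r) list(x = 2 * r$x, y = 2 * r$y)),
               p$class)
  })
  expect_equal(shared_border_length(dbl, ps_rect(0, 0, 10, 8)), 2 * l1)
})

test_that("overlapping patches raise an invalid-mosaic error", {
  m <- list(land_patch(ps_rect(0, 0, 10, 10), "cropland"),
            land_patch(ps_rect(5, 0, 15, 10), "forest"))
  expect_error(shared_border_length(m, ps_rect(0, 0, 15, 10)),
               "invalid mosaic")
})

test_that("mean interior distance matches single-point hand cases", {
  # 2 x 2 m cropland fully surrounded by forest, one centre sample point
  crop <- ps_rect(0, 0, 2, 2)
  forest <- land_patch(c(ps_rect(-10, -10, 12, 12),
                         lapply(ps_rect(0, 0, 2, 2), function(r) {
                           list(x = rev(r$x), y = rev(r$y))
                         })), "forest")
  expect_equal(mean_interior_distance(crop, list(forest), spacing = 2), 1.0)
  # excluded water forces the forest patch 50 m away
  crop2 <- ps_rect(0, 0, 10, 10)
  water <- land_patch(ps_rect(10, 0, 20, 10), "water")
  far_forest <- land_patch(ps_rect(55, 0, 65, 10), "forest")
  expect_equal(mean_interior_distance(crop2, list(water, far_forest),
                                      spacing = 10), 50.0)
})

test_that("mean interior distance equals the brute-force oracle", {
  crop <- ps_rect(0, 0, 100, 100)
  ring <- land_patch(c(ps_rect(-50, -50, 150, 150),
                       lapply(ps_rect(0, 0, 100, 100), function(r) {
                         list(x = rev(r$x), y = rev(r$y))
                       })), "forest")
  got <- mean_interior_distance(crop, list(ring), spacing = 10)
  want <- oracle_interior_distance(crop, list(ring), spacing = 10)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("mean interior distance is stable under spacing halving", {
  crop <- ps_rect(0, 0, 100, 100)
  ring <- land_patch(c(ps_rect(-50, -50, 150, 150),
                       lapply(ps_rect(0, 0, 100, 100), function(r) {
                         list(x = rev(r$x), y = rev(r$y))
                       })), "forest")
  d1 <- mean_interior_distance(crop, list(ring), spacing = 10)
  d2 <- mean_interior_distance(crop, list(ring), spacing = 5)
  expect_lt(abs(d1 - d2) / d2, 0.05)
})

test_that("missing habitat or empty grid give the undefined marker", {
  crop <- ps_rect(0, 0, 10, 10)
  expect_warning(
    d <- mean_interior_distance(crop, list(land_patch(ps_rect(20, 0, 30, 10),
                                                      "water")), spacing = 5),
    "no eligible habitat")
  expect_true(is.na(d))
  tiny <- ps_rect(0, 0, 1, 1)
  expect_true(is.na(mean_interior_distance(
    tiny, list(land_patch(ps_rect(5, 0, 6, 1), "forest")), spacing = 10)))
})

test_that("overlay areas match hand overlays", {
  a <- ps_rect(0, 0, 1, 1)
  expect_equal(overlay_area(a, a), 1.0)
  expect_equal(overlay_area(a, ps_rect(5, 5, 6, 6)), 0.0)
  expect_equal(overlay_area(a, ps_rect(0.5, 0, 1.5, 1)), 0.5)
  b <- ps_rect(0.2, 0.2, 0.7, 0.9)
  expect_lte(overlay_area(a, b), min(polygon_area(a), polygon_area(b)))
})

test_that("grid points use the half-pitch offset convention", {
  g <- grid_points(ps_rect(0, 0, 100, 100), 50)
  expect_equal(nrow(g), 4)
  expect_setequal(g$x, c(25, 75))
  expect_error(grid_points(ps_rect(0, 0, 1, 1), 0), "parameter error")
})
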