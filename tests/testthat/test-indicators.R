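# Per-indicator hand-checkable examples, the z-scaling contract, and the
# rigid-motion / ratio-scaling properties of the engine.

# A minimal study-area object over an explicit window.
mk_study <- function(ps) {
  list(polygons = ps, area_ha = ps_area(ps) / 1e4,
       centre = c(x = NA_real_, y = NA_real_))
}

test_that("LanVar is border length per hectare", {
  mosaic <- list(land_patch(ps_rect(0, 0, 1, 1), "cropland"),
                 land_patch(ps_rect(1, 0, 2, 1), "forest"))
  st <- mk_study(ps_rect(0, 0, 2, 1))
  expect_equal(lanvar(st, mosaic), 1.0 / 2e-4)  # 5000 m/ha
  # homogeneous window has no borders
  mono <- list(land_patch(ps_rect(0, 0, 2, 1), "cropland"))
  expect_equal(lanvar(st, mono), 0)
  # doubling the study area with no new borders halves the value
  st2 <- mk_study(ps_rect(0, -1, 2, 1))
  expect_equal(lanvar(st2, mosaic), lanvar(st, mosaic) / 2)
})

test_that("CrpDst excludes water and built-up habitats", {
  crop <- list(ps_rect(0, 0, 10, 10))
  mosaic <- list(land_patch(ps_rect(10, 0, 20, 10), "water"),
                 land_patch(ps_rect(55, 0, 65, 10), "forest"))
  d <- crpdst(crop, mosaic, spacing = 10)
  expect_equal(d, 50.0)  # single grid point (5,5) to forest at x = 55
  expect_error(crpdst(list(), mosaic), "no cropland")
})

test_that("Gra doubles the inventory overlap", {
  g <- list(ps_rect(0, 0, 300, 100))  # 3 ha grassland
  inv1 <- ps_rect(0, 0, 100, 100)     # 1 ha in the inventory
  expect_equal(gra(g, inv1, 10), 0.4)
  expect_equal(gra(list(), inv1, 10), 0)
  inv_all <- ps_rect(-10, -10, 400, 200)
  expect_equal(gra(g, inv_all, 10), 0.6)
})

test_that("SSHab counts points inside cropland only", {
  crop <- list(ps_rect(0, 0, 200, 100))  # 2 ha
  pts <- data.frame(x = c(10, 20, 30, 40), y = 50)
  expect_equal(sshab(pts, crop, 2), 2.0)
  outside <- data.frame(x = 500, y = 500)
  expect_equal(sshab(outside, crop, 2), 0)
  expect_warning(v <- sshab(pts, crop, 0), "zero cropland")
  expect_true(is.na(v))
})

test_that("RodVar counts distinct road-adjacent patches per hectare", {
  st <- mk_study(ps_rect(0, 0, 100, 100))  # 1 ha
  mosaic <- list(land_patch(ps_rect(0, 0, 30, 100), "cropland"),
                 land_patch(ps_rect(30, 0, 60, 100), "forest"),
                 land_patch(ps_rect(60, 0, 100, 100), "other_open"))
  # road crosses the first two patches only
  road <- list(list(x = c(5, 55), y = c(50, 50)))
  expect_equal(rodvar(mosaic, road, st), 2.0)
  expect_equal(rodvar(mosaic, list(), st), 0)
  # the same patch touched by two roads is counted once
  two <- list(list(x = c(5, 25), y = c(20, 20)),
              list(x = c(5, 25), y = c(80, 80)))
  expect_equal(rodvar(mosaic, two, st), 1.0)
})

test_that("Acc components are the road share and mean population density", {
  st <- mk_study(ps_rect(0, 0, 1000, 1000))
  road <- list(list(x = c(-100, 1100), y = c(500, 500)))
  pop <- expand.grid(x = seq(-9500, 10500, by = 1000),
                     y = seq(-9500, 10500, by = 1000))
  pop$density <- 100
  a <- acc(st, road, pop, cell_size = 1000)
  expect_equal(unname(a["road_share"]), 0.2, tolerance = 1e-3)
  expect_equal(unname(a["pop_density"]), 100, tolerance = 1e-9)
  a0 <- acc(st, list(), pop, cell_size = 1000)
  expect_equal(unname(a0["road_share"]), 0)
})

test_that("population density weights boundary cells by exact overlap", {
  st <- mk_study(ps_rect(0, 0, 1000, 1000))
  pop <- expand.grid(x = seq(-14500, 15500, by = 1000),
                     y = seq(-14500, 15500, by = 1000))
  # density increases with x: boundary weighting must shift the mean from
  # any simple cell-count average; compare against full-precision oracle
  pop$density <- pmax(0, pop$x / 100 + 200)
  got <- pop_weighted_density(st, pop, cell_size = 1000)
  B <- o_buffer_polys(ps_rect(0, 0, 1000, 1000), 10000)
  w <- vapply(seq_len(nrow(pop)), function(i) {
    cell <- ps_rect(pop$x[i] - 500, pop$y[i] - 500,
                    pop$x[i] + 500, pop$y[i] + 500)
    o_area(o_clip(cell, B))
  }, numeric(1))
  expect_equal(got, sum(w * pop$density) / sum(w), tolerance = 1e-6)
})

test_that("Visit counts distinct users per source", {
  st <- mk_study(ps_rect(0, 0, 2000, 1000))  # 2 km2
  pts <- data.frame(
    x = c(10, 20, 30, 40, 50, 60, 70),
    y = 100,
    user_id = c("p1", "p1", "p1", "p2", "p3", "o1", "o2"),
    source = c(rep("photo", 5), rep("species_observation", 2)),
    stringsAsFactors = FALSE)
  v <- visit(pts, st)
  expect_equal(unname(v["photo_users_km2"]), 1.5)
  expect_equal(unname(v["obs_users_km2"]), 1.0)
  one <- data.frame(x = rep(10, 10), y = 10, user_id = "p9",
                    source = "photo", stringsAsFactors = FALSE)
  expect_equal(unname(visit(one, st)["photo_users_km2"]), 0.5)
  none <- pts[0, , drop = FALSE]
  expect_equal(unname(visit(none, st)), c(0, 0))
})

test_that("NatRes sums the three layers so overlaps add", {
  st <- mk_study(ps_rect(0, 0, 1000, 100))  # 10 ha
  layers <- list(nature_reserve = ps_rect(0, 0, 200, 100),
                 natura2000 = ps_rect(0, 0, 200, 100),
                 national_interest = list())
  expect_equal(natres(layers, st), 0.4)
  layers0 <- list(nature_reserve = list(), natura2000 = list(),
                  national_interest = list())
  expect_equal(natres(layers0, st), 0)
  full <- list(nature_reserve = ps_rect(-10, -10, 1100, 200),
               natura2000 = list(), national_interest = list())
  expect_equal(natres(full, st), 1.0)
})

test_that("z-scaling matches the population-SD closed form", {
  raw <- data.frame(farm_id = c("a", "b", "c"),
                    lanvar = c(1, 2, 3), crpdst = NA_real_, gra = NA_real_,
                    sshab = NA_real_, crpseq = NA_real_, rodvar = NA_real_,
                    road_share = NA_real_, pop_density = NA_real_,
                    photo_users_km2 = NA_real_, obs_users_km2 = NA_real_,
                    natres = NA_real_, stringsAsFactors = FALSE)
  sc <- scale_indicators(raw)
  expect_equal(sc$LanVar, (c(1, 2, 3) - 2) / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(sc$LanVar[2], 0)
})

test_that("constant columns scale to zero with a warning", {
  raw <- data.frame(farm_id = c("a", "b", "c"),
                    lanvar = c(5, 5, 5), crpdst = NA_real_, gra = NA_real_,
                    sshab = NA_real_, crpseq = NA_real_, rodvar = NA_real_,
                    road_share = NA_real_, pop_density = NA_real_,
                    photo_users_km2 = NA_real_, obs_users_km2 = NA_real_,
                    natres = NA_real_, stringsAsFactors = FALSE)
  expect_warning(sc <- scale_indicators(raw), "zero variance")
  expect_equal(sc$LanVar, c(0, 0, 0))
})

test_that("scaled columns have mean zero and unit SD on the fixture", {
  b <- fixture_bundle()
  res <- compute_indicators(b$bundle, b$farms)
  # the small fixture's 10 km population buffers all see the whole raster,
  # so pop_density is constant and scales to zero by the degenerate rule
  sc <- suppressWarnings(scale_indicators(res$raw))
  for (nm in setdiff(names(sc), "farm_id")) {
    x <- sc[[nm]][!is.na(sc[[nm]])]
    if (sqrt(mean((x - mean(x))^2)) == 0) next  # degenerate column
    expect_equal(mean(x), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((x - mean(x))^2)), 1, tolerance = 1e-9)
  }
  # composites are built from z-scaled components, then re-scaled
  raw <- res$raw
  z <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  acc_comp <- z(raw$road_share) + z(raw$pop_density)
  expect_equal(sc$Acc, z(acc_comp), tolerance = 1e-9)
  vis_comp <- z(raw$photo_users_km2) + z(raw$obs_users_km2)
  expect_equal(sc$Visit, z(vis_comp), tolerance = 1e-9)
})

test_that("indicators are invariant under rigid motion", {
  shift_ps <- function(ps, dx, dy)
    lapply(ps, function(r) list(x = r$x + dx, y = r$y + dy))
  mosaic <- list(land_patch(ps_rect(0, 0, 40, 100), "cropland"),
                 land_patch(ps_rect(40, 0, 100, 100), "forest"))
  st <- mk_study(ps_rect(0, 0, 100, 100))
  road <- list(list(x = c(10, 90), y = c(50, 50)))
  dx <- 12345; dy <- -678
  mosaic2 <- lapply(mosaic, function(p)
    land_patch(shift_ps(p$geometry, dx, dy), p$class))
  st2 <- mk_study(shift_ps(st$polygons, dx, dy))
  road2 <- list(list(x = road[[1]]$x + dx, y = road[[1]]$y + dy))
  expect_equal(lanvar(st2, mosaic2), lanvar(st, mosaic), tolerance = 1e-9)
  expect_equal(rodvar(mosaic2, road2, st2), rodvar(mosaic, road, st),
               tolerance = 1e-9)
  crop1 <- list(mosaic[[1]]$geometry)
  crop2 <- list(shift_ps(mosaic[[1]]$geometry, dx, dy))
  expect_equal(crpdst(crop2, mosaic2), crpdst(crop1, mosaic))
})

test_that("ratio indicators rescale deterministically with length scale", {
  k <- 2
  scale_ps <- function(ps) lapply(ps, function(r)
    list(x = r$x * k, y = r$y * k))
  mosaic <- list(land_patch(ps_rect(0, 0, 40, 100), "cropland"),
                 land_patch(ps_rect(40, 0, 100, 100), "forest"))
  st <- mk_study(ps_rect(0, 0, 100, 100))
  mosaic2 <- lapply(mosaic, function(p)
    land_patch(scale_ps(p$geometry), p$class))
  st2 <- mk_study(scale_ps(st$polygons))
  # lanvar scales by 1/k; gra and natres are dimensionless
  expect_equal(lanvar(st2, mosaic2), lanvar(st, mosaic) / k,
               tolerance = 1e-9)
  g <- list(ps_rect(0, 0, 300, 100))
  inv <- ps_rect(0, 0, 100, 100)
  expect_equal(gra(lapply(g, scale_ps), scale_ps(inv), 10 * k^2),
               gra(g, inv, 10), tolerance = 1e-9)
  layers <- list(nature_reserve = ps_rect(0, 0, 20, 100),
                 natura2000 = list(), national_interest = list())
  layers2 <- list(nature_reserve = scale_ps(layers$nature_reserve),
                  natura2000 = list(), national_interest = list())
  expect_equal(natres(layers2, st2), natres(layers, st), tolerance = 1e-9)
})
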