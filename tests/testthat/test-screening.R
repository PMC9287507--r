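# Spearman screening, the exclusion rule, gridded summaries and the
# per-land-use summaries.

test_that("Spearman correlations hit the exact endpoints", {
  d <- data.frame(farm_id = letters[1:5],
                  A = c(1, 2, 3, 4, 5), B = c(2, 4, 6, 8, 10),
                  C = c(5, 4, 3, 2, 1))
  m <- spearman_matrix(d)
  expect_equal(m$r["A", "A"], 1)
  expect_equal(m$r["A", "B"], 1)
  expect_equal(m$r["A", "C"], -1)
  expect_true(all(m$r == t(m$r)))
})

test_that("tied data match the independent tie-corrected formula", {
  set.seed(21)
  for (i in 1:10) {
    x <- sample(1:4, 10, replace = TRUE)
    y <- sample(1:5, 10, replace = TRUE) + 0.1 * x
    d <- data.frame(farm_id = sprintf("f%02d", 1:10), X = x, Y = y)
    m <- spearman_matrix(d)
    o <- oracle_spearman(x, y)
    expect_equal(m$r["X", "Y"], o$r, tolerance = 1e-12)
    expect_equal(m$p["X", "Y"], o$p, tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30)
  d1 <- data.frame(farm_id = 1:30, X = x, Y = y)
  d2 <- data.frame(farm_id = 1:30, X = exp(x), Y = y^3)
  expect_equal(spearman_matrix(d1)$r["X", "Y"],
               spearman_matrix(d2)$r["X", "Y"])
})

test_that("strength labels respect thresholds and significance", {
  set.seed(33)
  n <- 200
  a <- rnorm(n)
  d <- data.frame(farm_id = seq_len(n),
                  A = a, B = a + rnorm(n, 0, 0.45), C = rnorm(n))
  m <- spearman_matrix(d)
  expect_equal(m$strength["A", "B"], "strong")
  expect_equal(m$strength["A", "C"], "n.s.")
})

screen_fixture <- function(n = 120) {
  set.seed(14)
  base <- rnorm(n)
  data.frame(farm_id = sprintf("f%03d", seq_len(n)),
             LanVar = base,
             CrpDst = exp(base) + rnorm(n, 0, 1e-6),
             RodVar = base^3 + rnorm(n, 0, 1e-6),
             Gra = rnorm(n), Acc = rnorm(n))
}

test_that("monotone derivatives of an indicator are screened out", {
  m <- spearman_matrix(screen_fixture())
  kept <- exclusion_screen(m)
  expect_true("LanVar" %in% kept)
  expect_false("CrpDst" %in% kept)
  expect_false("RodVar" %in% kept)
  expect_true(all(c("Gra", "Acc") %in% kept))
})

test_that("no strong pairs means everything is retained", {
  set.seed(9)
  d <- data.frame(farm_id = 1:80, LanVar = rnorm(80), Gra = rnorm(80),
                  Acc = rnorm(80))
  kept <- exclusion_screen(spearman_matrix(d))
  expect_setequal(kept, c("LanVar", "Gra", "Acc"))
})

test_that("a mutually strong triple keeps exactly its top-priority member", {
  set.seed(10)
  base <- rnorm(100)
  d <- data.frame(farm_id = 1:100,
                  SSHab = base + rnorm(100, 0, 0.05),
                  NatRes = base + rnorm(100, 0, 0.05),
                  Visit = base + rnorm(100, 0, 0.05))
  kept <- exclusion_screen(spearman_matrix(d))
  expect_equal(kept, "SSHab")
})

test_that("screening is independent of indicator column order", {
  d <- screen_fixture()
  d2 <- d[, c("farm_id", "Acc", "RodVar", "LanVar", "Gra", "CrpDst")]
  expect_setequal(exclusion_screen(spearman_matrix(d)),
                  exclusion_screen(spearman_matrix(d2)))
})

test_that("a priority list missing an indicator is an error", {
  m <- spearman_matrix(data.frame(farm_id = 1:10, Foo = rnorm(10),
                                  LanVar = rnorm(10)))
  expect_error(exclusion_screen(m), "priority list must cover")
})

test_that("grid cells aggregate with agricultural-area weights", {
  centres <- data.frame(farm_id = c("a", "b"), x = c(100, 200), y = c(1, 2))
  scaled <- data.frame(farm_id = c("a", "b"), Ind = c(1, -1))
  areas <- data.frame(farm_id = c("a", "b"), agri_area_ha = c(10, 30))
  g <- grid_summary(centres, scaled, areas, cell = 15000)
  expect_equal(nrow(g), 1)
  expect_equal(g$Ind, -0.5)
})

test_that("grid summary conserves the area-weighted national mean", {
  set.seed(17)
  n <- 60
  centres <- data.frame(farm_id = seq_len(n), x = runif(n, 0, 60000),
                        y = runif(n, 0, 60000))
  scaled <- data.frame(farm_id = seq_len(n), A = rnorm(n), B = rnorm(n))
  areas <- data.frame(farm_id = seq_len(n),
                      agri_area_ha = runif(n, 5, 80))
  g <- grid_summary(centres, scaled, areas)
  for (ind in c("A", "B")) {
    national <- sum(scaled[[ind]] * areas$agri_area_ha) /
      sum(areas$agri_area_ha)
    expect_equal(sum(g[[ind]] * g$area_ha) / sum(g$area_ha), national,
                 tolerance = 1e-9)
  }
})

test_that("identical values give zero above/below counts, empty cells vanish", {
  centres <- data.frame(farm_id = 1:4,
                        x = c(100, 16000, 31000, 46000), y = 100)
  scaled <- data.frame(farm_id = 1:4, Ind = rep(0.7, 4))
  areas <- data.frame(farm_id = 1:4, agri_area_ha = 10)
  g <- grid_summary(centres, scaled, areas)
  expect_equal(nrow(g), 4)  # only occupied cells appear
  expect_true(all(g$n_above == 0))
  expect_true(all(g$n_below == 0))
})

test_that("land-use visitor densities count distinct users per class", {
  landuse <- list(grassland = ps_rect(0, 0, 2000, 1000),
                  cropland = ps_rect(3000, 0, 4000, 1000))
  pts <- data.frame(
    x = c(100, 200, 300, 400, 500, 3500, 100),
    y = rep(500, 7),
    user_id = c("u1", "u2", "u3", "u4", "u5", "u1", "u1"),
    source = c(rep("species_observation", 5), "species_observation",
               "photo"),
    stringsAsFactors = FALSE)
  d <- landuse_point_density(pts, landuse)
  g_obs <- d$users_km2[d$class == "grassland" &
                         d$source == "species_observation"]
  expect_equal(g_obs, 5 / 2)
  # u1 appears in both classes and counts in both
  c_obs <- d$users_km2[d$class == "cropland" &
                         d$source == "species_observation"]
  expect_equal(c_obs, 1 / 1)
  g_photo <- d$users_km2[d$class == "grassland" & d$source == "photo"]
  expect_equal(g_photo, 1 / 2)
  expect_true(all(c("all") %in% d$class))
})

test_that("zero-area classes warn and yield the undefined marker", {
  landuse <- list(empty = list())
  pts <- data.frame(x = 1, y = 1, user_id = "u", source = "photo",
                    stringsAsFactors = FALSE)
  w <- capture_warnings(d <- landuse_point_density(pts, landuse))
  expect_true(any(grepl("zero area", w)))
  expect_true(any(is.na(d$users_km2[d$class == "empty"])))
})

test_that("protection shares are per layer and bounded", {
  landuse <- list(grassland = ps_rect(0, 0, 200, 200))
  layers <- list(nature_reserve = ps_rect(0, 0, 100, 100),
                 natura2000 = ps_rect(0, 0, 200, 200),
                 national_interest = ps_rect(1000, 0, 1100, 100))
  s <- landuse_protection_share(landuse, layers)
  get <- function(ly) s$pct[s$layer == ly]
  expect_equal(get("nature_reserve"), 25)
  expect_equal(get("natura2000"), 100)
  expect_equal(get("national_interest"), 0)
})
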