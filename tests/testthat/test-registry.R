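# Farm typology, livestock units, the four selection filters and study-area
# construction.

test_that("the two-thirds specialist rule and 400-hour cutoff classify farms", {
  expect_equal(classify_farm_type(c(dairy_cattle = 800, crops = 100)),
               "dairy_cattle")
  expect_equal(classify_farm_type(c(crops = 350)), "small_scale")
  expect_equal(classify_farm_type(c(crops = 500, dairy_cattle = 400,
                                    pigs = 100)), "mixed_farming")
})

test_that("exact two-thirds shares fall through to the mixed types", {
  # crops exactly 2/3: not a specialist, livestock 1/3: mixed farming
  expect_equal(classify_farm_type(c(crops = 800, sheep = 400)),
               "mixed_farming")
  # cattle (and all livestock) exactly 2/3: neither mixed cattle nor
  # mixed livestock -- every aggregate rule is strict
  expect_equal(classify_farm_type(c(dairy_cattle = 400, meat_cattle = 400,
                                    crops = 400)), "mixed_farming")
})

test_that("cattle and livestock aggregates give the mixed types", {
  expect_equal(classify_farm_type(c(dairy_cattle = 500, meat_cattle = 400,
                                    crops = 100)), "mixed_cattle")
  expect_equal(classify_farm_type(c(sheep = 300, pigs = 300, crops = 200)),
               "mixed_livestock")
  # horse-dominated farms have no specialist type: mixed livestock
  expect_equal(classify_farm_type(c(horses = 900, crops = 100)),
               "mixed_livestock")
})

test_that("classification is scale-invariant above the threshold", {
  h <- c(crops = 500, meat_cattle = 300)
  expect_equal(classify_farm_type(h), classify_farm_type(h * 7))
})

test_that("malformed hour maps are classification errors", {
  expect_error(classify_farm_type(numeric(0)), "classification error")
  expect_error(classify_farm_type(c(fishing = 500)), "classification error")
  expect_error(classify_farm_type(c(crops = -1)), "classification error")
})

test_that("livestock units apply the coefficient table", {
  expect_equal(livestock_units(c(dairy_cow = 10)), 10.0)
  expect_equal(livestock_units(setNames(numeric(0), character(0))), 0.0)
  expect_equal(livestock_units(c(sheep = 50)), 5.0)
  expect_error(livestock_units(c(llama = 3)), "unknown livestock species")
})

# Toy register exercising the four selection filters in order.
toy_register <- function() {
  farms <- data.frame(
    farm_id = c("A", "B", "C", "D", "E"),
    hours_crops = c(100, 500, 100, 600, 600),
    hours_meat_cattle = c(500, 0, 500, 0, 0),
    n_dairy_cow = 0, n_other_cattle = 0, n_sheep = 0, n_horse = 0,
    n_pig = 0, n_poultry = 0, stringsAsFactors = FALSE)
  geoms <- list(ps_rect(0, 0, 200, 200), ps_rect(400, 0, 600, 200),
                ps_rect(800, 0, 1000, 200), ps_rect(0, 400, 200, 600),
                ps_rect(400, 400, 600, 600), ps_rect(800, 400, 1000, 600))
  parcels <- data.frame(
    parcel_id = paste0("P", 1:6),
    farm_id = c("A", "C", "C", "D", "D", "E"),
    land_use = c("semi_natural_grassland", "cropland",
                 "semi_natural_grassland", "cropland", "cropland",
                 "cropland"),
    area_ha = 4, stringsAsFactors = FALSE)
  parcels$geometry <- geoms
  mkseq <- function(pid, miss = integer(0)) {
    cc <- rep("ley", 7); cc[miss] <- NA
    data.frame(parcel_id = pid, year = 1:7, crop_code = cc,
               stringsAsFactors = FALSE)
  }
  # D: one of two equal-area parcels incomplete -> 50% coverage... make it
  # 40% by unequal areas below; here P4 incomplete, P5 complete
  parcels$area_ha[parcels$parcel_id == "P4"] <- 6
  parcels$area_ha[parcels$parcel_id == "P5"] <- 4
  sequences <- rbind(mkseq("P2"), mkseq("P4", miss = 3), mkseq("P5"),
                     mkseq("P6"))
  # C has a horse so filter iii passes for it; A has pasture and no grazers
  farms$n_horse[farms$farm_id == "C"] <- 1
  list(farms = derive_farm_attributes(farms, parcels), parcels = parcels,
       sequences = sequences)
}

test_that("the four selection filters fire in order on the toy register", {
  tr <- toy_register()
  sel <- select_farms(tr$farms, tr$parcels, tr$sequences)
  expect_setequal(sel$farms$farm_id, c("C", "E"))
  log <- setNames(sel$log$rule, sel$log$farm_id)
  expect_equal(unname(log["A"]), "i_no_cropland")
  expect_equal(unname(log["B"]), "ii_no_parcels")
  expect_equal(unname(log["D"]), "iv_incomplete_sequences")
})

test_that("pasture without grazers is excluded, one horse retains the farm", {
  tr <- toy_register()
  tr$farms$n_horse[tr$farms$farm_id == "C"] <- 0
  sel <- select_farms(tr$farms, tr$parcels, tr$sequences)
  expect_equal(sel$log$rule[sel$log$farm_id == "C"],
               "iii_pasture_no_grazers")
})

test_that("selection is independent of input ordering and can be empty", {
  tr <- toy_register()
  perm <- c(4, 2, 5, 1, 3)
  sel1 <- select_farms(tr$farms, tr$parcels, tr$sequences)
  sel2 <- select_farms(tr$farms[perm, , drop = FALSE], tr$parcels,
                       tr$sequences)
  expect_setequal(sel1$farms$farm_id, sel2$farms$farm_id)
  only_a <- tr$farms[tr$farms$farm_id == "A", , drop = FALSE]
  expect_warning(sel3 <- select_farms(only_a, tr$parcels, tr$sequences),
                 "all farms excluded")
  expect_equal(nrow(sel3$farms), 0)
})

test_that("clean registers pass the filters untouched", {
  tr <- toy_register()
  clean <- tr$farms[tr$farms$farm_id %in% c("C", "E"), , drop = FALSE]
  sel <- select_farms(clean, tr$parcels, tr$sequences)
  expect_equal(nrow(sel$log), 0)
  expect_equal(nrow(sel$farms), 2)
})

test_that("study area of one square parcel matches the dilation closed form", {
  sa <- build_study_area(list(ps_rect(0, 0, 100, 100)))
  want_ha <- (10000 + 4 * 100 * 50 + pi * 50^2) / 1e4
  expect_lt(abs(sa$area_ha - want_ha) / want_ha, 0.01)
  expect_equal(unname(sa$centre), c(50, 50))
  expect_gt(sa$area_ha, 1.0)  # strictly exceeds the parcel area
})

test_that("distant parcels give disjoint polygons in one study area", {
  sa <- build_study_area(list(ps_rect(0, 0, 100, 100),
                              ps_rect(1100, 0, 1200, 100)))
  expect_length(sa$polygons, 2)
  # centre is the parcel-area-weighted centroid, not the buffered one
  expect_equal(unname(sa$centre), c((50 + 1150) / 2, 50))
})

test_that("derived attributes aggregate areas and livestock", {
  tr <- toy_register()
  f <- tr$farms
  expect_equal(f$agri_area_ha[f$farm_id == "C"], 8)
  expect_equal(f$cropland_ha[f$farm_id == "C"], 4)
  expect_equal(f$grassland_ha[f$farm_id == "C"], 4)
  expect_equal(f$lsu[f$farm_id == "C"], 0.8)
  expect_equal(f$lsu_density[f$farm_id == "C"], 0.1)
  expect_true(is.na(f$lsu_density[f$farm_id == "B"]))
  expect_equal(f$farm_type[f$farm_id == "A"], "meat_cattle")
})
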