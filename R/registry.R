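# Farm register handling: typology from standardised working hours,
# livestock units, the four selection filters and study-area construction.

#' Enterprise activity vocabulary
#' @return Character vector of activity names used in `hours_<activity>`
#'   register columns.
#' @export
farm_activities <- function() {
  c("crops", "dairy_cattle", "meat_cattle", "sheep", "pigs", "poultry",
    "horses")
}

livestock_activities <- function() setdiff(farm_activities(), "crops")

#' Classify a farm by standardised working hours
#'
#' Farms with fewer than 400 standardised working hours per year are
#' small-scale.  Otherwise a farm is a specialist of an activity if more than
#' two-thirds of its hours are spent on it (a share of exactly two-thirds is
#' not enough).  Dairy plus meat cattle exceeding two-thirds (with neither
#' alone a specialist) gives mixed cattle; any other case where all livestock
#' activities jointly exceed two-thirds gives mixed livestock (this includes
#' horse-dominated farms, which have no specialist type of their own);
#' everything else is mixed farming.
#'
#' @param hours Named numeric vector of hours per activity
#'   (see [farm_activities()]).
#' @return Detailed farm type, one of [farm_types()]`$detailed`.
#' @export
classify_farm_type <- function(hours) {
  if (length(hours) == 0L || is.null(names(hours)))
    stop("classification error: empty or unnamed hours map")
  bad <- setdiff(names(hours), farm_activities())
  if (length(bad) > 0L)
    stop("classification error: unknown activity ", paste(bad, collapse = ", "))
  if (any(hours < 0)) stop("classification error: negative hours")
  total <- sum(hours)
  if (total < 400) return("small_scale")
  share <- hours / total
  spec <- c(crops = "crop_production", dairy_cattle = "dairy_cattle",
            meat_cattle = "meat_cattle", sheep = "sheep", pigs = "pigs",
            poultry = "poultry")
  for (a in names(spec)) {
    if (!is.na(share[a]) && share[a] > 2 / 3) return(unname(spec[a]))
  }
  cattle <- sum(share[intersect(c("dairy_cattle", "meat_cattle"),
                                names(share))], na.rm = TRUE)
  if (cattle > 2 / 3) return("mixed_cattle")
  lvst <- sum(share[intersect(livestock_activities(), names(share))],
              na.rm = TRUE)
  if (lvst > 2 / 3) return("mixed_livestock")
  "mixed_farming"
}

#' Farm type vocabularies
#' @return List with `detailed` and `general` type vectors and the
#'   detailed-to-general mapping `to_general`.
#' @export
farm_types <- function() {
  to_general <- c(crop_production = "crops",
                  dairy_cattle = "ruminants", meat_cattle = "ruminants",
                  mixed_cattle = "ruminants", sheep = "ruminants",
                  pigs = "monogastrics", poultry = "monogastrics",
                  mixed_livestock = "mixed", mixed_farming = "mixed",
                  small_scale = "small_scale")
  list(detailed = names(to_general),
       general = unique(unname(to_general)),
       to_general = to_general)
}

#' Default livestock-unit coefficients
#'
#' Eurostat-style grazing-equivalent coefficients per head.
#' @return Named numeric vector (LSU per head).
#' @export
default_lsu_table <- function() {
  c(dairy_cow = 1.0, other_cattle = 0.6, sheep = 0.1, horse = 0.8,
    pig = 0.3, poultry = 0.014)
}

#' Livestock units of a farm
#'
#' @param counts Named numeric vector of head counts per species.
#' @param table Coefficients, see [default_lsu_table()].
#' @return Total livestock units.
#' @export
livestock_units <- function(counts, table = default_lsu_table()) {
  if (length(counts) == 0L) return(0)
  bad <- setdiff(names(counts), names(table))
  if (length(bad) > 0L)
    stop("unknown livestock species: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative head count")
  sum(counts * table[names(counts)])
}

ruminant_or_horse_species <- function() {
  c("dairy_cow", "other_cattle", "sheep", "horse")
}

#' Derive farm attributes from register and parcels
#'
#' Adds detailed and general farm type, agricultural/cropland/grassland areas
#' (ha), livestock units and livestock density (LSU per ha agricultural
#' land; `NA` when the farm has no parcels).
#'
#' @param farms Register data.frame: `farm_id`, `hours_<activity>` and
#'   `n_<species>` columns.
#' @param parcels Parcel data.frame: `parcel_id`, `farm_id`, `land_use`,
#'   `area_ha`.
#' @param lsu_table Livestock-unit coefficients.
#' @return `farms` with derived columns appended.
#' @export
derive_farm_attributes <- function(farms, parcels,
                                   lsu_table = default_lsu_table()) {
  hcols <- grep("^hours_", names(farms), value = TRUE)
  ncols <- grep("^n_", names(farms), value = TRUE)
  hmat <- as.matrix(farms[, hcols, drop = FALSE])
  colnames(hmat) <- sub("^hours_", "", hcols)
  nmat <- as.matrix(farms[, ncols, drop = FALSE])
  colnames(nmat) <- sub("^n_", "", ncols)
  types <- vapply(seq_len(nrow(farms)), function(i) {
    classify_farm_type(hmat[i, ])
  }, character(1))
  farms$farm_type <- types
  farms$farm_type_general <- unname(farm_types()$to_general[types])
  agg <- function(use) {
    sel <- parcels$land_use == use
    a <- tapply(parcels$area_ha[sel], parcels$farm_id[sel], sum)
    out <- as.numeric(a[match(farms$farm_id, names(a))])
    ifelse(is.na(out), 0, out)
  }
  farms$cropland_ha <- agg("cropland")
  farms$grassland_ha <- agg("semi_natural_grassland")
  farms$agri_area_ha <- farms$cropland_ha + farms$grassland_ha
  farms$lsu <- vapply(seq_len(nrow(farms)), function(i) {
    livestock_units(nmat[i, ], lsu_table)
  }, numeric(1))
  farms$lsu_density <- ifelse(farms$agri_area_ha > 0,
                              farms$lsu / farms$agri_area_ha, NA_real_)
  farms
}

#' Apply the four farm selection filters
#'
#' In order: (i) farms whose parcels include no cropland, (ii) farms with no
#' parcel geometry at all (register entry not matched to the parcel
#' database), (iii) farms with pasture (semi-natural grassland parcels) but
#' no ruminants or horses, and (iv) farms for which complete crop sequences
#' can be derived for less than `coverage` of cropland area.
#'
#' @param farms Farm register (see [derive_farm_attributes()]).
#' @param parcels Parcel table with `farm_id`, `land_use`, `area_ha`,
#'   `parcel_id`.
#' @param sequences Long crop-sequence table: `parcel_id`, `year`,
#'   `crop_code` (`NA` = missing year).
#' @param crop_cfg Crop configuration (for the sequence length).
#' @param coverage Minimum complete-sequence share of cropland area (0.5).
#' @return List with `farms` (included rows) and `log`
#'   (farm_id, rule) for every excluded farm.
#' @export
select_farms <- function(farms, parcels, sequences,
                         crop_cfg = default_crop_config(), coverage = 0.5) {
  has_parcel <- farms$farm_id %in% parcels$farm_id
  crop_ha <- farms$cropland_ha
  rum <- rep(0, nrow(farms))
  for (sp in ruminant_or_horse_species()) {
    col <- paste0("n_", sp)
    if (col %in% names(farms)) rum <- rum + farms[[col]]
  }
  # complete-sequence coverage per farm
  cov <- compute_sequence_coverage(farms$farm_id, parcels, sequences,
                                   crop_cfg$years)
  rule <- rep(NA_character_, nrow(farms))
  rule[is.na(rule) & has_parcel & crop_ha == 0] <- "i_no_cropland"
  rule[is.na(rule) & !has_parcel] <- "ii_no_parcels"
  rule[is.na(rule) & farms$grassland_ha > 0 & rum == 0] <-
    "iii_pasture_no_grazers"
  rule[is.na(rule) & cov < coverage] <- "iv_incomplete_sequences"
  keep <- is.na(rule)
  if (!any(keep)) warning("all farms excluded by selection filters")
  list(farms = farms[keep, , drop = FALSE],
       log = data.frame(farm_id = farms$farm_id[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

compute_sequence_coverage <- function(farm_ids, parcels, sequences, years) {
  crp <- parcels[parcels$land_use == "cropland", , drop = FALSE]
  n_ok <- tapply(!is.na(sequences$crop_code), sequences$parcel_id, sum)
  complete <- names(n_ok)[n_ok == years]
  tot <- tapply(crp$area_ha, crp$farm_id, sum)
  cmp <- tapply(crp$area_ha[crp$parcel_id %in% complete],
                crp$farm_id[crp$parcel_id %in% complete], sum)
  cov <- as.numeric(cmp[match(farm_ids, names(cmp))]) /
    as.numeric(tot[match(farm_ids, names(tot))])
  cov[is.na(cov)] <- 0
  # farms with no cropland: coverage irrelevant, mark as full
  no_crop <- !(farm_ids %in% crp$farm_id)
  cov[no_crop] <- 1
  cov
}

#' Build a farm's study area
#'
#' Union of the farm's parcels dilated by `buffer` metres; the centre point
#' is the area-weighted centroid of the unbuffered parcels.
#'
#' @param parcel_geoms List of parcel polysets (at least one).
#' @param buffer Buffer distance in metres (default 50).
#' @param arc_tolerance Passed to [buffer_region()].
#' @return A `study_area`: list with `polygons` (polyset), `area_ha` and
#'   `centre` (c(x, y)).
#' @export
build_study_area <- function(parcel_geoms, buffer = 50,
                             arc_tolerance = NULL) {
  if (length(parcel_geoms) == 0L) stop("study area needs at least one parcel")
  all_rings <- do.call(c, parcel_geoms)
  polys <- buffer_region(polygons = all_rings, distance = buffer,
                         arc_tolerance = arc_tolerance)
  a <- vapply(parcel_geoms, ps_area, numeric(1))
  cents <- vapply(parcel_geoms, ps_centroid, numeric(2))
  centre <- c(x = sum(cents[1, ] * a) / sum(a),
              y = sum(cents[2, ] * a) / sum(a))
  structure(list(polygons = polys, area_ha = ps_area(polys) / 1e4,
                 centre = centre),
            class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat("<study_area>", length(x$polygons), "ring(s),",
      sprintf("%.2f ha,", x$area_ha),
      sprintf("centre (%.0f, %.0f)\n", x$centre[1], x$centre[2]))
  invisible(x)
}
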