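# The nine farm-level ecosystem-service indicators.
#
# Supply-side indicators evaluated inside each farm's study area (the 50 m
# dilation of its parcels): landscape variation, cropland distance to
# non-cropland, semi-natural grassland, small-scale habitats, crop-sequence
# quality, roadside variation, accessibility (road share + population
# density), visitors (photo + species-observation users) and protected-area
# coverage.

#' Canonical indicator names
#' @return Character vector of the nine indicator columns.
#' @export
indicator_names <- function() {
  c("LanVar", "CrpDst", "Gra", "SSHab", "CrpSeq", "RodVar", "Acc", "Visit",
    "NatRes")
}

#' Landscape variation
#'
#' Total length of borders between land-cover patches of different class
#' within the study area, divided by study-area size.
#'
#' @param study A `study_area`.
#' @param mosaic List of [land_patch()] objects.
#' @return Border density in metres per hectare.
#' @export
lanvar <- function(study, mosaic) {
  shared_border_length(mosaic, study$polygons) / study$area_ha
}

#' Cropland distance to non-cropland
#'
#' Mean distance from cropland interior (regular grid sample) to the nearest
#' non-cropland habitat patch, excluding water and densely built-up areas.
#'
#' @param cropland_geoms List of cropland parcel polysets.
#' @param mosaic List of [land_patch()] objects (the candidate habitats).
#' @param spacing Grid pitch in metres (default 25).
#' @return Mean distance in metres (`NA` if undefined).
#' @export
crpdst <- function(cropland_geoms, mosaic, spacing = 25) {
  if (length(cropland_geoms) == 0L) stop("no cropland parcel")
  target <- do.call(c, cropland_geoms)
  mean_interior_distance(target, mosaic,
                         excluded_classes = c("water", "built_up"),
                         spacing = spacing)
}

#' Semi-natural grassland
#'
#' Grassland area plus grassland area also present in the quality inventory
#' (i.e. inventory overlap weighted by a factor of two), divided by the
#' farm's agricultural area.
#'
#' @param grassland_geoms List of grassland parcel polysets.
#' @param inventory Inventory polyset (may be empty).
#' @param agri_area_ha Farm agricultural area in hectares.
#' @return Weighted grassland share (unitless).
#' @export
gra <- function(grassland_geoms, inventory, agri_area_ha) {
  stopifnot(agri_area_ha > 0)
  if (length(grassland_geoms) == 0L) return(0)
  g <- sum(vapply(grassland_geoms, ps_area, numeric(1))) / 1e4
  i <- sum(vapply(grassland_geoms, function(p) overlay_area(p, inventory),
                  numeric(1))) / 1e4
  (g + i) / agri_area_ha
}

#' Small-scale habitats
#'
#' Number of small-scale habitat points (field islets, clearance cairns, ...)
#' inside cropland, divided by cropland area.
#'
#' @param habitats data.frame with columns `x`, `y`.
#' @param cropland_geoms List of cropland parcel polysets.
#' @param cropland_ha Cropland area in hectares.
#' @return Habitats per hectare (`NA` with a warning when `cropland_ha` is 0).
#' @export
sshab <- function(habitats, cropland_geoms, cropland_ha) {
  if (cropland_ha <= 0) {
    warning("zero cropland: small-scale habitat density undefined")
    return(NA_real_)
  }
  if (nrow(habitats) == 0L) return(0)
  target <- do.call(c, cropland_geoms)
  bb <- ps_bbox(target)
  sel <- habitats$x >= bb[1] & habitats$x <= bb[3] &
    habitats$y >= bb[2] & habitats$y <= bb[4]
  if (!any(sel)) return(0)
  inside <- point_in_ps(habitats$x[sel], habitats$y[sel], target)
  sum(inside) / cropland_ha
}

#' Roadside variation
#'
#' Number of distinct land-cover patches inside the study area that touch
#' roads dilated by `adjacency_dist`, divided by study-area size.
#'
#' @param mosaic List of [land_patch()] objects.
#' @param roads List of polylines, or NULL when `road_zone` is given.
#' @param study A `study_area`.
#' @param adjacency_dist Dilation distance in metres (default 5).
#' @param road_zone Optional precomputed dilation of the roads.
#' @return Patches per hectare.
#' @export
rodvar <- function(mosaic, roads, study, adjacency_dist = 5,
                   road_zone = NULL) {
  if (is.null(road_zone)) {
    if (length(roads) == 0L) return(0)
    road_zone <- buffer_region(lines = roads, distance = adjacency_dist)
  }
  zone <- ps_intersect(road_zone, study$polygons)
  if (length(zone) == 0L) return(0)
  zb <- ps_bbox(zone)
  n <- 0L
  for (p in mosaic) {
    if (!bbox_overlaps(ps_bbox(p$geometry), zb)) next
    piece <- ps_intersect(p$geometry, study$polygons)
    if (length(piece) == 0L) next
    if (ps_area(ps_intersect(piece, zone)) > 0) n <- n + 1L
  }
  n / study$area_ha
}

#' Accessibility components
#'
#' Share of the study area within `road_dist` of a road, and area-weighted
#' mean population density within `pop_buffer` of the study area.  The two
#' components are z-scaled and summed later, in [scale_indicators()].
#'
#' @param study A `study_area`.
#' @param roads List of polylines, or NULL when `road_buffer` is given.
#' @param pop data.frame of raster cell centres: `x`, `y`, `density`
#'   (persons per km2).
#' @param cell_size Raster cell size in metres.
#' @param road_dist Road-proximity distance in metres (default 100).
#' @param pop_buffer Population buffer in metres (default 10000).
#' @param road_buffer Optional precomputed dilation of the roads.
#' @return Named vector `c(road_share =, pop_density =)`.
#' @export
acc <- function(study, roads, pop, cell_size, road_dist = 100,
                pop_buffer = 10000, road_buffer = NULL) {
  if (is.null(road_buffer)) {
    road_buffer <- if (length(roads) == 0L) list() else
      buffer_region(lines = roads, distance = road_dist)
  }
  road_share <- if (length(road_buffer) == 0L) 0 else
    overlay_area(study$polygons, road_buffer) / (study$area_ha * 1e4)
  pd <- pop_weighted_density(study, pop, cell_size, pop_buffer)
  c(road_share = road_share, pop_density = pd)
}

# Area-weighted mean raster density within a buffer around the study area.
# Cells provably inside/outside the buffer (corner test plus centre-to-
# boundary distance exceeding the cell half-diagonal) take weight cell_area
# or 0; boundary-straddling cells get an exact polygon intersection.
pop_weighted_density <- function(study, pop, cell_size, pop_buffer = 10000) {
  B <- buffer_region(polygons = study$polygons, distance = pop_buffer)
  bb <- ps_bbox(B)
  half <- cell_size / 2
  cand <- which(pop$x >= bb[1] - half & pop$x <= bb[3] + half &
                  pop$y >= bb[2] - half & pop$y <= bb[4] + half)
  if (length(cand) == 0L) return(NA_real_)
  px <- pop$x[cand]; py <- pop$y[cand]
  seg <- ps_segments(B)
  dctr <- dist_points_segments(px, py, seg$x0, seg$y0, seg$x1, seg$y1)
  ctr_in <- point_in_ps(px, py, B)
  corners_in <- point_in_ps(px - half, py - half, B) &
    point_in_ps(px + half, py - half, B) &
    point_in_ps(px - half, py + half, B) &
    point_in_ps(px + half, py + half, B)
  clear <- dctr > half * sqrt(2) * (1 + 1e-9)
  w <- rep(NA_real_, length(cand))
  w[clear & ctr_in & corners_in] <- cell_size^2
  w[clear & !ctr_in] <- 0
  amb <- which(is.na(w))
  # boundary-straddling cells are clipped one by one: batching them into a
  # single boolean call merges edge-touching rectangles into shared rings,
  # which would make the piece-to-cell attribution ambiguous
  for (j in amb) {
    cell <- ps_rect(px[j] - half, py[j] - half, px[j] + half, py[j] + half)
    w[j] <- ps_area(ps_intersect(cell, B))
  }
  if (sum(w) == 0) return(NA_real_)
  sum(w * pop$density[cand]) / sum(w)
}

#' Visitor components
#'
#' Distinct users per source with at least one point inside the study area,
#' divided by study-area size in km2.  The two sources are z-scaled and
#' summed later, in [scale_indicators()].
#'
#' @param points data.frame: `x`, `y`, `user_id`, `source` (`"photo"` or
#'   `"species_observation"`).
#' @param study A `study_area`.
#' @return Named vector `c(photo_users_km2 =, obs_users_km2 =)`.
#' @export
visit <- function(points, study) {
  km2 <- study$area_ha / 100
  counts <- c(photo = 0, species_observation = 0)
  if (nrow(points) > 0L) {
    bb <- ps_bbox(study$polygons)
    sel <- points$x >= bb[1] & points$x <= bb[3] &
      points$y >= bb[2] & points$y <= bb[4]
    pts <- points[sel, , drop = FALSE]
    if (nrow(pts) > 0L) {
      inside <- point_in_ps(pts$x, pts$y, study$polygons)
      pts <- pts[inside, , drop = FALSE]
      for (s in names(counts))
        counts[s] <- length(unique(pts$user_id[pts$source == s]))
    }
  }
  c(photo_users_km2 = unname(counts["photo"]) / km2,
    obs_users_km2 = unname(counts["species_observation"]) / km2)
}

#' Protected-area coverage
#'
#' Sum over the three protection layers of the layer's overlap with the study
#' area, divided by study-area size (layers add, so the ratio can reach 3).
#'
#' @param layers Named list of three polysets (`nature_reserve`,
#'   `natura2000`, `national_interest`).
#' @param study A `study_area`.
#' @return Coverage ratio in `[0, 3]`.
#' @export
natres <- function(layers, study) {
  a <- vapply(layers, function(l) overlay_area(l, study$polygons), numeric(1))
  sum(a) / (study$area_ha * 1e4)
}

#' Compute the raw indicator matrix for a set of farms
#'
#' @param bundle A `landscape_bundle` (see [simulate_landscape()]).
#' @param farms Included farm register rows (see [select_farms()]).
#' @param config Analysis configuration, see [default_analysis_config()].
#' @param indicators Subset of [indicator_names()] to compute (default all).
#' @return List with `raw` (farm x indicator/component data.frame),
#'   `study_areas` (named list of `study_area`) and `centres`/`areas`
#'   data.frames used downstream.
#' @export
compute_indicators <- function(bundle, farms,
                               config = default_analysis_config(),
                               indicators = indicator_names()) {
  stopifnot(all(indicators %in% indicator_names()))
  patches <- bundle$patches
  pb <- vapply(patches, function(p) ps_bbox(p$geometry), numeric(4))
  cls_all <- vapply(patches, `[[`, character(1), "class")
  need_roads <- any(c("Acc", "RodVar") %in% indicators)
  road_buffer <- road_zone <- list()
  rb100 <- rbzone <- NULL
  if (need_roads && length(bundle$roads) > 0L) {
    if ("Acc" %in% indicators) {
      road_buffer <- buffer_region(lines = bundle$roads,
                                   distance = config$road_dist)
      rb100 <- ring_bboxes(road_buffer)
    }
    if ("RodVar" %in% indicators) {
      road_zone <- buffer_region(lines = bundle$roads,
                                 distance = config$road_adjacency)
      rbzone <- ring_bboxes(road_zone)
    }
  }
  inventory <- bundle$inventory
  inv_rb <- if (length(inventory) > 0L) ring_bboxes(inventory) else NULL
  prot_rb <- lapply(bundle$protected, function(l) {
    if (length(l) > 0L) ring_bboxes(l) else NULL
  })
  # segment cache for the interior-distance indicator
  elig_idx <- which(!(cls_all %in% c("cropland", "water", "built_up")))
  seg_cache <- NULL
  if ("CrpDst" %in% indicators)
    seg_cache <- lapply(patches[elig_idx], function(p) ps_segments(p$geometry))
  n <- nrow(farms)
  raw <- data.frame(farm_id = farms$farm_id,
                    lanvar = NA_real_, crpdst = NA_real_, gra = NA_real_,
                    sshab = NA_real_, crpseq = NA_real_, rodvar = NA_real_,
                    road_share = NA_real_, pop_density = NA_real_,
                    photo_users_km2 = NA_real_, obs_users_km2 = NA_real_,
                    natres = NA_real_, stringsAsFactors = FALSE)
  study_areas <- vector("list", n)
  names(study_areas) <- farms$farm_id
  centres <- data.frame(farm_id = farms$farm_id, x = NA_real_, y = NA_real_)
  seq_wide <- sequences_by_parcel(bundle$sequences, config$crop$years)
  for (i in seq_len(n)) {
    fid <- farms$farm_id[i]
    psel <- bundle$parcels$farm_id == fid
    geoms <- bundle$parcels$geometry[psel]
    land_use <- bundle$parcels$land_use[psel]
    areas_ha <- bundle$parcels$area_ha[psel]
    pids <- bundle$parcels$parcel_id[psel]
    study <- build_study_area(geoms, buffer = config$study_buffer)
    study_areas[[i]] <- study
    centres$x[i] <- study$centre[1]; centres$y[i] <- study$centre[2]
    sb <- ps_bbox(study$polygons)
    near <- which(pb[1, ] <= sb[3] & pb[3, ] >= sb[1] &
                    pb[2, ] <= sb[4] & pb[4, ] >= sb[2])
    crop <- land_use == "cropland"
    if (any(c("LanVar", "RodVar") %in% indicators)) {
      pieces <- lapply(near, function(k) {
        ps_intersect(patches[[k]]$geometry, study$polygons)
      })
      keep <- vapply(pieces, length, integer(1)) > 0L
      pieces <- pieces[keep]
      pcls <- cls_all[near][keep]
      if ("LanVar" %in% indicators)
        raw$lanvar[i] <- border_length_pieces(pieces, pcls) / study$area_ha
      if ("RodVar" %in% indicators) {
        zone_local <- if (length(road_zone) == 0L) list() else
          ps_intersect(select_rings(road_zone, rbzone, sb), study$polygons)
        raw$rodvar[i] <- if (length(zone_local) == 0L) 0 else {
          zb <- ps_bbox(zone_local)
          hits <- vapply(pieces, function(pc) {
            bbox_overlaps(ps_bbox(pc), zb) &&
              ps_area(ps_intersect(pc, zone_local)) > 0
          }, logical(1))
          sum(hits) / study$area_ha
        }
      }
    }
    if ("CrpDst" %in% indicators && any(crop))
      raw$crpdst[i] <- crpdst_fast(geoms[crop], pb, elig_idx, seg_cache,
                                   spacing = config$grid_pitch)
    if ("Gra" %in% indicators) {
      inv_local <- if (length(inventory) == 0L) list() else
        select_rings(inventory, inv_rb, sb)
      raw$gra[i] <- gra(geoms[land_use == "semi_natural_grassland"],
                        inv_local, farms$agri_area_ha[i])
    }
    if ("SSHab" %in% indicators)
      raw$sshab[i] <- sshab(bundle$habitats, geoms[crop],
                            farms$cropland_ha[i])
    if ("CrpSeq" %in% indicators && any(crop)) {
      scores <- vapply(pids[crop], function(pid) {
        s <- seq_wide[[pid]]
        if (is.null(s)) NA_real_ else crpseq_parcel(s, config$crop)
      }, numeric(1))
      raw$crpseq[i] <- crpseq_farm(scores, areas_ha[crop],
                                   coverage = config$sequence_coverage)
    }
    if ("Acc" %in% indicators) {
      rb_local <- if (length(road_buffer) == 0L) list() else
        select_rings(road_buffer, rb100, sb)
      a <- acc(study, NULL, bundle$population, bundle$pop_cell_size,
               road_dist = config$road_dist, pop_buffer = config$pop_buffer,
               road_buffer = rb_local)
      raw$road_share[i] <- a["road_share"]
      raw$pop_density[i] <- a["pop_density"]
    }
    if ("Visit" %in% indicators) {
      v <- visit(bundle$visitors, study)
      raw$photo_users_km2[i] <- v["photo_users_km2"]
      raw$obs_users_km2[i] <- v["obs_users_km2"]
    }
    if ("NatRes" %in% indicators) {
      layers_local <- lapply(names(bundle$protected), function(nm) {
        l <- bundle$protected[[nm]]
        if (length(l) == 0L) list() else select_rings(l, prot_rb[[nm]], sb)
      })
      raw$natres[i] <- natres(layers_local, study)
    }
  }
  areas <- data.frame(farm_id = farms$farm_id,
                      agri_area_ha = farms$agri_area_ha)
  list(raw = raw, study_areas = study_areas, centres = centres,
       areas = areas)
}

sequences_by_parcel <- function(sequences, years) {
  if (is.null(sequences) || nrow(sequences) == 0L) return(list())
  split(sequences$crop_code[order(sequences$parcel_id, sequences$year)],
        sequences$parcel_id[order(sequences$parcel_id, sequences$year)])
}

# Different-class border length from patch pieces already clipped to the
# window (the segment-matching route of shared_border_length).
border_length_pieces <- function(pieces, classes, tol = 0.01) {
  border_length_segments(pieces, classes, tol = tol)
}

# crpdst against a precomputed segment cache of eligible habitat patches:
# widen the candidate bounding box until every grid point's nearest found
# habitat is provably nearest overall (patches outside a box expanded by
# `margin` are at least `margin` from every point inside it).
crpdst_fast <- function(cropland_geoms, pb, elig_idx, seg_cache,
                        spacing = 25) {
  if (length(elig_idx) == 0L) {
    warning("no eligible habitat patch; interior distance undefined")
    return(NA_real_)
  }
  target <- do.call(c, cropland_geoms)
  pts <- grid_points(target, spacing)
  if (nrow(pts) == 0L) return(NA_real_)
  tb <- ps_bbox(target)
  margin <- 200
  repeat {
    sel <- which(pb[1, elig_idx] <= tb[3] + margin &
                   pb[3, elig_idx] >= tb[1] - margin &
                   pb[2, elig_idx] <= tb[4] + margin &
                   pb[4, elig_idx] >= tb[2] - margin)
    if (length(sel) > 0L) {
      segs <- seg_cache[sel]
      d <- dist_points_segments(pts$x, pts$y,
                                unlist(lapply(segs, `[[`, "x0")),
                                unlist(lapply(segs, `[[`, "y0")),
                                unlist(lapply(segs, `[[`, "x1")),
                                unlist(lapply(segs, `[[`, "y1")))
      if (max(d) <= margin || length(sel) == length(elig_idx))
        return(mean(d))
    }
    margin <- margin * 4
  }
}

#' z-scale the indicator matrix
#'
#' Column-wise `(x - mean) / sd` over non-missing farms with the population
#' (divide-by-n) standard deviation.  The accessibility and visitor
#' composites are assembled from z-scaled components first and the composite
#' columns are then re-scaled with the rest.  Zero-variance columns scale to
#' all zeros with a warning.
#'
#' @param raw Raw indicator data.frame from [compute_indicators()].
#' @return data.frame `farm_id` plus the scaled [indicator_names()] columns
#'   (columns whose raw values were not computed are dropped).
#' @export
scale_indicators <- function(raw) {
  zcol <- function(x, name) {
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("need >= 2 non-missing farms to scale ", name)
    m <- mean(x[ok])
    s <- sqrt(mean((x[ok] - m)^2))
    if (s == 0) {
      warning("zero variance in ", name, "; scaled column set to 0")
      return(ifelse(ok, 0, NA_real_))
    }
    (x - m) / s
  }
  out <- data.frame(farm_id = raw$farm_id, stringsAsFactors = FALSE)
  base <- c(LanVar = "lanvar", CrpDst = "crpdst", Gra = "gra",
            SSHab = "sshab", CrpSeq = "crpseq", RodVar = "rodvar",
            NatRes = "natres")
  for (nm in names(base)) {
    x <- raw[[base[[nm]]]]
    if (!all(is.na(x))) out[[nm]] <- zcol(x, nm)
  }
  if (!all(is.na(raw$road_share)) || !all(is.na(raw$pop_density))) {
    comp <- zcol(raw$road_share, "road_share") +
      zcol(raw$pop_density, "pop_density")
    out$Acc <- zcol(comp, "Acc")
  }
  if (!all(is.na(raw$photo_users_km2)) || !all(is.na(raw$obs_users_km2))) {
    comp <- zcol(raw$photo_users_km2, "photo_users_km2") +
      zcol(raw$obs_users_km2, "obs_users_km2")
    out$Visit <- zcol(comp, "Visit")
  }
  out[, c("farm_id", intersect(indicator_names(), names(out))),
      drop = FALSE]
}
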