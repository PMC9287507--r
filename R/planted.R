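# Planted group effects: shift one indicator's raw driver for a target farm
# group by a known number of residual standard deviations, so that the
# downstream effect-size machinery can be validated by parameter recovery.

#' Describe a planted effect
#'
#' @param group Target farm group: a detailed farm type (the generator's
#'   ground-truth label).
#' @param indicator One of the nine indicator names whose raw driver the
#'   generator controls: `"Gra"` (land-use conversion), `"SSHab"` (habitat
#'   points), `"Visit"` (visitor users), `"NatRes"` (reserve placement) or
#'   `"LanVar"` (contrast strips).
#' @param delta Standardised shift in units of the indicator's across-farm
#'   raw standard deviation.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(group, indicator, delta) {
  if (!indicator %in% indicator_names())
    stop("vocabulary error: unknown indicator ", indicator)
  supported <- c("Gra", "SSHab", "Visit", "NatRes", "LanVar")
  if (!indicator %in% supported)
    stop("vocabulary error: no planting mechanism for ", indicator,
         " (supported: ", paste(supported, collapse = ", "), ")")
  structure(list(group = group, indicator = indicator, delta = delta),
            class = "planted_effect")
}

#' Apply planted effects to a landscape bundle
#'
#' Shifts the target group's expected raw indicator by approximately
#' `delta` standard deviations (exactly, for `Gra`) and leaves other farms
#' untouched.  A zero `delta` returns the bundle unchanged.
#'
#' @param bundle A `landscape_bundle`.
#' @param effects List of [planted_effect()] objects.
#' @param seed Integer seed for the planting sub-stream.
#' @return The modified bundle (mosaic reassembled when geometry changed).
#' @export
apply_planted_effects <- function(bundle, effects, seed = 1) {
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  geom_changed <- FALSE
  for (e in effects) {
    if (!inherits(e, "planted_effect")) e <- do.call(planted_effect, e)
    if (e$delta == 0) next
    targets <- bundle$farms$farm_id[bundle$farms$intended_type == e$group]
    targets <- intersect(targets, bundle$parcels$farm_id)
    if (length(targets) == 0L)
      stop("planted effect targets no farm (group ", e$group, ")")
    shift <- e$delta * plant_raw_sd(bundle, e$indicator)
    bundle <- with_substream(seed, paste0("planted_", e$indicator), {
      switch(e$indicator,
             Gra = plant_gra(bundle, targets, shift),
             SSHab = plant_sshab(bundle, targets, shift),
             Visit = plant_visit(bundle, targets, shift),
             NatRes = plant_natres(bundle, targets, shift),
             LanVar = plant_lanvar(bundle, targets, shift))
    })
    if (e$indicator %in% c("Gra", "NatRes", "LanVar")) geom_changed <- TRUE
  }
  if (geom_changed) bundle$patches <- assemble_mosaic(bundle)
  bundle
}

# Across-farm raw SD of the indicator before planting.  The shift magnitude
# is interpreted on the analysed population, so the SD is taken over the
# farms that pass the selection filters: farms excluded from analysis (for
# example grass-only holdings, whose Gra can reach the factor-of-two cap)
# must not widen the unit in which the effect is expressed.
plant_raw_sd <- function(bundle, indicator) {
  farms <- derive_farm_attributes(bundle$farms, bundle$parcels)
  sel <- suppressWarnings(
    select_farms(farms, bundle$parcels, bundle$sequences))
  res <- compute_indicators(bundle, sel$farms, indicators = indicator)
  col <- switch(indicator, Gra = "gra", SSHab = "sshab", LanVar = "lanvar",
                NatRes = "natres", Visit = NULL)
  if (indicator == "Visit") {
    # use the per-source user densities jointly: planting shifts both
    x <- res$raw$photo_users_km2 + res$raw$obs_users_km2
  } else x <- res$raw[[col]]
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot plant effect: raw ", indicator, " has no variation")
  s
}

# Split `area_m2` off a rectangular parcel along its longer side; returns
# list(kept_ring, cut_ring) or NULL if the parcel is too small.
split_rect <- function(ps, area_m2) {
  bb <- ps_bbox(ps)
  w <- bb[3] - bb[1]; h <- bb[4] - bb[2]
  tot <- w * h
  if (area_m2 >= tot) return(NULL)
  if (w >= h) {
    cut_w <- area_m2 / h
    list(kept = ps_rect(bb[1], bb[2], bb[3] - cut_w, bb[4]),
         cut = ps_rect(bb[3] - cut_w, bb[2], bb[3], bb[4]))
  } else {
    cut_h <- area_m2 / w
    list(kept = ps_rect(bb[1], bb[2], bb[3], bb[4] - cut_h),
         cut = ps_rect(bb[1], bb[4] - cut_h, bb[3], bb[4]))
  }
}

# Gra: convert cropland to semi-natural grassland (or back, for negative
# shifts).  Conversion leaves total agricultural area unchanged, so the raw
# Gra shift is exactly `convert_area / agri_area` for the untouched-inventory
# case.
plant_gra <- function(bundle, targets, shift) {
  parcels <- bundle$parcels
  next_id <- max(as.integer(sub("^P", "", parcels$parcel_id))) + 1L
  new_rows <- list()
  for (fid in targets) {
    idx <- which(parcels$farm_id == fid)
    A <- sum(parcels$area_ha[idx])
    need_ha <- shift * A  # grassland hectares to add (or remove)
    from_use <- if (need_ha > 0) "cropland" else "semi_natural_grassland"
    to_use <- if (need_ha > 0) "semi_natural_grassland" else "cropland"
    rem <- abs(need_ha)
    cand <- idx[parcels$land_use[idx] == from_use]
    cand <- cand[order(-parcels$area_ha[cand])]
    for (j in cand) {
      if (rem <= 1e-9) break
      aj <- parcels$area_ha[j]
      # keep at least a sliver of the source land use on the farm
      take <- min(rem, aj * 0.9)
      sp <- split_rect(parcels$geometry[[j]], take * 1e4)
      if (is.null(sp)) next
      parcels$geometry[[j]] <- sp$kept
      parcels$area_ha[j] <- ps_area(sp$kept) / 1e4
      pid <- sprintf("P%05d", next_id); next_id <- next_id + 1L
      new_rows[[length(new_rows) + 1L]] <- list(
        parcel_id = pid, farm_id = fid, land_use = to_use,
        area_ha = ps_area(sp$cut) / 1e4, geometry = sp$cut)
      rem <- rem - take
    }
    if (rem > 0.05 * abs(need_ha))
      warning("planted Gra shift truncated for farm ", fid)
  }
  if (length(new_rows) > 0L) {
    add <- data.frame(
      parcel_id = vapply(new_rows, `[[`, character(1), "parcel_id"),
      farm_id = vapply(new_rows, `[[`, character(1), "farm_id"),
      land_use = vapply(new_rows, `[[`, character(1), "land_use"),
      area_ha = vapply(new_rows, `[[`, numeric(1), "area_ha"),
      stringsAsFactors = FALSE)
    add$geometry <- lapply(new_rows, `[[`, "geometry")
    parcels <- rbind(parcels, add)
    # converted-to-cropland slices get a complete ley sequence so sequence
    # coverage cannot drop below the selection threshold
    crop_new <- add$parcel_id[add$land_use == "cropland"]
    if (length(crop_new) > 0L) {
      yrs <- bundle$meta$config$crop$years
      bundle$sequences <- rbind(bundle$sequences, data.frame(
        parcel_id = rep(crop_new, each = yrs),
        year = rep(seq_len(yrs), length(crop_new)),
        crop_code = "ley", stringsAsFactors = FALSE))
    }
  }
  bundle$parcels <- parcels
  bundle
}

plant_sshab <- function(bundle, targets, shift) {
  parcels <- bundle$parcels
  for (fid in targets) {
    idx <- which(parcels$farm_id == fid & parcels$land_use == "cropland")
    if (length(idx) == 0L) next
    crop_ha <- sum(parcels$area_ha[idx])
    n_new <- round(shift * crop_ha)
    if (n_new > 0) {
      pick <- sample(idx, n_new, replace = TRUE,
                     prob = parcels$area_ha[idx])
      xs <- ys <- numeric(n_new)
      for (k in seq_len(n_new)) {
        bb <- ps_bbox(parcels$geometry[[pick[k]]])
        xs[k] <- runif(1, bb[1], bb[3]); ys[k] <- runif(1, bb[2], bb[4])
      }
      bundle$habitats <- rbind(bundle$habitats, data.frame(
        x = xs, y = ys, kind = "field_islet", stringsAsFactors = FALSE))
    } else if (n_new < 0) {
      target <- do.call(c, parcels$geometry[idx])
      inside <- which(point_in_ps(bundle$habitats$x, bundle$habitats$y,
                                  target))
      drop <- head(inside, min(length(inside), -n_new))
      if (length(drop) > 0L)
        bundle$habitats <- bundle$habitats[-drop, , drop = FALSE]
    }
  }
  bundle
}

plant_visit <- function(bundle, targets, shift) {
  cfg <- bundle$meta$config
  parcels <- bundle$parcels
  uid <- 0L
  for (fid in targets) {
    idx <- which(parcels$farm_id == fid)
    study <- build_study_area(parcels$geometry[idx],
                              buffer = 50)
    km2 <- study$area_ha / 100
    # split the combined user-density shift evenly over the two sources
    for (src in c("photo", "species_observation")) {
      n_new <- round(shift / 2 * km2)
      if (n_new <= 0) next
      pick <- sample(idx, n_new, replace = TRUE,
                     prob = parcels$area_ha[idx])
      for (k in seq_len(n_new)) {
        bb <- ps_bbox(parcels$geometry[[pick[k]]])
        uid <- uid + 1L
        bundle$visitors <- rbind(bundle$visitors, data.frame(
          x = runif(1, bb[1], bb[3]), y = runif(1, bb[2], bb[4]),
          user_id = sprintf("plant%06d", uid), source = src,
          stringsAsFactors = FALSE))
      }
    }
  }
  bundle
}

plant_natres <- function(bundle, targets, shift) {
  parcels <- bundle$parcels
  add <- list()
  for (fid in targets) {
    idx <- which(parcels$farm_id == fid)
    study <- build_study_area(parcels$geometry[idx], buffer = 50)
    need <- shift * study$area_ha * 1e4
    cand <- idx[order(-parcels$area_ha[idx])]
    for (j in cand) {
      if (need <= 0) break
      aj <- parcels$area_ha[j] * 1e4
      take <- min(need, aj * 0.95)
      sp <- split_rect(parcels$geometry[[j]], take)
      if (is.null(sp)) next
      add <- c(add, sp$cut)
      need <- need - take
    }
  }
  if (length(add) > 0L)
    bundle$protected$nature_reserve <-
      ps_union(c(bundle$protected$nature_reserve, add))
  bundle
}

plant_lanvar <- function(bundle, targets, shift, strip_width = 20) {
  parcels <- bundle$parcels
  for (fid in targets) {
    idx <- which(parcels$farm_id == fid)
    study <- build_study_area(parcels$geometry[idx], buffer = 50)
    need <- shift * study$area_ha  # metres of new border
    cand <- idx[order(-parcels$area_ha[idx])]
    for (j in cand) {
      if (need <= 0) break
      bb <- ps_bbox(parcels$geometry[[j]])
      w <- bb[3] - bb[1]; h <- bb[4] - bb[2]
      if (min(w, h) < 3 * strip_width) next
      len <- min(max(w, h) - 2 * strip_width, need / 2)
      if (len < strip_width) next
      if (w >= h) {
        y0 <- (bb[2] + bb[4]) / 2 - strip_width / 2
        strip <- ps_rect(bb[1] + strip_width, y0,
                         bb[1] + strip_width + len, y0 + strip_width)
      } else {
        x0 <- (bb[1] + bb[3]) / 2 - strip_width / 2
        strip <- ps_rect(x0, bb[2] + strip_width,
                         x0 + strip_width, bb[2] + strip_width + len)
      }
      bundle$strips[[length(bundle$strips) + 1L]] <-
        list(geometry = strip, class = "other_open")
      need <- need - (2 * len + 2 * strip_width)
    }
  }
  bundle
}
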