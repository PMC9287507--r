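# Synthetic landscape and farm-register generator.
#
# Emulates the statistical structure the farm-level analysis assumes: a farm
# register with enterprise hours and livestock, rectangular parcels on a
# lattice (guaranteeing a valid non-overlapping mosaic), a Voronoi matrix of
# forest/water/built-up/open patches, roads, a coarse population raster,
# georeferenced visitor points from two sources, three protected-area layers
# and a grassland quality inventory.  Deterministic given (config, seed);
# every component draws from its own named sub-stream.

#' Default per-farm-type generator parameters
#'
#' Ruminant types get high ley shares and grassland parcels; monogastric
#' types larger parcels and cereal-heavy rotations, so the qualitative
#' contrasts between farm types are reproducible by construction.
#'
#' @return Named list (one entry per detailed farm type) of parameter lists.
#' @export
default_type_params <- function() {
  base <- function(parcel_lambda, area_meanlog, area_sdlog, p_grass,
                   grass_share_lo, grass_share_hi, ley_start, ley_stay,
                   sshab_rate, hours_lo, hours_hi, main_activity,
                   main_share_lo, main_share_hi, livestock) {
    list(parcel_lambda = parcel_lambda, area_meanlog = area_meanlog,
         area_sdlog = area_sdlog, p_grass = p_grass,
         grass_share_lo = grass_share_lo, grass_share_hi = grass_share_hi,
         ley_start = ley_start, ley_stay = ley_stay,
         sshab_rate = sshab_rate, hours_lo = hours_lo, hours_hi = hours_hi,
         main_activity = main_activity, main_share_lo = main_share_lo,
         main_share_hi = main_share_hi, livestock = livestock)
  }
  list(
    crop_production = base(2.5, log(45), 0.7, 0.05, 0.1, 0.2, 0.15, 0.45,
                           0.08, 900, 4000, "crops", 0.75, 0.95,
                           list(horse = c(0, 0.02))),
    dairy_cattle = base(2.5, log(60), 0.6, 0.9, 0.15, 0.35, 0.6, 0.85,
                        0.2, 1500, 6000, "dairy_cattle", 0.72, 0.92,
                        list(dairy_cow = c(0.3, 0.9),
                             other_cattle = c(0.15, 0.5))),
    meat_cattle = base(2.2, log(35), 0.7, 0.9, 0.2, 0.45, 0.6, 0.85,
                       0.25, 700, 2500, "meat_cattle", 0.72, 0.92,
                       list(other_cattle = c(0.3, 1.2))),
    mixed_cattle = base(2.3, log(45), 0.6, 0.9, 0.15, 0.4, 0.6, 0.85,
                        0.2, 1000, 4000, "mixed_cattle", 0, 0,
                        list(dairy_cow = c(0.15, 0.5),
                             other_cattle = c(0.15, 0.7))),
    sheep = base(2.0, log(18), 0.7, 0.9, 0.25, 0.5, 0.55, 0.8,
                 0.25, 500, 1500, "sheep", 0.72, 0.92,
                 list(sheep = c(1, 5))),
    pigs = base(2.2, log(50), 0.6, 0.05, 0.1, 0.2, 0.1, 0.35,
                0.06, 1200, 5000, "pigs", 0.72, 0.92,
                list(pig = c(0.5, 3))),
    poultry = base(2.2, log(40), 0.6, 0.05, 0.1, 0.2, 0.1, 0.35,
                   0.06, 1200, 5000, "poultry", 0.72, 0.92,
                   list(poultry = c(30, 300))),
    mixed_livestock = base(2.2, log(30), 0.6, 0.8, 0.2, 0.45, 0.55, 0.8,
                           0.22, 800, 2500, "mixed_livestock", 0, 0,
                           list(other_cattle = c(0.2, 0.6),
                                sheep = c(0.5, 2))),
    mixed_farming = base(2.5, log(40), 0.7, 0.6, 0.1, 0.3, 0.4, 0.65,
                         0.15, 900, 3000, "mixed_farming", 0, 0,
                         list(other_cattle = c(0.1, 0.5))),
    small_scale = base(1.2, log(8), 0.6, 0.5, 0.2, 0.5, 0.5, 0.75,
                       0.3, 120, 390, "crops", 0.4, 0.9,
                       list(horse = c(0.05, 0.3)))
  )
}

#' Default simulation configuration
#'
#' World extent, farm-type mixture, per-type parameters, matrix-mosaic grain,
#' road density, population surface, visitor intensities, protected-layer
#' coverages and crop vocabulary.  With `homogeneous = TRUE` every farm type
#' shares one parameter set and livestock is drawn independently of the type
#' label, making the label a pure decoration: the exchangeable null used for
#' calibration studies.
#'
#' @param n_farms Number of farms (default 250).
#' @param world World side length in metres (default 30000).
#' @param homogeneous Make all farm types statistically identical.
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(n_farms = 250, world = 30000,
                               homogeneous = FALSE) {
  mix <- c(crop_production = 0.28, dairy_cattle = 0.07, meat_cattle = 0.18,
           mixed_cattle = 0.02, sheep = 0.06, pigs = 0.01, poultry = 0.005,
           mixed_livestock = 0.03, mixed_farming = 0.09,
           small_scale = 0.265)
  tp <- default_type_params()
  if (homogeneous) {
    shared <- tp$mixed_farming
    shared$p_grass <- 0.5
    shared$livestock <- list()  # drawn by the homogeneous rule instead
    for (nm in names(tp)) {
      keep <- tp[[nm]][c("hours_lo", "hours_hi", "main_activity",
                         "main_share_lo", "main_share_hi")]
      tp[[nm]] <- shared
      tp[[nm]][names(keep)] <- keep  # hours still produce the type label
    }
  }
  structure(list(
    world = world, n_farms = n_farms, type_mix = mix / sum(mix),
    type_params = tp, homogeneous = homogeneous,
    lattice = 50,
    matrix_seeds_per_km2 = 0.5,
    matrix_class_mix = c(forest = 0.6, water = 0.08, built_up = 0.05,
                         other_open = 0.27),
    road_density_m_per_km2 = 600,
    pop_cell_size = 1000, pop_base = 15, pop_peak = 1500,
    pop_decay = 6000, pop_noise_sd = 0.4,
    visitor_intensity = c(photo = 0.35, species_observation = 0.5),
    visitor_points_per_user = 3,
    protected_coverage = c(nature_reserve = 0.04, natura2000 = 0.05,
                           national_interest = 0.08),
    inventory_prob = 0.5,
    missing_year_prob = 0.01, bad_farm_frac = 0.05, bad_missing_prob = 0.5,
    crop = default_crop_config()
  ), class = "sim_config")
}

# Named RNG sub-stream: a deterministic seed derived from the global seed and
# a component name, kept below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Generate a synthetic landscape bundle
#'
#' @param config A `sim_config`, see [default_sim_config()].
#' @param seed Integer random seed; recorded in the bundle metadata.
#' @return A `landscape_bundle`: farm register, parcels with 7-year crop
#'   sequences, land-cover mosaic, roads, population raster, visitor points,
#'   protected layers, grassland inventory and small-scale habitat points.
#' @export
simulate_landscape <- function(config = default_sim_config(), seed = 1) {
  if (config$n_farms < 1 || config$world <= 0)
    stop("config error: need at least one farm and a positive world extent")
  W <- config$world
  farms <- with_substream(seed, "farms", gen_farms(config))
  pp <- with_substream(seed, "parcels", gen_parcels(config, farms))
  farms <- gen_livestock(config, farms, pp$parcels, seed)
  tiles <- with_substream(seed, "mosaic", gen_matrix_tiles(config))
  roads <- with_substream(seed, "roads", gen_roads(config))
  population <- with_substream(seed, "population", gen_population(config))
  visitors <- with_substream(seed, "visitors", gen_visitors(config))
  protected <- with_substream(seed, "protected", gen_protected(config))
  inventory <- with_substream(seed, "inventory",
                              gen_inventory(config, pp$parcels))
  habitats <- with_substream(seed, "habitats",
                             gen_habitats(config, farms, pp$parcels))
  sequences <- with_substream(seed, "sequences",
                              gen_sequences(config, farms, pp$parcels))
  bundle <- structure(list(
    world = W, farms = farms, parcels = pp$parcels, sequences = sequences,
    matrix_tiles = tiles, strips = list(), roads = roads,
    population = population, pop_cell_size = config$pop_cell_size,
    visitors = visitors, protected = protected, inventory = inventory,
    habitats = habitats,
    meta = list(seed = seed, config = config)
  ), class = "landscape_bundle")
  bundle$patches <- assemble_mosaic(bundle)
  bundle
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat("<landscape_bundle>", nrow(x$farms), "farms,", nrow(x$parcels),
      "parcels,", length(x$patches), "patches,",
      sprintf("world %.0f x %.0f km\n", x$world / 1000, x$world / 1000))
  invisible(x)
}

gen_farms <- function(config) {
  n <- config$n_farms
  types <- sample(names(config$type_mix), n, replace = TRUE,
                  prob = config$type_mix)
  acts <- farm_activities()
  hours <- matrix(0, nrow = n, ncol = length(acts),
                  dimnames = list(NULL, acts))
  for (i in seq_len(n)) {
    p <- config$type_params[[types[i]]]
    tot <- runif(1, p$hours_lo, p$hours_hi)
    if (types[i] == "mixed_cattle") {
      s <- runif(1, 0.72, 0.92)
      w <- runif(1, 0.35, 0.65)
      hours[i, "dairy_cattle"] <- tot * s * w
      hours[i, "meat_cattle"] <- tot * s * (1 - w)
      hours[i, "crops"] <- tot * (1 - s)
    } else if (types[i] == "mixed_livestock") {
      s <- runif(1, 0.72, 0.92)
      sub <- c("meat_cattle", "sheep", "pigs")
      w <- runif(3); w <- 0.6 * w / sum(w) + 0.13  # no sub-activity > 2/3
      hours[i, sub] <- tot * s * w
      hours[i, "crops"] <- tot * (1 - s)
    } else if (types[i] == "mixed_farming") {
      s <- runif(1, 0.36, 0.62)  # livestock share, neither side > 2/3
      hours[i, "meat_cattle"] <- tot * s
      hours[i, "crops"] <- tot * (1 - s)
    } else {
      s <- runif(1, p$main_share_lo, p$main_share_hi)
      hours[i, p$main_activity] <- tot * s
      rest <- setdiff(c("crops", "meat_cattle"), p$main_activity)[1]
      hours[i, rest] <- tot * (1 - s)
    }
  }
  out <- data.frame(farm_id = sprintf("F%04d", seq_len(n)),
                    intended_type = types, stringsAsFactors = FALSE)
  for (a in acts) out[[paste0("hours_", a)]] <- hours[, a]
  out
}

gen_livestock <- function(config, farms, parcels, seed) {
  with_substream(seed, "livestock", {
    sp <- names(default_lsu_table())
    for (s in sp) farms[[paste0("n_", s)]] <- 0
    grass_ha <- tapply(parcels$area_ha[parcels$land_use ==
                                         "semi_natural_grassland"],
                       parcels$farm_id[parcels$land_use ==
                                         "semi_natural_grassland"], sum)
    agri_ha <- tapply(parcels$area_ha, parcels$farm_id, sum)
    for (i in seq_len(nrow(farms))) {
      fid <- farms$farm_id[i]
      area <- agri_ha[fid]; if (is.na(area)) area <- 0
      has_grass <- !is.na(grass_ha[fid]) && grass_ha[fid] > 0
      if (config$homogeneous) {
        # livestock independent of the type label; grassland implies grazers
        if (has_grass) farms$n_horse[i] <- 1 + rpois(1, 1.5)
        if (runif(1) < 0.2) farms$n_pig[i] <- rpois(1, 25)
      } else {
        lv <- config$type_params[[farms$intended_type[i]]]$livestock
        for (s in names(lv)) {
          dens <- runif(1, lv[[s]][1], lv[[s]][2])
          farms[[paste0("n_", s)]][i] <- round(dens * area)
        }
        # grazed grassland needs grazers: top up with a horse if none
        rum <- farms$n_dairy_cow[i] + farms$n_other_cattle[i] +
          farms$n_sheep[i] + farms$n_horse[i]
        if (has_grass && rum == 0 && runif(1) < 0.95)
          farms$n_horse[i] <- 1 + rpois(1, 1)
      }
    }
    farms
  })
}

# Rectangular parcels on a lattice with a global occupancy grid, so parcels
# never overlap within or across farms.
gen_parcels <- function(config, farms) {
  W <- config$world; L <- config$lattice
  ncell <- floor(W / L)
  occ <- matrix(FALSE, nrow = ncell, ncol = ncell)
  rows <- list()
  pid <- 0L
  margin <- max(2L, ceiling(2000 / L))
  for (i in seq_len(nrow(farms))) {
    p <- config$type_params[[farms$intended_type[i]]]
    cx <- sample(seq(margin, ncell - margin), 1)
    cy <- sample(seq(margin, ncell - margin), 1)
    nparc <- 1L + rpois(1, p$parcel_lambda)
    area_ha <- rlnorm(1, p$area_meanlog, p$area_sdlog)
    grass <- runif(1) < p$p_grass
    gshare <- if (grass) runif(1, p$grass_share_lo, p$grass_share_hi) else 0
    wsplit <- rexp(nparc); wsplit <- wsplit / sum(wsplit)
    land_use <- rep("cropland", nparc)
    if (grass) land_use[which.min(wsplit)] <- "semi_natural_grassland"
    # grassland parcel takes gshare of area, rest split over cropland
    pareas <- if (grass) {
      g <- area_ha * gshare
      rest <- wsplit[land_use == "cropland"]
      out <- numeric(nparc)
      out[land_use == "semi_natural_grassland"] <- g
      out[land_use == "cropland"] <- area_ha * (1 - gshare) *
        rest / sum(rest)
      out
    } else area_ha * wsplit
    for (j in seq_len(nparc)) {
      cells <- max(1L, round(pareas[j] * 1e4 / L^2))
      asp <- runif(1, 0.6, 1.7)
      wc <- max(1L, round(sqrt(cells * asp)))
      hc <- max(1L, ceiling(cells / wc))
      pos <- find_free_block(occ, cx, cy, wc, hc)
      if (is.null(pos)) next
      occ[pos[1]:(pos[1] + hc - 1L), pos[2]:(pos[2] + wc - 1L)] <- TRUE
      pid <- pid + 1L
      x0 <- (pos[2] - 1L) * L; y0 <- (pos[1] - 1L) * L
      rows[[pid]] <- list(parcel_id = sprintf("P%05d", pid),
                          farm_id = farms$farm_id[i],
                          land_use = land_use[j],
                          area_ha = wc * hc * L^2 / 1e4,
                          geometry = ps_rect(x0, y0, x0 + wc * L,
                                             y0 + hc * L))
    }
  }
  parcels <- data.frame(
    parcel_id = vapply(rows, `[[`, character(1), "parcel_id"),
    farm_id = vapply(rows, `[[`, character(1), "farm_id"),
    land_use = vapply(rows, `[[`, character(1), "land_use"),
    area_ha = vapply(rows, `[[`, numeric(1), "area_ha"),
    stringsAsFactors = FALSE)
  parcels$geometry <- lapply(rows, `[[`, "geometry")
  list(parcels = parcels)
}

# Scan an expanding square spiral around (cy, cx) for a free wc x hc block.
find_free_block <- function(occ, cy, cx, wc, hc, max_ring = 60L) {
  n <- nrow(occ)
  for (ring in 0:max_ring) {
    cand <- if (ring == 0L) cbind(cy, cx) else {
      r <- ring
      tops <- cbind(cy - r, (cx - r):(cx + r))
      bots <- cbind(cy + r, (cx - r):(cx + r))
      lefts <- cbind((cy - r + 1):(cy + r - 1), cx - r)
      rights <- cbind((cy - r + 1):(cy + r - 1), cx + r)
      rbind(tops, bots, lefts, rights)
    }
    for (k in seq_len(nrow(cand))) {
      r0 <- cand[k, 1]; c0 <- cand[k, 2]
      if (r0 < 1L || c0 < 1L || r0 + hc - 1L > n || c0 + wc - 1L > n) next
      block <- occ[r0:(r0 + hc - 1L), c0:(c0 + wc - 1L)]
      if (!any(block)) return(c(r0, c0))
    }
  }
  NULL
}

gen_matrix_tiles <- function(config) {
  W <- config$world
  nseed <- max(4L, round(config$matrix_seeds_per_km2 * (W / 1000)^2))
  xs <- runif(nseed, 0, W); ys <- runif(nseed, 0, W)
  dd <- deldir::deldir(xs, ys, rw = c(0, W, 0, W))
  tl <- deldir::tile.list(dd)
  classes <- sample(names(config$matrix_class_mix), nseed, replace = TRUE,
                    prob = config$matrix_class_mix)
  lapply(seq_along(tl), function(k) {
    ring <- orient_ring(list(x = tl[[k]]$x, y = tl[[k]]$y),
                        clockwise = FALSE)
    list(geometry = list(ring), class = classes[k],
         patch_id = sprintf("M%04d", k))
  })
}

# Mosaic: Voronoi matrix tiles minus parcels and planted strips, plus the
# parcels (cropland / semi-natural grassland) and strips as patches.
assemble_mosaic <- function(bundle) {
  parcels <- bundle$parcels
  cut_geoms <- c(parcels$geometry,
                 lapply(bundle$strips, `[[`, "geometry"))
  cut_bb <- vapply(cut_geoms, ps_bbox, numeric(4))
  patches <- list()
  for (tile in bundle$matrix_tiles) {
    g <- tile$geometry
    tb <- ps_bbox(g)
    hit <- which(cut_bb[1, ] <= tb[3] & cut_bb[3, ] >= tb[1] &
                   cut_bb[2, ] <= tb[4] & cut_bb[4, ] >= tb[2])
    if (length(hit) > 0L)
      g <- ps_minus(g, do.call(c, cut_geoms[hit]))
    if (length(g) == 0L || ps_area(g) < 1) next
    patches[[length(patches) + 1L]] <-
      land_patch(g, tile$class, tile$patch_id)
  }
  for (i in seq_len(nrow(parcels))) {
    patches[[length(patches) + 1L]] <-
      land_patch(parcels$geometry[[i]], parcels$land_use[i],
                 parcels$parcel_id[i])
  }
  for (i in seq_along(bundle$strips)) {
    s <- bundle$strips[[i]]
    patches[[length(patches) + 1L]] <-
      land_patch(s$geometry, s$class, sprintf("S%04d", i))
  }
  patches
}

gen_roads <- function(config) {
  W <- config$world
  target <- config$road_density_m_per_km2 * (W / 1000)^2
  roads <- list()
  total <- 0
  while (total < target) {
    horizontal <- runif(1) < 0.5
    a <- runif(1, 0, W)
    xs <- seq(0, W, by = 2000)
    jit <- cumsum(rnorm(length(xs), 0, 300))
    line <- if (horizontal) list(x = xs, y = pmin(W, pmax(0, a + jit)))
    else list(x = pmin(W, pmax(0, a + jit)), y = xs)
    roads[[length(roads) + 1L]] <- line
    total <- total + sum(sqrt(diff(line$x)^2 + diff(line$y)^2))
  }
  roads
}

gen_population <- function(config) {
  W <- config$world; cs <- config$pop_cell_size
  ctr <- seq(cs / 2, W, by = cs)
  g <- expand.grid(x = ctr, y = ctr, KEEP.OUT.ATTRS = FALSE)
  ux <- runif(1, 0.25 * W, 0.75 * W); uy <- runif(1, 0.25 * W, 0.75 * W)
  d2 <- (g$x - ux)^2 + (g$y - uy)^2
  dens <- config$pop_base + config$pop_peak *
    exp(-d2 / (2 * config$pop_decay^2))
  dens <- dens * rlnorm(nrow(g), 0, config$pop_noise_sd)
  data.frame(x = g$x, y = g$y, density = dens)
}

gen_visitors <- function(config) {
  W <- config$world
  km2 <- (W / 1000)^2
  out <- list()
  for (src in names(config$visitor_intensity)) {
    npts <- rpois(1, config$visitor_intensity[[src]] * km2)
    if (npts == 0L) next
    nusers <- max(1L, round(npts / config$visitor_points_per_user))
    uprob <- 1 / seq_len(nusers)  # a few prolific users, many casual
    out[[src]] <- data.frame(
      x = runif(npts, 0, W), y = runif(npts, 0, W),
      user_id = paste0(substr(src, 1, 3),
                       sample(nusers, npts, replace = TRUE, prob = uprob)),
      source = src, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      user_id = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

gen_protected <- function(config) {
  W <- config$world
  out <- list()
  for (layer in names(config$protected_coverage)) {
    target <- config$protected_coverage[[layer]] * W^2
    polys <- list()
    tot <- 0
    while (tot < target) {
      a <- rlnorm(1, log(8e5), 0.8)  # patch ~ 0.8 km2
      w <- sqrt(a * runif(1, 0.5, 2))
      h <- a / w
      x0 <- runif(1, 0, W - w); y0 <- runif(1, 0, W - h)
      polys <- c(polys, ps_rect(x0, y0, x0 + w, y0 + h))
      tot <- tot + a
    }
    out[[layer]] <- ps_union(polys)
  }
  out
}

gen_inventory <- function(config, parcels) {
  sel <- which(parcels$land_use == "semi_natural_grassland")
  polys <- list()
  for (i in sel) {
    if (runif(1) > config$inventory_prob) next
    bb <- ps_bbox(parcels$geometry[[i]])
    f <- runif(1, 0.6, 1)
    w <- (bb[3] - bb[1]) * sqrt(f); h <- (bb[4] - bb[2]) * sqrt(f)
    x0 <- runif(1, bb[1], bb[3] - w); y0 <- runif(1, bb[2], bb[4] - h)
    polys <- c(polys, ps_rect(x0, y0, x0 + w, y0 + h))
  }
  if (length(polys) == 0L) return(list())
  ps_union(polys)
}

gen_habitats <- function(config, farms, parcels) {
  xs <- numeric(0); ys <- numeric(0); kind <- character(0)
  kinds <- c("field_islet", "clearance_cairn", "stone_wall")
  rate <- vapply(farms$intended_type, function(t)
    config$type_params[[t]]$sshab_rate, numeric(1))
  names(rate) <- farms$farm_id
  sel <- which(parcels$land_use == "cropland")
  for (i in sel) {
    lam <- rate[parcels$farm_id[i]] * parcels$area_ha[i]
    k <- rpois(1, lam)
    if (k == 0L) next
    bb <- ps_bbox(parcels$geometry[[i]])
    xs <- c(xs, runif(k, bb[1], bb[3]))
    ys <- c(ys, runif(k, bb[2], bb[4]))
    kind <- c(kind, sample(kinds, k, replace = TRUE))
  }
  data.frame(x = xs, y = ys, kind = kind, stringsAsFactors = FALSE)
}

gen_sequences <- function(config, farms, parcels) {
  crops <- config$crop$crops
  others <- setdiff(crops, "ley")
  years <- config$crop$years
  type_of <- setNames(farms$intended_type, farms$farm_id)
  bad <- setNames(runif(nrow(farms)) < config$bad_farm_frac, farms$farm_id)
  sel <- which(parcels$land_use == "cropland")
  res <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    p <- config$type_params[[type_of[parcels$farm_id[i]]]]
    seqv <- character(years)
    state <- if (runif(1) < p$ley_start) "ley"
    else sample(others, 1)
    seqv[1] <- state
    for (t in 2:years) {
      if (state == "ley") {
        state <- if (runif(1) < p$ley_stay) "ley" else sample(others, 1)
      } else {
        state <- if (runif(1) < p$ley_start * 0.5) "ley"
        else sample(others, 1)
      }
      seqv[t] <- state
    }
    mp <- if (bad[parcels$farm_id[i]]) config$bad_missing_prob
    else config$missing_year_prob
    miss <- runif(years) < mp
    seqv[miss] <- NA_character_
    res[[k]] <- data.frame(parcel_id = parcels$parcel_id[i],
                           year = seq_len(years), crop_code = seqv,
                           stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(parcel_id = character(0), year = integer(0),
                      crop_code = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
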