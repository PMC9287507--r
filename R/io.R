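# GeoJSON and bundle I/O.  Geometries live on a planar metric plane; GeoJSON
# is used purely as a container format (no CRS handling).

ring_close <- function(r) {
  cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
}

# Group a polyset's rings into GeoJSON MultiPolygon coordinates: positive
# rings are outers, negative rings become holes of the outer containing them.
ps_to_multipolygon <- function(ps) {
  areas <- vapply(ps, ring_signed_area, numeric(1))
  outers <- which(areas > 0)
  holes <- which(areas < 0)
  if (length(outers) == 0L) { outers <- seq_along(ps); holes <- integer(0) }
  polys <- lapply(outers, function(i) list(ring_close(ps[[i]])))
  for (h in holes) {
    px <- ps[[h]]$x[1]; py <- ps[[h]]$y[1]
    owner <- NULL; owner_area <- Inf
    for (k in seq_along(outers)) {
      o <- outers[k]
      if (point_in_ps(px, py, ps[o]) && abs(areas[o]) < owner_area) {
        owner <- k; owner_area <- abs(areas[o])
      }
    }
    if (is.null(owner)) owner <- 1L
    polys[[owner]][[length(polys[[owner]]) + 1L]] <- ring_close(ps[[h]])
  }
  polys
}

multipolygon_to_ps <- function(coords) {
  ps <- list()
  for (poly in coords) {
    for (k in seq_along(poly)) {
      m <- poly[[k]]
      if (is.list(m)) m <- do.call(rbind, m)
      n <- nrow(m)
      if (all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
      ps[[length(ps) + 1L]] <- orient_ring(list(x = m[, 1], y = m[, 2]),
                                           clockwise = k > 1L)
    }
  }
  ps
}

geom_to_list <- function(geometry, type) {
  switch(type,
         multipolygon = list(type = "MultiPolygon",
                             coordinates = ps_to_multipolygon(geometry)),
         linestring = list(type = "LineString",
                           coordinates = cbind(geometry$x, geometry$y)),
         point = list(type = "Point",
                      coordinates = c(geometry$x, geometry$y)))
}

#' Write features to a GeoJSON FeatureCollection
#'
#' @param features List of features, each `list(geometry =, type =,
#'   properties =)` with `type` one of `"multipolygon"`, `"linestring"`,
#'   `"point"`; multipolygon geometries are polysets.
#' @param path Output file.
#' @export
write_geojson <- function(features, path) {
  feats <- lapply(features, function(f) {
    list(type = "Feature",
         geometry = geom_to_list(f$geometry, f$type),
         properties = if (length(f$properties) == 0L) NULL else f$properties)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file.
#' @return List of features: `list(geometry =, type =, properties =)`;
#'   multipolygon geometries come back as polysets.
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  # whole-number coordinates parse as integers; force doubles so later
  # arithmetic (e.g. shoelace sums) cannot overflow
  num <- function(v) as.numeric(unlist(v))
  lapply(obj$features, function(f) {
    g <- f$geometry
    co <- g$coordinates
    out <- switch(tolower(g$type),
      multipolygon = {
        coords <- lapply(co, function(poly) {
          lapply(poly, function(ring) {
            do.call(rbind, lapply(ring, num))
          })
        })
        list(geometry = multipolygon_to_ps(coords), type = "multipolygon")
      },
      polygon = {
        coords <- list(lapply(co, function(ring) {
          do.call(rbind, lapply(ring, num))
        }))
        list(geometry = multipolygon_to_ps(coords), type = "multipolygon")
      },
      linestring = {
        m <- do.call(rbind, lapply(co, num))
        list(geometry = list(x = m[, 1], y = m[, 2]), type = "linestring")
      },
      point = list(geometry = list(x = num(co[[1]]), y = num(co[[2]])),
                   type = "point"),
      stop("unsupported GeoJSON geometry type: ", g$type))
    out$properties <- f$properties
    out
  })
}

matrix_to_meta <- function(m) {
  list(rows = rownames(m), cols = colnames(m), data = as.vector(m))
}

meta_to_matrix <- function(l) {
  matrix(unlist(l$data), nrow = length(l$rows),
         dimnames = list(unlist(l$rows), unlist(l$cols)))
}

#' Write a landscape bundle to a directory
#'
#' Writes `landcover.geojson`, `roads.geojson`, `parcels.geojson`,
#' `protected_<layer>.geojson`, `inventory.geojson`, `visitors.geojson`,
#' `habitats.geojson`, `population.csv`, `farms.csv`, `crop_sequences.csv`
#' and `meta.yaml` (config + seed).  Creates the directory if needed.
#'
#' @param bundle A `landscape_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  fp <- function(x) file.path(dir, x)
  write_geojson(lapply(bundle$patches, function(p) {
    list(geometry = p$geometry, type = "multipolygon",
         properties = list(class = p$class, patch_id = p$patch_id))
  }), fp("landcover.geojson"))
  write_geojson(lapply(seq_along(bundle$roads), function(i) {
    list(geometry = bundle$roads[[i]], type = "linestring",
         properties = list(road_id = sprintf("R%03d", i)))
  }), fp("roads.geojson"))
  write_geojson(lapply(seq_len(nrow(bundle$parcels)), function(i) {
    list(geometry = bundle$parcels$geometry[[i]], type = "multipolygon",
         properties = list(parcel_id = bundle$parcels$parcel_id[i],
                           farm_id = bundle$parcels$farm_id[i],
                           land_use = bundle$parcels$land_use[i]))
  }), fp("parcels.geojson"))
  for (layer in names(bundle$protected)) {
    g <- bundle$protected[[layer]]
    feats <- if (length(g) == 0L) list() else
      list(list(geometry = g, type = "multipolygon",
                properties = list(layer = layer)))
    write_geojson(feats, fp(paste0("protected_", layer, ".geojson")))
  }
  inv <- if (length(bundle$inventory) == 0L) list() else
    list(list(geometry = bundle$inventory, type = "multipolygon",
              properties = list()))
  write_geojson(inv, fp("inventory.geojson"))
  write_geojson(lapply(seq_len(nrow(bundle$visitors)), function(i) {
    list(geometry = list(x = bundle$visitors$x[i], y = bundle$visitors$y[i]),
         type = "point",
         properties = list(user_id = bundle$visitors$user_id[i],
                           source = bundle$visitors$source[i]))
  }), fp("visitors.geojson"))
  write_geojson(lapply(seq_len(nrow(bundle$habitats)), function(i) {
    list(geometry = list(x = bundle$habitats$x[i], y = bundle$habitats$y[i]),
         type = "point",
         properties = list(kind = bundle$habitats$kind[i]))
  }), fp("habitats.geojson"))
  write.csv(bundle$population, fp("population.csv"), row.names = FALSE)
  farms <- bundle$farms
  write.csv(farms, fp("farms.csv"), row.names = FALSE)
  write.csv(bundle$sequences, fp("crop_sequences.csv"), row.names = FALSE)
  cfg <- bundle$meta$config
  cfg$crop$S <- matrix_to_meta(cfg$crop$S)
  yaml::write_yaml(list(seed = bundle$meta$seed,
                        world = bundle$world,
                        pop_cell_size = bundle$pop_cell_size,
                        config = unclass(cfg)),
                   fp("meta.yaml"))
  invisible(dir)
}

#' Read a landscape bundle from a directory
#'
#' Inverse of [write_bundle()] for the bundle's external interface (the
#' internal Voronoi tiles are not round-tripped; the mosaic is read back as
#' patches).
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `landscape_bundle`.
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir)
  fp <- function(x) file.path(dir, x)
  meta <- yaml::read_yaml(fp("meta.yaml"))
  cfg <- meta$config
  cfg$crop$S <- meta_to_matrix(cfg$crop$S)
  cfg$crop$R <- unlist(cfg$crop$R)
  cfg$crop$weights <- unlist(cfg$crop$weights)
  cfg$crop$crops <- unlist(cfg$crop$crops)
  for (nm in c("type_mix", "matrix_class_mix", "visitor_intensity",
               "protected_coverage")) cfg[[nm]] <- unlist(cfg[[nm]])
  class(cfg) <- "sim_config"
  patches <- lapply(read_geojson(fp("landcover.geojson")), function(f) {
    land_patch(f$geometry, f$properties$class, f$properties$patch_id)
  })
  roads <- lapply(read_geojson(fp("roads.geojson")), `[[`, "geometry")
  pfeat <- read_geojson(fp("parcels.geojson"))
  parcels <- data.frame(
    parcel_id = vapply(pfeat, function(f) f$properties$parcel_id,
                       character(1)),
    farm_id = vapply(pfeat, function(f) f$properties$farm_id, character(1)),
    land_use = vapply(pfeat, function(f) f$properties$land_use,
                      character(1)),
    stringsAsFactors = FALSE)
  parcels$geometry <- lapply(pfeat, `[[`, "geometry")
  parcels$area_ha <- vapply(parcels$geometry, ps_area, numeric(1)) / 1e4
  parcels <- parcels[, c("parcel_id", "farm_id", "land_use", "area_ha",
                         "geometry")]
  protected <- list()
  for (layer in c("nature_reserve", "natura2000", "national_interest")) {
    f <- read_geojson(fp(paste0("protected_", layer, ".geojson")))
    protected[[layer]] <- if (length(f) == 0L) list() else f[[1]]$geometry
  }
  invf <- read_geojson(fp("inventory.geojson"))
  inventory <- if (length(invf) == 0L) list() else invf[[1]]$geometry
  vfeat <- read_geojson(fp("visitors.geojson"))
  visitors <- data.frame(
    x = vapply(vfeat, function(f) f$geometry$x, numeric(1)),
    y = vapply(vfeat, function(f) f$geometry$y, numeric(1)),
    user_id = vapply(vfeat, function(f) f$properties$user_id, character(1)),
    source = vapply(vfeat, function(f) f$properties$source, character(1)),
    stringsAsFactors = FALSE)
  hfeat <- read_geojson(fp("habitats.geojson"))
  habitats <- data.frame(
    x = vapply(hfeat, function(f) f$geometry$x, numeric(1)),
    y = vapply(hfeat, function(f) f$geometry$y, numeric(1)),
    kind = vapply(hfeat, function(f) f$properties$kind, character(1)),
    stringsAsFactors = FALSE)
  farms <- read.csv(fp("farms.csv"), stringsAsFactors = FALSE)
  sequences <- read.csv(fp("crop_sequences.csv"), stringsAsFactors = FALSE)
  structure(list(
    world = meta$world, farms = farms, parcels = parcels,
    sequences = sequences, matrix_tiles = NULL, strips = list(),
    roads = roads, population = read.csv(fp("population.csv")),
    pop_cell_size = meta$pop_cell_size, visitors = visitors,
    protected = protected, inventory = inventory, habitats = habitats,
    patches = patches,
    meta = list(seed = meta$seed, config = cfg)
  ), class = "landscape_bundle")
}
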