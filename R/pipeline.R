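# Analysis configuration and the staged pipeline
# (simulate -> select -> indicators -> cluster -> compare -> screen -> map).

#' Default analysis configuration
#'
#' All analysis constants with their standard values: 50 m study buffer,
#' 100 m road band, 10 km population buffer, 20 km reference radius,
#' alpha = 0.01, strong-correlation threshold 0.5, >20-farm cluster
#' retention, five size clusters, 15 km grid with 80th/20th percentiles,
#' 7-year sequences with a 50% coverage threshold, 5 m road adjacency, 25 m
#' interior-distance grid pitch, plus the crop configuration, livestock-unit
#' table and indicator priority list.
#'
#' @return An `analysis_config` list.
#' @export
default_analysis_config <- function() {
  structure(list(
    study_buffer = 50, road_dist = 100, pop_buffer = 10000,
    radius = 20000, alpha = 0.01,
    strong_threshold = 0.5, moderate_threshold = 0.3,
    min_cluster_n = 20, target_density_clusters = 4, density_k_max = 12,
    size_clusters = 5, grid_cell = 15000, pct_hi = 0.80, pct_lo = 0.20,
    sequence_coverage = 0.5, road_adjacency = 5, grid_pitch = 25,
    type_level = "detailed", p_adjust = "none",
    crop = default_crop_config(), lsu = as.list(default_lsu_table()),
    priority = default_indicator_priority()
  ), class = "analysis_config")
}

analysis_config_from <- function(x) {
  cfg <- default_analysis_config()
  for (nm in names(x)) {
    if (nm == "crop") {
      for (cn in names(x$crop)) cfg$crop[[cn]] <- x$crop[[cn]]
    } else cfg[[nm]] <- x[[nm]]
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema-checks a pipeline configuration (YAML path or list) and reports
#' every analysis constant deviating from the package defaults.  Deviations
#' are reported, not fatal; structural problems (negative distances,
#' malformed sections) are errors.
#'
#' @param config YAML file path or configuration list.
#' @return List with `ok`, `deviations` (data.frame) and the normalised
#'   `config`.
#' @export
validate_config <- function(config) {
  cfg <- normalize_pipeline_config(config)
  a <- cfg$analysis
  defaults <- default_analysis_config()
  pos <- c("study_buffer", "road_dist", "pop_buffer", "radius", "alpha",
           "strong_threshold", "min_cluster_n", "size_clusters",
           "grid_cell", "pct_hi", "pct_lo", "sequence_coverage",
           "grid_pitch")
  for (nm in pos) {
    v <- a[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("schema error: ", nm, " must be a positive number")
  }
  if (a$road_adjacency < 0)
    stop("schema error: road_adjacency must be non-negative")
  scalars <- setdiff(names(defaults), c("crop", "lsu", "priority"))
  dev <- list()
  for (nm in scalars) {
    if (!identical(a[[nm]], defaults[[nm]]))
      dev[[length(dev) + 1L]] <- data.frame(
        constant = nm, value = paste(a[[nm]], collapse = ","),
        default = paste(defaults[[nm]], collapse = ","),
        stringsAsFactors = FALSE)
  }
  deviations <- if (length(dev) > 0L) do.call(rbind, dev) else
    data.frame(constant = character(0), value = character(0),
               default = character(0))
  list(ok = TRUE, deviations = deviations, config = cfg)
}

# A pipeline config has sections: seed, sim (generator), analysis.
normalize_pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  sim_over <- config$sim
  sim <- default_sim_config(
    n_farms = if (!is.null(sim_over$n_farms)) sim_over$n_farms else 250,
    world = if (!is.null(sim_over$world)) sim_over$world else 30000,
    homogeneous = isTRUE(sim_over$homogeneous))
  for (nm in setdiff(names(sim_over), c("n_farms", "world", "homogeneous")))
    sim[[nm]] <- sim_over[[nm]]
  analysis <- analysis_config_from(config$analysis)
  list(seed = if (!is.null(config$seed)) config$seed else 1,
       sim = sim, analysis = analysis)
}

pipeline_stages <- function() {
  c("simulate", "select", "indicators", "cluster", "compare", "screen",
    "map")
}

dependency_error <- function(artefact, stage, needed_by) {
  stop("dependency error: missing artefact '", artefact,
       "' (produced by stage '", stage, "', needed by '", needed_by,
       "'); run the earlier stage first", call. = FALSE)
}

scheme_file_tag <- function(scheme) gsub("[^a-z_]", "_", tolower(scheme))

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' artefacts under `out` plus a manifest with file checksums.  Reruns with
#' the same configuration and seed are byte-identical.  Later stages resume
#' from artefacts on disk when earlier stages are not part of `stages`.
#'
#' @param config Pipeline configuration: YAML path, list, or NULL for
#'   defaults (sections `seed`, `sim`, `analysis`).
#' @param out Output directory.
#' @param stages Character vector of stages (see `farmscapes:::pipeline_stages`)
#'   or `"all"`.
#' @param seed Optional seed overriding the configuration's.
#' @return Invisibly, a list with the in-memory state of the final stages.
#' @export
run_pipeline <- function(config = NULL, out = "farmscapes_out",
                         stages = "all", seed = NULL) {
  cfg <- validate_config(config)$config
  if (!is.null(seed)) cfg$seed <- seed
  if (identical(stages, "all")) stages <- pipeline_stages()
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  manifest <- list(seed = cfg$seed, stages = list())
  fp <- function(x) file.path(out, x)

  need_bundle <- function(stage) {
    if (!is.null(st$bundle)) return(st$bundle)
    if (!file.exists(fp("bundle/meta.yaml")))
      dependency_error("bundle/", "simulate", stage)
    st$bundle <- read_bundle(fp("bundle"))
    st$bundle
  }
  need_farms <- function(stage) {
    if (!is.null(st$farms)) return(st$farms)
    if (!file.exists(fp("farms_included.csv")))
      dependency_error("farms_included.csv", "select", stage)
    st$farms <- read.csv(fp("farms_included.csv"), stringsAsFactors = FALSE)
    st$farms
  }
  need_indicators <- function(stage) {
    if (is.null(st$scaled)) {
      if (!file.exists(fp("indicators_scaled.csv")))
        dependency_error("indicators_scaled.csv", "indicators", stage)
      st$scaled <- read.csv(fp("indicators_scaled.csv"),
                            stringsAsFactors = FALSE)
      cen <- read.csv(fp("farm_centres.csv"), stringsAsFactors = FALSE)
      st$centres <- cen[, c("farm_id", "x", "y")]
      st$areas <- cen[, c("farm_id", "agri_area_ha")]
    }
    invisible(NULL)
  }
  need_assignments <- function(stage) {
    if (!is.null(st$assignments)) return(st$assignments)
    # the grouping step is deterministic given the farm table and the
    # configuration, so a resumed run rebuilds it rather than reparsing the
    # CSVs; the artefact check still enforces the stage order
    if (length(list.files(out, pattern = "^clusters_.*\\.csv$")) == 0L)
      dependency_error("clusters_*.csv", "cluster", stage)
    st$assignments <- build_assignments(need_farms(stage), cfg$analysis)
    st$assignments
  }
  log_stage <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = as.list(setNames(unname(tools::md5sum(fp(files))), files)))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      st$bundle <- simulate_landscape(cfg$sim, seed = cfg$seed)
      write_bundle(st$bundle, fp("bundle"))
      log_stage("simulate", file.path("bundle", c("farms.csv", "meta.yaml",
                                                  "parcels.geojson")))
    } else if (stage == "select") {
      bundle <- need_bundle("select")
      farms <- derive_farm_attributes(bundle$farms, bundle$parcels,
                                      unlist(cfg$analysis$lsu))
      sel <- select_farms(farms, bundle$parcels, bundle$sequences,
                          cfg$analysis$crop, cfg$analysis$sequence_coverage)
      st$farms <- sel$farms
      write.csv(sel$farms[, setdiff(names(sel$farms), "geometry")],
                fp("farms_included.csv"), row.names = FALSE)
      write.csv(sel$log, fp("farms_excluded.csv"), row.names = FALSE)
      log_stage("select", c("farms_included.csv", "farms_excluded.csv"))
    } else if (stage == "indicators") {
      bundle <- need_bundle("indicators")
      farms <- need_farms("indicators")
      res <- compute_indicators(bundle, farms, cfg$analysis)
      st$raw <- res$raw
      st$centres <- res$centres
      st$areas <- res$areas
      st$study_areas <- res$study_areas
      st$scaled <- scale_indicators(res$raw)
      write.csv(st$raw, fp("indicators_raw.csv"), row.names = FALSE)
      write.csv(st$scaled, fp("indicators_scaled.csv"), row.names = FALSE)
      cen <- merge(res$centres, res$areas, by = "farm_id", sort = TRUE)
      write.csv(cen, fp("farm_centres.csv"), row.names = FALSE)
      log_stage("indicators", c("indicators_raw.csv",
                                "indicators_scaled.csv",
                                "farm_centres.csv"))
    } else if (stage == "cluster") {
      farms <- need_farms("cluster")
      st$assignments <- build_assignments(farms, cfg$analysis)
      files <- character(0)
      for (asg in st$assignments) {
        tag <- scheme_file_tag(asg$scheme)
        write.csv(asg$assignments, fp(paste0("clusters_", tag, ".csv")),
                  row.names = FALSE)
        write.csv(asg$clusters, fp(paste0("cluster_summary_", tag, ".csv")),
                  row.names = FALSE)
        files <- c(files, paste0("clusters_", tag, ".csv"),
                   paste0("cluster_summary_", tag, ".csv"))
      }
      log_stage("cluster", files)
    } else if (stage == "compare") {
      farms <- need_farms("compare")
      need_indicators("compare")
      need_assignments("compare")
      files <- character(0)
      excluded <- list()
      st$comparisons <- list()
      for (asg in st$assignments) {
        cmp <- compare_scheme(asg, st$scaled, st$centres, st$areas,
                              radius = cfg$analysis$radius,
                              alpha = cfg$analysis$alpha,
                              p_adjust = cfg$analysis$p_adjust)
        st$comparisons[[asg$scheme]] <- cmp
        tag <- scheme_file_tag(asg$scheme)
        write.csv(cmp$rows, fp(paste0("comparison_", tag, ".csv")),
                  row.names = FALSE)
        files <- c(files, paste0("comparison_", tag, ".csv"))
        excluded[[asg$scheme]] <- cmp$excluded
      }
      excl <- do.call(rbind, c(excluded,
                               list(make.row.names = FALSE)))
      write.csv(excl, fp("comparison_excluded.csv"), row.names = FALSE)
      log_stage("compare", c(files, "comparison_excluded.csv"))
    } else if (stage == "screen") {
      need_indicators("screen")
      corr <- spearman_matrix(st$scaled, alpha = cfg$analysis$alpha,
                              strong = cfg$analysis$strong_threshold,
                              moderate = cfg$analysis$moderate_threshold)
      st$corr <- corr
      st$retained <- exclusion_screen(corr, cfg$analysis$priority)
      idx <- which(upper.tri(corr$r), arr.ind = TRUE)
      inds <- colnames(corr$r)
      write.csv(data.frame(
        a = inds[idx[, 1]], b = inds[idx[, 2]],
        r_s = corr$r[idx], p = corr$p[idx], n = corr$n[idx],
        strength = corr$strength[idx], stringsAsFactors = FALSE),
        fp("correlations.csv"), row.names = FALSE)
      writeLines(st$retained, fp("retained_indicators.txt"))
      log_stage("screen", c("correlations.csv", "retained_indicators.txt"))
    } else if (stage == "map") {
      bundle <- need_bundle("map")
      need_indicators("map")
      if (is.null(st$retained)) {
        if (!file.exists(fp("retained_indicators.txt")))
          dependency_error("retained_indicators.txt", "screen", "map")
        st$retained <- readLines(fp("retained_indicators.txt"))
      }
      keep <- c("farm_id", intersect(names(st$scaled), st$retained))
      gs <- grid_summary(st$centres, st$scaled[, keep, drop = FALSE],
                         st$areas, cell = cfg$analysis$grid_cell,
                         hi = cfg$analysis$pct_hi, lo = cfg$analysis$pct_lo)
      write.csv(gs, fp("grid_summary.csv"), row.names = FALSE)
      lu <- landuse_classes(bundle, cfg$analysis)
      write.csv(landuse_point_density(bundle$visitors, lu),
                fp("landuse_visitors.csv"), row.names = FALSE)
      write.csv(landuse_protection_share(lu, bundle$protected),
                fp("landuse_protection.csv"), row.names = FALSE)
      log_stage("map", c("grid_summary.csv", "landuse_visitors.csv",
                         "landuse_protection.csv"))
    }
  }
  yaml::write_yaml(manifest, fp("manifest.yaml"))
  invisible(as.list(st))
}

build_assignments <- function(farms, acfg) {
  out <- list()
  asg <- try(group_by_type(farms, level = acfg$type_level), silent = TRUE)
  if (!inherits(asg, "try-error")) out[[asg$scheme]] <- asg
  if (nrow(farms) > acfg$size_clusters) {
    asg <- try(cluster_size(farms, k = acfg$size_clusters), silent = TRUE)
    if (!inherits(asg, "try-error")) out[[asg$scheme]] <- asg
  }
  lsu_tab <- unlist(acfg$lsu)
  glsu <- farm_group_lsu(farms, lsu_tab)
  single <- rowSums(glsu > 0) <= 1
  for (sp in names(species_groups())) {
    sel <- single & (glsu[, sp] > 0 | rowSums(glsu) == 0)
    sub <- farms[sel, , drop = FALSE]
    asg <- try(cluster_density(sub, sp,
                               min_cluster_n = acfg$min_cluster_n,
                               target_clusters = acfg$target_density_clusters,
                               k_max = acfg$density_k_max,
                               lsu_table = lsu_tab), silent = TRUE)
    if (!inherits(asg, "try-error")) out[[asg$scheme]] <- asg
  }
  out
}

# Land-use classes for the per-land-use summaries: the two agricultural land
# uses plus the non-agricultural remainder of the study areas ("outside").
landuse_classes <- function(bundle, acfg) {
  parcels <- bundle$parcels
  crop <- do.call(c, parcels$geometry[parcels$land_use == "cropland"])
  grass_sel <- parcels$land_use == "semi_natural_grassland"
  out <- list()
  if (!is.null(crop)) out$cropland <- ps_union(crop)
  if (any(grass_sel))
    out$semi_natural_grassland <-
      ps_union(do.call(c, parcels$geometry[grass_sel]))
  study_all <- buffer_region(polygons = do.call(c, parcels$geometry),
                             distance = acfg$study_buffer)
  outside <- ps_minus(study_all, do.call(c, parcels$geometry))
  if (length(outside) > 0L) out$outside <- outside
  out
}
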