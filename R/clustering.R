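# Farm groupings: exact 1-D k-means plus the three grouping schemes
# (type, livestock density per species, farm size).

#' Exact one-dimensional k-means
#'
#' Solves the k-means objective exactly for scalar data by dynamic
#' programming over contiguous partitions of the sorted values (the optimal
#' 1-D partition is always contiguous).  Deterministic, no seeding.
#'
#' @param values Numeric vector.
#' @param k Number of clusters, `1 <= k <=` number of distinct values.
#' @return List with `labels` (cluster index per input value, clusters
#'   numbered by increasing mean), `centers` (cluster means, increasing),
#'   `size` (cluster sizes) and `withinss` (per-cluster within sum of
#'   squares).
#' @export
kmeans_1d <- function(values, k) {
  n <- length(values)
  if (k < 1 || k > n)
    stop("parameter error: k must be between 1 and length(values)")
  if (length(unique(values)) < k)
    stop("parameter error: fewer distinct values than clusters")
  ord <- order(values)
  v <- values[ord]
  p1 <- cumsum(v); p2 <- cumsum(v^2)
  # cost of segment (i..j], 0-based prefix convention via c(0, p)
  P1 <- c(0, p1); P2 <- c(0, p2)
  segcost <- function(i, j) {
    # i, j vectors of segment starts/ends (1-based inclusive)
    s1 <- P1[j + 1L] - P1[i]
    s2 <- P2[j + 1L] - P2[i]
    s2 - s1^2 / (j - i + 1L)
  }
  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(1L, nrow = k, ncol = n)
  D[1, ] <- segcost(rep(1L, n), seq_len(n))
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        i <- q:j  # start index of the last cluster
        cand <- D[q - 1L, i - 1L] + segcost(i, rep(j, length(i)))
        best <- which.min(cand)
        D[q, j] <- cand[best]
        B[q, j] <- i[best]
      }
    }
  }
  # backtrack
  breaks <- integer(k + 1L)
  breaks[k + 1L] <- n
  j <- n
  for (q in k:1) {
    breaks[q] <- B[q, j] - 1L
    j <- breaks[q]
  }
  lab_sorted <- rep(seq_len(k), diff(breaks))
  labels <- integer(n)
  labels[ord] <- lab_sorted
  centers <- vapply(seq_len(k), function(q) mean(v[lab_sorted == q]),
                    numeric(1))
  size <- tabulate(lab_sorted, k)
  wss <- vapply(seq_len(k), function(q) {
    vv <- v[lab_sorted == q]; sum((vv - mean(vv))^2)
  }, numeric(1))
  list(labels = labels, centers = centers, size = size, withinss = wss)
}

new_cluster_assignment <- function(scheme, assignments, clusters,
                                   reference, dropped = NULL) {
  structure(list(scheme = scheme, assignments = assignments,
                 clusters = clusters, reference = reference,
                 dropped = dropped),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", x$scheme, "\n")
  cat("  farms:", nrow(x$assignments), " clusters:", nrow(x$clusters),
      " reference:", x$reference, "\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Livestock species groups used for density clustering
#'
#' Maps clustering species groups to the head-count species they contain.
#' @return Named list of character vectors.
#' @export
species_groups <- function() {
  list(cattle = c("dairy_cow", "other_cattle"),
       sheep = "sheep",
       horses = "horse",
       pigs_poultry = c("pig", "poultry"))
}

farm_group_lsu <- function(farms, lsu_table = default_lsu_table()) {
  grp <- species_groups()
  out <- matrix(0, nrow = nrow(farms), ncol = length(grp),
                dimnames = list(NULL, names(grp)))
  for (g in names(grp)) {
    for (sp in grp[[g]]) {
      col <- paste0("n_", sp)
      if (col %in% names(farms))
        out[, g] <- out[, g] + farms[[col]] * lsu_table[[sp]]
    }
  }
  out
}

#' Cluster single-species farms by livestock density
#'
#' Farms keeping only the given species group are clustered on livestock
#' units per hectare of agricultural land with exact 1-D k-means.  `k` is
#' increased from `target_clusters` until at least `target_clusters` clusters
#' have more than `min_cluster_n` farms; clusters at or below that size are
#' dropped (their farms leave the scheme).  Farms with zero livestock units
#' form the reference group.
#'
#' @param farms Farm register rows (see [derive_farm_attributes()]) holding
#'   only farms with zero livestock or livestock in the single group
#'   `species`; a farm with livestock in two groups is an error.
#' @param species One of `names(species_groups())`.
#' @param min_cluster_n Retention threshold: clusters need more than this
#'   many farms (default 20).
#' @param target_clusters Required number of qualifying clusters (default 4).
#' @param k_max Largest k tried before giving up (default 12).
#' @param lsu_table Livestock-unit coefficients.
#' @return A `cluster_assignment`; labels `"1"`..`"k"` by increasing mean
#'   density, reference label `"reference"`.
#' @export
cluster_density <- function(farms, species, min_cluster_n = 20,
                            target_clusters = 4, k_max = 12,
                            lsu_table = default_lsu_table()) {
  stopifnot(species %in% names(species_groups()))
  glsu <- farm_group_lsu(farms, lsu_table)
  npos <- rowSums(glsu > 0)
  if (any(npos > 1))
    stop("precondition violation: mixed-species farm in density clustering")
  other <- setdiff(colnames(glsu), species)
  if (any(glsu[, other, drop = FALSE] > 0))
    stop("precondition violation: farm keeping a different species in input")
  is_ref <- rowSums(glsu) == 0
  dens <- glsu[, species] / farms$agri_area_ha
  idx <- which(!is_ref)
  if (length(idx) < target_clusters)
    stop("scheme infeasible: too few ", species, " farms")
  found <- NULL
  for (k in target_clusters:k_max) {
    if (k > length(unique(dens[idx]))) break
    km <- kmeans_1d(dens[idx], k)
    if (sum(km$size > min_cluster_n) >= target_clusters) {
      found <- km; break
    }
  }
  if (is.null(found))
    stop("scheme infeasible: no k <= ", k_max, " yields ", target_clusters,
         " clusters with more than ", min_cluster_n, " farms (species ",
         species, ")")
  keep_cl <- which(found$size > min_cluster_n)
  keep <- found$labels %in% keep_cl
  relab <- match(found$labels, keep_cl)  # NA for dropped
  assignments <- data.frame(
    farm_id = c(farms$farm_id[idx][keep], farms$farm_id[is_ref]),
    cluster = c(as.character(relab[keep]),
                rep("reference", sum(is_ref))),
    value = c(dens[idx][keep], dens[is_ref]),
    stringsAsFactors = FALSE)
  cl <- lapply(seq_along(keep_cl), function(q) {
    vv <- dens[idx][found$labels == keep_cl[q]]
    data.frame(cluster = as.character(q), mean = mean(vv), min = min(vv),
               max = max(vv), n = length(vv), is_reference = FALSE)
  })
  clusters <- do.call(rbind, c(cl, list(data.frame(
    cluster = "reference", mean = 0, min = 0, max = 0, n = sum(is_ref),
    is_reference = TRUE))))
  dropped <- data.frame(farm_id = farms$farm_id[idx][!keep],
                        value = dens[idx][!keep], stringsAsFactors = FALSE)
  new_cluster_assignment(paste0("density:", species), assignments, clusters,
                         "reference", dropped)
}

#' Cluster farms into size classes
#'
#' Exact 1-D k-means on total agricultural area; the most populous cluster
#' (ties: the smaller mean) is the reference.  A warning is issued if the
#' reference is not the smallest-size cluster.
#'
#' @param farms Farm register with `agri_area_ha`.
#' @param k Number of size clusters (default 5).
#' @return A `cluster_assignment` with labels `"1"`..`"k"` by increasing
#'   mean size.
#' @export
cluster_size <- function(farms, k = 5) {
  km <- kmeans_1d(farms$agri_area_ha, k)
  ref <- which.max(km$size)
  if (ref != 1L)
    warning("most populous size cluster is not the smallest-size cluster")
  assignments <- data.frame(
    farm_id = farms$farm_id,
    cluster = ifelse(km$labels == ref, "reference",
                     as.character(km$labels)),
    value = farms$agri_area_ha, stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(seq_len(k), function(q) {
    vv <- farms$agri_area_ha[km$labels == q]
    data.frame(cluster = if (q == ref) "reference" else as.character(q),
               mean = mean(vv), min = min(vv), max = max(vv),
               n = length(vv), is_reference = q == ref)
  }))
  new_cluster_assignment("size", assignments, clusters, "reference")
}

#' Group farms by farm type
#'
#' One group per farm type at the detailed or general level; specialist crop
#' production farms are the reference group.
#'
#' @param farms Farm register with `farm_type` / `farm_type_general`.
#' @param level `"detailed"` or `"general"`.
#' @return A `cluster_assignment` whose labels are the type names.
#' @export
group_by_type <- function(farms, level = c("detailed", "general")) {
  level <- match.arg(level)
  types <- if (level == "detailed") farms$farm_type else farms$farm_type_general
  ref <- if (level == "detailed") "crop_production" else "crops"
  if (!any(types == ref))
    stop("reference-empty error: no crop production farms present")
  assignments <- data.frame(farm_id = farms$farm_id, cluster = types,
                            value = NA_real_, stringsAsFactors = FALSE)
  tab <- table(types)
  clusters <- data.frame(cluster = names(tab), mean = NA_real_,
                         min = NA_real_, max = NA_real_,
                         n = as.integer(tab),
                         is_reference = names(tab) == ref,
                         stringsAsFactors = FALSE)
  new_cluster_assignment(paste0("type:", level), assignments, clusters, ref)
}
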