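# Indicator redundancy screening, gridded regional summaries and per-land-use
# visitor/protection summaries.

#' Spearman rank-correlation matrix of the scaled indicators
#'
#' Pairwise-complete Spearman correlations with average ranks for ties;
#' two-sided p-values from the t approximation `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param scaled data.frame: `farm_id` plus indicator columns.
#' @param alpha Significance level for the strength labels (default 0.01).
#' @param strong,moderate Correlation thresholds for the labels (0.5, 0.3).
#' @return A `correlation_matrix`: list with matrices `r`, `p`, `n` and
#'   character matrix `strength` (`"strong"`, `"moderate"`, `"weak"`,
#'   `"n.s."`).
#' @export
spearman_matrix <- function(scaled, alpha = 0.01, strong = 0.5,
                            moderate = 0.3) {
  inds <- setdiff(names(scaled), "farm_id")
  m <- as.matrix(scaled[, inds, drop = FALSE])
  k <- length(inds)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(inds, inds))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 3) next
      rs <- cor(rank(m[ok, i]), rank(m[ok, j]))
      r[i, j] <- rs
      if (i == j) { p[i, j] <- 0; next }
      if (abs(rs) >= 1) { p[i, j] <- 0; next }
      tt <- rs * sqrt((n - 2) / (1 - rs^2))
      p[i, j] <- 2 * pt(-abs(tt), n - 2)
    }
  }
  strength <- matrix("n.s.", k, k, dimnames = list(inds, inds))
  sig <- !is.na(p) & p < alpha
  strength[sig] <- "weak"
  strength[sig & r >= moderate] <- "moderate"
  strength[sig & r >= strong] <- "strong"
  diag(strength) <- "strong"
  structure(list(r = r, p = p, n = nmat, strength = strength,
                 alpha = alpha, strong = strong, moderate = moderate),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>", ncol(x$r), "indicators\n")
  print(round(x$r, 2))
  invisible(x)
}

#' Default indicator retention priority
#'
#' Landscape variation first (it captures the broadest set of ecosystem
#' services); the two indicators known to be largely redundant with it come
#' last.
#'
#' @return Character vector of indicator names, highest priority first.
#' @export
default_indicator_priority <- function() {
  c("LanVar", "Gra", "CrpSeq", "SSHab", "Acc", "Visit", "NatRes",
    "CrpDst", "RodVar")
}

#' Exclude strongly correlated indicators
#'
#' Builds the graph of significantly, strongly positively correlated
#' indicator pairs (`r_s >= strong`, `p < alpha`) and keeps only the
#' highest-priority member of each connected group.
#'
#' @param corr A `correlation_matrix` from [spearman_matrix()].
#' @param priority Ordered indicator names, highest priority first.
#' @return Character vector of retained indicator names (priority order
#'   filtered to the input's indicators).
#' @export
exclusion_screen <- function(corr, priority = default_indicator_priority()) {
  inds <- colnames(corr$r)
  if (!all(inds %in% priority))
    stop("priority list must cover all indicators: missing ",
         paste(setdiff(inds, priority), collapse = ", "))
  k <- length(inds)
  adj <- !is.na(corr$r) & corr$r >= corr$strong &
    !is.na(corr$p) & corr$p < corr$alpha
  diag(adj) <- FALSE
  # connected components by label propagation
  comp <- seq_len(k)
  repeat {
    new <- comp
    for (i in seq_len(k)) {
      nb <- which(adj[i, ])
      if (length(nb) > 0L) new[i] <- min(comp[i], comp[nb])
    }
    if (identical(new, comp)) break
    comp <- new
  }
  pri <- match(inds, priority)
  keep <- vapply(split(seq_len(k), comp), function(grp) {
    grp[which.min(pri[grp])]
  }, integer(1))
  retained <- inds[sort(keep)]
  intersect(priority, retained)
}

#' Gridded regional summary of indicator values
#'
#' Assigns farms to square grid cells by centre point and computes, per cell
#' and indicator, the agricultural-area-weighted mean scaled value; then
#' counts, per cell, indicators whose value lies strictly above the `hi`
#' percentile / strictly below the `lo` percentile of all cell values of
#' that indicator.
#'
#' @param centres data.frame `farm_id`, `x`, `y`.
#' @param scaled Scaled indicator data.frame (retained indicators only).
#' @param areas data.frame `farm_id`, `agri_area_ha`.
#' @param cell Grid cell size in metres (default 15000).
#' @param hi,lo Percentiles (defaults 0.80, 0.20).
#' @param origin Grid origin, default `c(0, 0)` (landscape lower-left).
#' @return data.frame: `cell_x`, `cell_y` (cell origins), `n_farms`,
#'   `area_ha`, one column per indicator, `n_above`, `n_below`.
#' @export
grid_summary <- function(centres, scaled, areas, cell = 15000,
                         hi = 0.80, lo = 0.20, origin = c(0, 0)) {
  inds <- setdiff(names(scaled), "farm_id")
  ids <- scaled$farm_id
  cx <- centres$x[match(ids, centres$farm_id)]
  cy <- centres$y[match(ids, centres$farm_id)]
  a <- areas$agri_area_ha[match(ids, areas$farm_id)]
  gx <- origin[1] + cell * floor((cx - origin[1]) / cell)
  gy <- origin[2] + cell * floor((cy - origin[2]) / cell)
  key <- paste(gx, gy)
  cells <- unique(key)
  out <- data.frame(cell_x = as.numeric(sub(" .*", "", cells)),
                    cell_y = as.numeric(sub(".* ", "", cells)))
  out$n_farms <- as.integer(table(key)[cells])
  out$area_ha <- as.numeric(tapply(a, key, sum)[cells])
  for (ind in inds) {
    v <- scaled[[ind]]
    wm <- vapply(cells, function(k) {
      sel <- key == k & !is.na(v)
      if (!any(sel)) return(NA_real_)
      sum(v[sel] * a[sel]) / sum(a[sel])
    }, numeric(1))
    out[[ind]] <- unname(wm)
  }
  vals <- as.matrix(out[, inds, drop = FALSE])
  qhi <- apply(vals, 2, quantile, probs = hi, na.rm = TRUE, type = 7)
  qlo <- apply(vals, 2, quantile, probs = lo, na.rm = TRUE, type = 7)
  out$n_above <- as.integer(rowSums(sweep(vals, 2, qhi, ">"), na.rm = TRUE))
  out$n_below <- as.integer(rowSums(sweep(vals, 2, qlo, "<"), na.rm = TRUE))
  out
}

#' Visitor-user density per land-use class
#'
#' Distinct users (per source) with at least one point inside each land-use
#' class's polygons, divided by the class area; a user visiting two classes
#' counts in both.  A row with class `"all"` gives the average over the
#' union of all classes.
#'
#' @param points data.frame `x`, `y`, `user_id`, `source`.
#' @param landuse Named list of polysets (classes must not overlap).
#' @return data.frame `class`, `source`, `area_km2`, `users_km2`.
#' @export
landuse_point_density <- function(points, landuse) {
  rows <- list()
  srcs <- c("photo", "species_observation")
  all_geoms <- do.call(c, unname(landuse))
  for (cls in c(names(landuse), "all")) {
    g <- if (cls == "all") all_geoms else landuse[[cls]]
    km2 <- ps_area(g) / 1e6
    for (src in srcs) {
      u <- NA_real_
      if (km2 > 0) {
        sel <- points$source == src
        inside <- sel
        inside[sel] <- point_in_ps(points$x[sel], points$y[sel], g)
        u <- length(unique(points$user_id[inside])) / km2
      } else {
        warning("land-use class ", cls, " has zero area")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, source = src, area_km2 = km2, users_km2 = u,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Protected share per land-use class and protection layer
#'
#' @param landuse Named list of polysets.
#' @param layers Named list of protection-layer polysets.
#' @return data.frame `class`, `layer`, `pct` (percentage of the class's
#'   area inside the layer).
#' @export
landuse_protection_share <- function(landuse, layers) {
  rows <- list()
  for (cls in names(landuse)) {
    a <- ps_area(landuse[[cls]])
    for (ly in names(layers)) {
      pct <- if (a > 0) 100 * overlay_area(landuse[[cls]], layers[[ly]]) / a
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, layer = ly, pct = pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
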