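# Local reference comparison: per-farm difference from the area-weighted
# mean of surrounding reference farms, then cluster-level Welch tests and a
# Welch-mirrored Cohen's d.

#' Local area-weighted difference
#'
#' `D = I - sum(i * a) / sum(a)` where `I` is the focal farm's scaled
#' indicator value and `i`, `a` are scaled values and agricultural areas of
#' the reference farms in the focal farm's neighbourhood.
#'
#' @param I Focal farm's scaled indicator value.
#' @param ref_values Reference farms' scaled values.
#' @param ref_areas Reference farms' agricultural areas (ha).
#' @return The difference `D`.
#' @export
local_difference <- function(I, ref_values, ref_areas) {
  stopifnot(length(ref_values) == length(ref_areas))
  if (length(ref_values) == 0L)
    stop("no reference farm in context")
  ok <- !is.na(ref_values)
  if (!any(ok)) return(NA_real_)
  I - sum(ref_values[ok] * ref_areas[ok]) / sum(ref_areas[ok])
}

#' Welch's unequal-variances t test
#'
#' Two-sided test of equal means with the Welch statistic and
#' Welch-Satterthwaite degrees of freedom; sample (n-1) variances.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("welch_t needs at least 2 values per sample")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) stop("degenerate samples: both variances zero")
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d with a Welch-mirrored variance term
#'
#' `d = (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)` with sample
#' variances, mirroring the variance treatment of Welch's t test rather than
#' pooling by sample size.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return Effect size `d`.
#' @export
cohens_d_welch <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("cohens_d_welch needs at least 2 values per sample")
  (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
}

#' Effect-size category
#'
#' Strict thresholds: large `|d| > 0.8`, moderate `|d| > 0.5`, small
#' `|d| > 0.2`, otherwise negligible.
#'
#' @param d Cohen's d.
#' @return One of `"large"`, `"moderate"`, `"small"`, `"negligible"`.
#' @export
effect_category <- function(d) {
  stopifnot(is.finite(d))
  if (abs(d) > 0.8) "large"
  else if (abs(d) > 0.5) "moderate"
  else if (abs(d) > 0.2) "small"
  else "negligible"
}

#' Compare farm clusters to surrounding reference farms
#'
#' For every farm in the scheme (reference farms included) computes the local
#' difference `D` of each scaled indicator from the area-weighted mean of
#' reference-cluster farms within `radius` of the farm's centre (the focal
#' farm is never its own reference).  Each non-reference cluster is then
#' compared to the reference cluster per indicator with Welch's t test and
#' the Welch-mirrored Cohen's d.
#'
#' @param assignment A `cluster_assignment`.
#' @param scaled data.frame: `farm_id` plus one column per scaled indicator.
#' @param centres data.frame: `farm_id`, `x`, `y` (m).
#' @param areas data.frame: `farm_id`, `agri_area_ha`.
#' @param radius Reference search radius in metres (default 20000).
#' @param alpha Significance level (default 0.01).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   across the scheme's rows (default `"none"`, as tests are reported per
#'   indicator without correction).
#' @return List with `rows` (one row per cluster x indicator, including a
#'   mean-D row for the reference cluster), `D` (farm x indicator local
#'   differences) and `excluded` (farms with no reference within radius).
#' @export
compare_scheme <- function(assignment, scaled, centres, areas,
                           radius = 20000, alpha = 0.01,
                           p_adjust = "none") {
  asg <- assignment$assignments
  ids <- asg$farm_id
  stopifnot(all(ids %in% scaled$farm_id), all(ids %in% centres$farm_id),
            all(ids %in% areas$farm_id))
  inds <- setdiff(names(scaled), "farm_id")
  sc <- as.matrix(scaled[match(ids, scaled$farm_id), inds, drop = FALSE])
  cx <- centres$x[match(ids, centres$farm_id)]
  cy <- centres$y[match(ids, centres$farm_id)]
  ar <- areas$agri_area_ha[match(ids, areas$farm_id)]
  is_ref <- asg$cluster == assignment$reference
  ridx <- which(is_ref)
  if (length(ridx) == 0L) stop("reference cluster is empty")
  rx <- cx[ridx]; ry <- cy[ridx]; ra <- ar[ridx]
  rsc <- sc[ridx, , drop = FALSE]
  rna <- !is.na(rsc)
  D <- matrix(NA_real_, nrow = length(ids), ncol = length(inds),
              dimnames = list(NULL, inds))
  excluded <- logical(length(ids))
  r2 <- radius^2
  for (f in seq_along(ids)) {
    d2 <- (rx - cx[f])^2 + (ry - cy[f])^2
    sel <- d2 <= r2
    if (is_ref[f]) sel[ridx == f] <- FALSE
    if (!any(sel)) { excluded[f] <- TRUE; next }
    w <- ra[sel]
    m <- rsc[sel, , drop = FALSE]
    wsum <- crossprod(rna[sel, , drop = FALSE], w)  # per-indicator sum of a
    m0 <- m; m0[is.na(m0)] <- 0
    wmean <- crossprod(m0, w) / wsum
    D[f, ] <- sc[f, ] - as.numeric(wmean)
  }
  rows <- list()
  refD <- D[ridx[!excluded[ridx]], , drop = FALSE]
  for (ind in inds) {
    y <- refD[, ind]; y <- y[!is.na(y)]
    rows[[length(rows) + 1L]] <- data.frame(
      scheme = assignment$scheme, cluster = assignment$reference,
      indicator = ind, n_focal = length(y), mean_D = mean(y),
      t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
      category = NA_character_, significant = NA,
      stringsAsFactors = FALSE)
  }
  cl_labels <- setdiff(unique(asg$cluster), assignment$reference)
  for (cl in cl_labels) {
    fidx <- which(asg$cluster == cl & !excluded)
    for (ind in inds) {
      x <- D[fidx, ind]; x <- x[!is.na(x)]
      y <- refD[, ind]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) next
      wt <- welch_t(x, y)
      d <- cohens_d_welch(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = assignment$scheme, cluster = cl, indicator = ind,
        n_focal = length(x), mean_D = mean(x),
        t = wt$t, df = wt$df, p = wt$p, d = d,
        category = effect_category(d), significant = NA,
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  test <- !is.na(rows$p)
  if (p_adjust != "none")
    rows$p[test] <- stats::p.adjust(rows$p[test], method = p_adjust)
  rows$significant[test] <- rows$p[test] < alpha
  Ddf <- data.frame(farm_id = ids, cluster = asg$cluster, D,
                    stringsAsFactors = FALSE, check.names = FALSE)
  list(rows = rows,
       D = Ddf[!excluded, , drop = FALSE],
       excluded = data.frame(farm_id = ids[excluded],
                             cluster = asg$cluster[excluded],
                             reason = rep("no reference farm within radius",
                                          sum(excluded)),
                             stringsAsFactors = FALSE))
}
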