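# Independent oracles used by the test suite.  Everything here is coded
# separately from the package: areas/perimeters by local shoelace code,
# boolean operations by direct polyclip calls, point-in-polygon through sp,
# statistics through base formulas written out long-hand or stats::t.test /
# stats::cor.test, and 1-D k-means by exhaustive partition enumeration.

o_ring_area <- function(r) {
  n <- length(r$x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + r$x[i] * r$y[j] - r$x[j] * r$y[i]
  }
  s / 2
}

o_area <- function(ps) {
  if (length(ps) == 0L) return(0)
  abs(sum(vapply(ps, o_ring_area, numeric(1))))
}

o_perim <- function(ps) {
  if (length(ps) == 0L) return(0)
  tot <- 0
  for (r in ps) {
    n <- length(r$x)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      tot <- tot + sqrt((r$x[j] - r$x[i])^2 + (r$y[j] - r$y[i])^2)
    }
  }
  tot
}

o_clip <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

o_selfunion <- function(ps) {
  if (length(ps) == 0L) return(list())
  polyclip::polyclip(ps, ps, op = "union",
                     fillA = "nonzero", fillB = "nonzero")
}

# Even-odd point-in-polyset via sp (boundary points count as inside).
o_inside <- function(px, py, ps) {
  if (length(px) == 0L) return(logical(0))
  cnt <- integer(length(px))
  for (r in ps) {
    hit <- sp::point.in.polygon(px, py, r$x, r$y)
    cnt <- cnt + as.integer(hit >= 1)
  }
  cnt %% 2L == 1L
}

# Minimum distance from one point to a polyset's edges, plain R.
o_pt_ps_dist <- function(px, py, ps) {
  best <- Inf
  for (r in ps) {
    n <- length(r$x)
    x0 <- r$x; y0 <- r$y
    x1 <- c(r$x[-1], r$x[1]); y1 <- c(r$y[-1], r$y[1])
    dx <- x1 - x0; dy <- y1 - y0
    L2 <- dx^2 + dy^2
    t <- ((px - x0) * dx + (py - y0) * dy) / ifelse(L2 == 0, 1, L2)
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
    best <- min(best, sqrt(min(d2)))
  }
  best
}

# Shared different-class border length by boundary subdivision: every
# boundary segment of one patch is split at the projections of the other
# patch's vertices, and each subsegment counts when its midpoint falls inside
# the projected span of an anti-parallel segment of the other boundary that
# is collinear within `tol`.  Tolerance-aware, so it stays correct on mosaics
# whose abutting boundaries carry hairline vertex drift.
o_segments <- function(ps) {
  out <- NULL
  for (r in ps) {
    n <- length(r$x)
    out <- rbind(out, cbind(r$x, r$y, c(r$x[-1], r$x[1]),
                            c(r$y[-1], r$y[1])))
  }
  out
}

o_border_pair <- function(A, B, tol) {
  tot <- 0
  for (ia in seq_len(nrow(A))) {
    a0 <- A[ia, 1:2]; a1 <- A[ia, 3:4]
    d <- a1 - a0; la <- sqrt(sum(d^2))
    if (la <= tol) next
    u <- d / la
    spans <- NULL
    for (ib in seq_len(nrow(B))) {
      b0 <- B[ib, 1:2]; b1 <- B[ib, 3:4]
      db <- b1 - b0; lb <- sqrt(sum(db^2))
      if (lb <= tol) next
      if (sum(u * db) >= 0) next                       # not anti-parallel
      if (abs(u[1] * (b0[2] - a0[2]) - u[2] * (b0[1] - a0[1])) > tol) next
      if (abs(u[1] * (b1[2] - a0[2]) - u[2] * (b1[1] - a0[1])) > tol) next
      t0 <- sum(u * (b0 - a0)); t1 <- sum(u * (b1 - a0))
      spans <- rbind(spans, range(c(t0, t1)))
    }
    if (is.null(spans)) next
    cuts <- sort(unique(c(0, la, pmin(la, pmax(0, as.vector(spans))))))
    for (k in seq_len(length(cuts) - 1L)) {
      mid <- (cuts[k] + cuts[k + 1L]) / 2
      if (any(spans[, 1] <= mid & mid <= spans[, 2]))
        tot <- tot + (cuts[k + 1L] - cuts[k])
    }
  }
  tot
}

oracle_border_subdivision <- function(mosaic, window, tol = 0.01) {
  clipped <- lapply(mosaic, function(p) o_clip(p$geometry, window))
  cls <- vapply(mosaic, `[[`, character(1), "class")
  keep <- vapply(clipped, length, integer(1)) > 0L
  clipped <- clipped[keep]; cls <- cls[keep]
  m <- length(clipped)
  if (m < 2L) return(0)
  segs <- lapply(clipped, o_segments)
  bb <- lapply(segs, function(s) c(min(s[, c(1, 3)]), min(s[, c(2, 4)]),
                                   max(s[, c(1, 3)]), max(s[, c(2, 4)])))
  tot <- 0
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (cls[i] == cls[j]) next
    if (bb[[i]][1] > bb[[j]][3] + tol || bb[[j]][1] > bb[[i]][3] + tol ||
        bb[[i]][2] > bb[[j]][4] + tol || bb[[j]][2] > bb[[i]][4] + tol) next
    tot <- tot + o_border_pair(segs[[i]], segs[[j]], tol)
  }
  tot
}

# Regular interior grid (same convention as the package contract: pitch
# offset half a spacing from the bounding-box lower-left).
o_grid <- function(ps, spacing) {
  xs <- unlist(lapply(ps, `[[`, "x")); ys <- unlist(lapply(ps, `[[`, "y"))
  gx <- seq(min(xs) + spacing / 2, max(xs), by = spacing)
  gy <- seq(min(ys) + spacing / 2, max(ys), by = spacing)
  g <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  g[o_inside(g$x, g$y, ps), , drop = FALSE]
}

# Brute-force mean interior distance: loop grid points x eligible patches.
oracle_interior_distance <- function(target, habitats,
                                     excluded = c("water", "built_up"),
                                     spacing = 25) {
  elig <- Filter(function(p) !(p$class %in% c("cropland", excluded)),
                 habitats)
  pts <- o_grid(target, spacing)
  if (nrow(pts) == 0L || length(elig) == 0L) return(NA_real_)
  d <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (p in elig) {
      if (o_inside(pts$x[i], pts$y[i], p$geometry)) { best <- 0; break }
      best <- min(best, o_pt_ps_dist(pts$x[i], pts$y[i], p$geometry))
    }
    d[i] <- best
  }
  mean(d)
}

# ---------------------------------------------------------------------------
# Statistics oracles

oracle_welch <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

oracle_cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - sum(x) / nx)^2) / (nx - 1)
  vy <- sum((y - sum(y) / ny)^2) / (ny - 1)
  (sum(x) / nx - sum(y) / ny) / sqrt((vx + vy) / 2)
}

# Tie-corrected Spearman via Pearson on average ranks, written out, with the
# two-sided t-approximation p-value.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  r <- sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# ---------------------------------------------------------------------------
# Exhaustive 1-D k-means over contiguous partitions of the sorted values.
oracle_kmeans_1d <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  wss_seg <- function(a, b) { s <- v[a:b]; sum((s - mean(s))^2) }
  best <- Inf; best_breaks <- NULL
  if (k == 1L) {
    best <- wss_seg(1L, n); best_breaks <- integer(0)
  } else {
    combs <- utils::combn(n - 1L, k - 1L)
    for (c in seq_len(ncol(combs))) {
      br <- combs[, c]
      bounds <- c(0L, br, n)
      w <- 0
      for (q in seq_len(k)) w <- w + wss_seg(bounds[q] + 1L, bounds[q + 1L])
      if (w < best - 1e-12) { best <- w; best_breaks <- br }
    }
  }
  bounds <- c(0L, best_breaks, n)
  centers <- vapply(seq_len(k), function(q) {
    mean(v[(bounds[q] + 1L):bounds[q + 1L]])
  }, numeric(1))
  list(total_wss = best, centers = centers)
}

# ---------------------------------------------------------------------------
# Brute-force recomputation of the nine indicators for one farm, built from
# the naive primitives above and direct polyclip calls only.

o_arctol <- function(d) d * (1 - cos(pi / 36))

o_buffer_polys <- function(ps, d) {
  o_selfunion(polyclip::polyoffset(ps, d, jointype = "round",
                                   arctol = o_arctol(d)))
}

o_buffer_lines <- function(lines, d) {
  o_selfunion(polyclip::polylineoffset(lines, d, jointype = "round",
                                       endtype = "openround",
                                       arctol = o_arctol(d)))
}

oracle_farm_indicators <- function(bundle, farm, acfg) {
  parcels <- bundle$parcels[bundle$parcels$farm_id == farm$farm_id, ,
                            drop = FALSE]
  rings <- do.call(c, parcels$geometry)
  window <- o_buffer_polys(rings, acfg$study_buffer)
  w_ha <- o_area(window) / 1e4
  crop_sel <- parcels$land_use == "cropland"
  crop_rings <- do.call(c, parcels$geometry[crop_sel])
  out <- list()

  out$lanvar <- oracle_border_subdivision(bundle$patches, window) / w_ha

  out$crpdst <- oracle_interior_distance(crop_rings, bundle$patches,
                                         spacing = acfg$grid_pitch)

  grass_rings <- parcels$geometry[parcels$land_use ==
                                    "semi_natural_grassland"]
  g_ha <- sum(vapply(grass_rings, o_area, numeric(1))) / 1e4
  i_ha <- sum(vapply(grass_rings, function(g) {
    o_area(o_clip(g, bundle$inventory))
  }, numeric(1))) / 1e4
  out$gra <- (g_ha + i_ha) / farm$agri_area_ha

  inside_h <- o_inside(bundle$habitats$x, bundle$habitats$y, crop_rings)
  out$sshab <- sum(inside_h) / farm$cropland_ha

  # crop-sequence score, independent implementation
  cfgc <- acfg$crop
  score1 <- function(sq) {
    if (any(is.na(sq))) return(NA_real_)
    n <- length(sq)
    pair <- mean(vapply(2:n, function(t) cfgc$S[sq[t - 1], sq[t]],
                        numeric(1)))
    comp <- vapply(2:n, function(t) {
      seen <- which(sq[1:(t - 1)] == sq[t])
      if (length(seen) == 0L) TRUE
      else (t - max(seen)) >= cfgc$R[[sq[t]]]
    }, logical(1))
    divr <- (length(unique(sq)) - 1) / (n - 1)
    unname(cfgc$weights["pair"] * pair + cfgc$weights["return"] * mean(comp) +
             cfgc$weights["diversity"] * divr)
  }
  sq <- bundle$sequences
  cs <- vapply(which(crop_sel), function(i) {
    rows <- sq[sq$parcel_id == parcels$parcel_id[i], , drop = FALSE]
    score1(rows$crop_code[order(rows$year)])
  }, numeric(1))
  aa <- parcels$area_ha[crop_sel]
  ok <- !is.na(cs)
  out$crpseq <- if (sum(aa[ok]) < acfg$sequence_coverage * sum(aa)) NA_real_
  else sum(cs[ok] * aa[ok]) / sum(aa[ok])

  zone <- o_clip(o_buffer_lines(bundle$roads, acfg$road_adjacency), window)
  nhit <- 0L
  for (p in bundle$patches) {
    piece <- o_clip(p$geometry, window)
    if (length(piece) == 0L) next
    if (length(zone) > 0L && o_area(o_clip(piece, zone)) > 0) nhit <- nhit + 1L
  }
  out$rodvar <- nhit / w_ha

  rb <- o_buffer_lines(bundle$roads, acfg$road_dist)
  out$road_share <- o_area(o_clip(window, rb)) / (w_ha * 1e4)

  B <- o_buffer_polys(window, acfg$pop_buffer)
  pop <- bundle$population
  half <- bundle$pop_cell_size / 2
  wsum <- 0; vsum <- 0
  for (i in seq_len(nrow(pop))) {
    cellrect <- list(list(x = c(pop$x[i] - half, pop$x[i] + half,
                                pop$x[i] + half, pop$x[i] - half),
                          y = c(pop$y[i] - half, pop$y[i] - half,
                                pop$y[i] + half, pop$y[i] + half)))
    a <- o_area(o_clip(cellrect, B))
    wsum <- wsum + a
    vsum <- vsum + a * pop$density[i]
  }
  out$pop_density <- vsum / wsum

  km2 <- w_ha / 100
  vis <- bundle$visitors
  inside_v <- o_inside(vis$x, vis$y, window)
  out$photo_users_km2 <-
    length(unique(vis$user_id[inside_v & vis$source == "photo"])) / km2
  out$obs_users_km2 <-
    length(unique(vis$user_id[inside_v &
                                vis$source == "species_observation"])) / km2

  out$natres <- sum(vapply(bundle$protected, function(l) {
    o_area(o_clip(l, window))
  }, numeric(1))) / (w_ha * 1e4)

  out
}

# ---------------------------------------------------------------------------
# Shared small fixture: a compact synthetic landscape with >= 10 included
# farms, reused by the indicator-equivalence tests.
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_sim_config(n_farms = 16, world = 6000)
      b <- simulate_landscape(cfg, seed = 42)
      farms <- derive_farm_attributes(b$farms, b$parcels)
      sel <- select_farms(farms, b$parcels, b$sequences)
      cache <<- list(bundle = b, farms = sel$farms)
    }
    cache
  }
})

expect_rel_equal <- function(got, want, tol = 1e-6) {
  if (is.na(want)) {
    expect_true(is.na(got))
  } else if (abs(want) < 1e-12) {
    expect_lt(abs(got), tol)
  } else {
    expect_lt(abs(got - want) / abs(want), tol)
  }
}
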