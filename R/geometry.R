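#' @importFrom stats cor median na.omit pt quantile rlnorm rnorm rpois runif
#'   sd setNames var
#' @importFrom utils read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib farmscapes, .registration = TRUE
NULL

# Planar geometry on polygon sets ("polysets").
#
# A polyset is a list of rings; each ring is list(x =, y =) in metres, not
# closed (the first vertex is not repeated).  Outer rings are counter-
# clockwise (positive shoelace area), holes clockwise (negative).  This is
# polyclip's native representation, so every boolean/offsetting call goes
# straight to the Clipper library.

#' Build a rectangular polyset
#'
#' @param x0,y0,x1,y1 Corner coordinates in metres.
#' @return A polyset with one counter-clockwise ring.
#' @export
ps_rect <- function(x0, y0, x1, y1) {
  list(list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
}

#' Build a polyset from coordinate vectors
#'
#' @param x,y Ring vertex coordinates (unclosed).
#' @param holes Optional list of hole rings, each `list(x =, y =)`.
#' @return A polyset; the exterior ring is normalised counter-clockwise and
#'   holes clockwise.
#' @export
ps_polygon <- function(x, y, holes = NULL) {
  out <- list(orient_ring(list(x = x, y = y), clockwise = FALSE))
  for (h in holes) out[[length(out) + 1L]] <- orient_ring(h, clockwise = TRUE)
  out
}

ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

orient_ring <- function(r, clockwise = FALSE) {
  a <- ring_signed_area(r)
  if ((a < 0) != clockwise) {
    r$x <- rev(r$x); r$y <- rev(r$y)
  }
  r
}

ring_length <- function(r) {
  x <- r$x; y <- r$y
  sum(sqrt((c(x[-1], x[1]) - x)^2 + (c(y[-1], y[1]) - y)^2))
}

#' Area of a polygon with optional holes
#'
#' Shoelace area of the exterior ring minus any hole rings.
#'
#' @param poly A polyset (exterior ring plus optional holes).
#' @return Area in square metres.
#' @export
polygon_area <- function(poly) {
  check_polyset(poly)
  a <- ps_area(poly)
  if (a <= 0) stop("invalid geometry: polygon has non-positive area")
  a
}

check_polyset <- function(ps) {
  if (!is.list(ps) || length(ps) == 0L)
    stop("invalid geometry: empty polygon set")
  for (r in ps) {
    if (is.null(r$x) || is.null(r$y) || length(r$x) != length(r$y))
      stop("invalid geometry: ring coordinates malformed")
    if (length(unique(paste(r$x, r$y))) < 3L)
      stop("invalid geometry: degenerate ring (fewer than 3 distinct vertices)")
    if (ring_signed_area(r) == 0)
      stop("invalid geometry: degenerate ring (zero area)")
  }
  invisible(ps)
}

# Total area of a polyset: signed ring areas summed, holes cancelling.
ps_area <- function(ps) {
  if (length(ps) == 0L) return(0)
  abs(sum(vapply(ps, ring_signed_area, numeric(1))))
}

ps_perimeter <- function(ps) {
  if (length(ps) == 0L) return(0)
  sum(vapply(ps, ring_length, numeric(1)))
}

ps_bbox <- function(ps) {
  xs <- unlist(lapply(ps, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(ps, `[[`, "y"), use.names = FALSE)
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

bbox_overlaps <- function(a, b, margin = 0) {
  a[1] <= b[3] + margin && b[1] <= a[3] + margin &&
    a[2] <= b[4] + margin && b[2] <= a[4] + margin
}

ps_union <- function(ps) {
  if (length(ps) == 0L) return(list())
  polyclip::polyclip(ps, ps, op = "union",
                     fillA = "nonzero", fillB = "nonzero")
}

ps_intersect <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

ps_minus <- function(a, b) {
  if (length(a) == 0L) return(list())
  if (length(b) == 0L) return(a)
  polyclip::polyclip(a, b, op = "minus",
                     fillA = "nonzero", fillB = "nonzero")
}

#' Area of intersection of two polygon sets
#'
#' @param a,b Polysets.
#' @return Intersection area in square metres (0 when disjoint).
#' @export
overlay_area <- function(a, b) {
  ps_area(ps_intersect(a, b))
}

# Default arc tolerance: circular arcs approximated by segments subtending
# about 10 degrees, i.e. sagitta distance * (1 - cos(5 deg)).
default_arctol <- function(distance) distance * (1 - cos(pi / 36))

#' Buffer (dilate) polygons and/or polylines
#'
#' Dilates every input geometry by `distance` with round joins and caps and
#' merges overlapping dilations into single polygons.
#'
#' @param polygons A polyset (or NULL).
#' @param lines A list of polylines, each `list(x =, y =)` (or NULL).
#' @param distance Buffer distance in metres; must be positive.
#' @param arc_tolerance Maximum deviation of the arc approximation in metres;
#'   defaults to segments subtending about 10 degrees.
#' @return A merged polyset.
#' @export
buffer_region <- function(polygons = NULL, lines = NULL, distance,
                          arc_tolerance = NULL) {
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0)
    stop("parameter error: buffer distance must be a positive number")
  if (is.null(arc_tolerance)) arc_tolerance <- default_arctol(distance)
  out <- list()
  if (!is.null(polygons) && length(polygons) > 0L) {
    out <- c(out, polyclip::polyoffset(polygons, distance,
                                       jointype = "round",
                                       arctol = arc_tolerance))
  }
  if (!is.null(lines) && length(lines) > 0L) {
    out <- c(out, polyclip::polylineoffset(lines, distance,
                                           jointype = "round",
                                           endtype = "openround",
                                           arctol = arc_tolerance))
  }
  ps_union(out)
}

#' Construct a land-cover patch
#'
#' @param geometry A polyset.
#' @param class Land-cover class, one of [land_cover_classes()].
#' @param patch_id Identifier.
#' @return A `land_patch` list.
#' @export
land_patch <- function(geometry, class, patch_id = NA_character_) {
  if (!class %in% land_cover_classes())
    stop("invalid land-cover class: ", class)
  structure(list(geometry = geometry, class = class, patch_id = patch_id),
            class = "land_patch")
}

#' Closed vocabulary of land-cover classes
#' @return Character vector of valid patch classes.
#' @export
land_cover_classes <- function() {
  c("cropland", "semi_natural_grassland", "forest", "water", "built_up",
    "other_open")
}

#' Length of borders between land-cover patches of different class
#'
#' Total length, clipped to `window`, of edges shared by two patches of
#' different class.  Each shared edge is counted once; edges along the window
#' boundary or between same-class patches are not counted.
#'
#' Shared edges are found by matching boundary segments across patch pairs:
#' two segments contribute where they are anti-parallel and collinear within
#' `tol`, so boundaries that drift apart by a hairline after repeated clipping
#' still register as shared.
#'
#' @param mosaic List of [land_patch()] objects with non-overlapping
#'   geometries.
#' @param window Polyset to clip to.
#' @param tol Coincidence tolerance in metres (default 0.01).
#' @return Border length in metres.
#' @export
shared_border_length <- function(mosaic, window, tol = 0.01) {
  if (length(mosaic) == 0L) return(0)
  wb <- ps_bbox(window)
  clipped <- vector("list", length(mosaic))
  cls <- character(length(mosaic))
  for (i in seq_along(mosaic)) {
    p <- mosaic[[i]]
    if (bbox_overlaps(ps_bbox(p$geometry), wb)) {
      clipped[[i]] <- ps_intersect(p$geometry, window)
    } else clipped[[i]] <- list()
    cls[i] <- p$class
  }
  keep <- vapply(clipped, length, integer(1)) > 0L
  clipped <- clipped[keep]; cls <- cls[keep]
  if (length(clipped) == 0L) return(0)
  all_pieces <- do.call(c, clipped)
  total_union <- ps_union(all_pieces)
  piece_area <- sum(vapply(clipped, ps_area, numeric(1)))
  union_area <- ps_area(total_union)
  # tolerate numerical slivers along shared edges (e.g. Voronoi neighbours)
  area_tol <- 0.5 + 1e-7 * union_area
  if (piece_area > union_area + area_tol)
    stop("invalid mosaic: patches overlap")
  border_length_segments(clipped, cls, tol = tol)
}

# Shared different-class border length from clipped pieces, by accumulating
# collinear anti-parallel segment overlaps between piece boundaries.  A
# perimeter-difference identity would be exact on vertex-exact tilings but
# loses entire edges when abutting boundaries drift by even a hairline, so
# the segment route with an explicit coincidence tolerance is used instead.
border_length_segments <- function(pieces, classes, tol = 0.01) {
  n <- length(pieces)
  if (n < 2L) return(0)
  segs <- lapply(pieces, ps_segments)
  bbs <- lapply(pieces, ps_bbox)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (classes[i] == classes[j]) next
      if (bbs[[i]][1] > bbs[[j]][3] + tol || bbs[[j]][1] > bbs[[i]][3] + tol ||
          bbs[[i]][2] > bbs[[j]][4] + tol || bbs[[j]][2] > bbs[[i]][4] + tol)
        next
      a <- segs[[i]]; b <- segs[[j]]
      total <- total + cpp_border_overlap(a$x0, a$y0, a$x1, a$y1,
                                          b$x0, b$y0, b$x1, b$y1, tol)
    }
  }
  total
}

#' Regular interior sample points of a polyset
#'
#' Lays a square grid of pitch `spacing`, offset by half a pitch from the
#' bounding-box lower-left corner, and keeps points inside the polyset.
#'
#' @param ps Polyset.
#' @param spacing Grid pitch in metres.
#' @return data.frame with columns `x`, `y` (possibly zero rows).
#' @export
grid_points <- function(ps, spacing) {
  if (spacing <= 0) stop("parameter error: spacing must be positive")
  bb <- ps_bbox(ps)
  if (bb[1] + spacing / 2 > bb[3] || bb[2] + spacing / 2 > bb[4])
    return(data.frame(x = numeric(0), y = numeric(0)))
  xs <- seq(bb[1] + spacing / 2, bb[3], by = spacing)
  ys <- seq(bb[2] + spacing / 2, bb[4], by = spacing)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  inside <- point_in_ps(g$x, g$y, ps)
  g[inside, , drop = FALSE]
}

# Even-odd point-in-polyset test, vectorised over points and edges.
point_in_ps <- function(px, py, ps) {
  if (length(px) == 0L) return(logical(0))
  xi <- yi <- xj <- yj <- numeric(0)
  for (r in ps) {
    n <- length(r$x)
    j <- c(n, seq_len(n - 1L))
    xi <- c(xi, r$x); yi <- c(yi, r$y)
    xj <- c(xj, r$x[j]); yj <- c(yj, r$y[j])
  }
  cpp_point_in_rings(as.numeric(px), as.numeric(py), xi, yi, xj, yj)
}

# Minimum distance from each point to a set of segments (x0,y0)-(x1,y1).
dist_points_segments <- function(px, py, x0, y0, x1, y1) {
  if (length(px) == 0L) return(numeric(0))
  cpp_min_dist(as.numeric(px), as.numeric(py), as.numeric(x0),
               as.numeric(y0), as.numeric(x1), as.numeric(y1))
}

# Bounding boxes of individual rings as a 4 x n matrix.
ring_bboxes <- function(ps) {
  vapply(ps, function(r) c(min(r$x), min(r$y), max(r$x), max(r$y)),
         numeric(4))
}

# Rings of `ps` whose bbox overlaps `bb`; dropping far-away rings (including
# their holes, whose bboxes lie inside the outer's) leaves local overlays
# unchanged.
select_rings <- function(ps, rb, bb, margin = 0) {
  if (length(ps) == 0L) return(ps)
  hit <- rb[1, ] <= bb[3] + margin & rb[3, ] >= bb[1] - margin &
    rb[2, ] <= bb[4] + margin & rb[4, ] >= bb[2] - margin
  ps[hit]
}

ps_segments <- function(ps) {
  x0 <- numeric(0); y0 <- numeric(0); x1 <- numeric(0); y1 <- numeric(0)
  for (r in ps) {
    n <- length(r$x)
    x0 <- c(x0, r$x); y0 <- c(y0, r$y)
    x1 <- c(x1, c(r$x[-1], r$x[1])); y1 <- c(y1, c(r$y[-1], r$y[1]))
  }
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Mean distance from polygon interior to the nearest eligible habitat
#'
#' Samples `target` on a regular grid and averages, over grid points inside
#' `target`, the distance to the nearest patch whose class is neither
#' `cropland` nor in `excluded_classes`.
#'
#' @param target Polyset whose interior is sampled.
#' @param habitats List of [land_patch()] objects.
#' @param excluded_classes Classes never eligible (besides cropland).
#' @param spacing Grid pitch in metres (default 25).
#' @return Mean distance in metres, or `NA` (with a warning) if no grid point
#'   falls inside `target` or no eligible habitat exists.
#' @export
mean_interior_distance <- function(target, habitats,
                                   excluded_classes = c("water", "built_up"),
                                   spacing = 25) {
  d <- interior_distances(target, habitats, excluded_classes, spacing)
  if (length(d) == 0L) return(NA_real_)
  if (all(is.na(d))) return(NA_real_)
  mean(d)
}

# Per-grid-point distances to the nearest eligible habitat; NA vector when no
# eligible patch exists, zero-length when no grid point falls inside target.
interior_distances <- function(target, habitats,
                               excluded_classes = c("water", "built_up"),
                               spacing = 25) {
  eligible <- Filter(function(p) {
    p$class != "cropland" && !(p$class %in% excluded_classes)
  }, habitats)
  pts <- grid_points(target, spacing)
  if (nrow(pts) == 0L) return(numeric(0))
  if (length(eligible) == 0L) {
    warning("no eligible habitat patch; interior distance undefined")
    return(rep(NA_real_, nrow(pts)))
  }
  d <- rep(Inf, nrow(pts))
  inside_any <- rep(FALSE, nrow(pts))
  for (p in eligible) {
    seg <- ps_segments(p$geometry)
    d <- pmin(d, dist_points_segments(pts$x, pts$y,
                                      seg$x0, seg$y0, seg$x1, seg$y1))
    inside_any <- inside_any | point_in_ps(pts$x, pts$y, p$geometry)
  }
  d[inside_any] <- 0
  d
}

# Area-weighted centroid of a polyset (holes handled by signed areas).
ps_centroid <- function(ps) {
  cx <- 0; cy <- 0; atot <- 0
  for (r in ps) {
    x <- as.numeric(r$x); y <- as.numeric(r$y)
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a <- sum(cr) / 2
    if (a == 0) next
    cx <- cx + sum((x + xn) * cr) / 6
    cy <- cy + sum((y + yn) * cr) / 6
    atot <- atot + a
  }
  c(x = cx / atot, y = cy / atot)
}
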