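# Habitat map construction and point/region attribution.
#
# Buffered zones are stored implicitly as source geometry plus a width:
# membership is an exact distance-to-segment test, zone area is grid
# quadrature, and polygon export discretizes a rounded outline per feature.

#' Buffer a line or polygon layer
#'
#' Roads are buffered by 10 m and hydrological features by 20 m in the
#' default study configuration, to absorb digitisation error in the mapped
#' features.
#'
#' @param layer list with `kind` ("lines" or "polygons") and `parts` (list of
#'   two-column coordinate matrices), e.g. from [read_geojson()].
#' @param width buffer width in metres (> 0).
#' @return A `buffer_zone` object; see [zone_contains()], [zone_area()].
#' @export
buffer_features <- function(layer, width) {
  stopifnot(is.numeric(width), width > 0)
  parts <- layer$parts
  kind <- layer$kind
  if (length(parts)) assert_planar(parts)
  segs <- if (length(parts)) {
    do.call(rbind, lapply(parts, segments_of, close = (kind == "polygons")))
  } else matrix(numeric(0), ncol = 4L)
  structure(list(kind = kind, parts = parts, width = width, segs = segs),
            class = "buffer_zone")
}

#' Is each point inside a buffered zone?
#' @param zone a `buffer_zone`; @param px,py point coordinates (m).
#' @return Logical vector; boundary points count as inside (closed zones).
#' @export
zone_contains <- function(zone, px, py) {
  if (length(zone$parts) == 0L) return(rep(FALSE, length(px)))
  near <- dist_to_segments(px, py, zone$segs) <= zone$width
  if (zone$kind == "polygons") near | point_in_rings(px, py, zone$parts) else near
}

#' Area of a buffered zone by grid quadrature
#' @param zone a `buffer_zone`; @param cell quadrature cell edge (m); default
#'   width/20 capped so the grid stays below ~4e6 cells.
#' @return Area in square metres.
#' @export
zone_area <- function(zone, cell = NULL) {
  if (length(zone$parts) == 0L) return(0)
  b <- bbox_of(zone$parts, pad = zone$width)
  if (is.null(cell)) {
    cell <- zone$width / 20
    min_cell <- sqrt((b[2L] - b[1L]) * (b[4L] - b[3L]) / 4e6)
    cell <- max(cell, min_cell)
  }
  gx <- seq(b[1L] + cell / 2, b[2L], by = cell)
  gy <- seq(b[3L] + cell / 2, b[4L], by = cell)
  pts <- expand.grid(x = gx, y = gy)
  sum(zone_contains(zone, pts$x, pts$y)) * cell^2
}

#' Export a buffered zone as discretized outline polygons
#'
#' Each source feature becomes one ring traced at `width` from the feature
#' (rounded caps, 16 arc points); rings of overlapping features may overlap.
#' Membership tests always use the exact distance form, not these rings.
#' @param zone a `buffer_zone`; @return list of two-column ring matrices.
#' @export
zone_rings <- function(zone) {
  lapply(zone$parts, function(m) {
    if (zone$kind == "polygons") {
      # dilate ring outward from its centroid direction per vertex normal:
      # approximate by buffering the boundary and keeping the outer trace
      m2 <- rbind(m, m[1L, ])
      outline_polyline(m2, zone$width)
    } else outline_polyline(m, zone$width)
  })
}

# one-sided traversal outline of a polyline buffer (approximate, for export)
outline_polyline <- function(m, w, cap_pts = 16L) {
  n <- nrow(m)
  if (n < 2L) return(circle_ring(m[1L, 1L], m[1L, 2L], w, 32L))
  dir <- atan2(diff(m[, 2L]), diff(m[, 1L]))
  left <- right <- NULL
  for (i in seq_len(n - 1L)) {
    nx <- -sin(dir[i]) * w; ny <- cos(dir[i]) * w
    left <- rbind(left, c(m[i, 1L] + nx, m[i, 2L] + ny), c(m[i + 1L, 1L] + nx, m[i + 1L, 2L] + ny))
    right <- rbind(c(m[i, 1L] - nx, m[i, 2L] - ny), c(m[i + 1L, 1L] - nx, m[i + 1L, 2L] - ny), right)
  }
  cap <- function(cx, cy, a0, a1) {
    th <- seq(a0, a1, length.out = cap_pts)
    cbind(cx + w * cos(th), cy + w * sin(th))
  }
  end_cap <- cap(m[n, 1L], m[n, 2L], dir[n - 1L] - pi / 2, dir[n - 1L] + pi / 2)
  start_cap <- cap(m[1L, 1L], m[1L, 2L], dir[1L] + pi / 2, dir[1L] + 3 * pi / 2)
  rbind(left, end_cap, right, start_cap)
}

#' Jenks natural breaks (optimal 1-D classification)
#'
#' Finds the k-class partition of the sorted values minimizing the total
#' within-class sum of squared deviations (Fisher's dynamic programme; the
#' classical natural-breaks optimization used to cut a continuous cover
#' index into discrete classes).
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes (>= 2).
#' @param sample optional subsample size: breaks computed on a deterministic
#'   regular subsample of the sorted values (default NULL = all values).
#' @return Numeric vector of k-1 break values; class c is
#'   `breaks[c-1] < x <= breaks[c]`.
#' @export
jenks_breaks <- function(values, k, sample = NULL) {
  v <- values[is.finite(values)]
  stopifnot(k >= 2L)
  nd <- length(unique(v))
  if (nd < k)
    stop(sprintf("need at least %d distinct values for %d classes, got %d", k, k, nd))
  v <- sort(v)
  if (!is.null(sample) && length(v) > sample)
    v <- v[unique(round(seq(1L, length(v), length.out = sample)))]
  ends <- .jenks_dp(v, as.integer(k)) + 1L  # 1-based last index per class
  v[ends]
}

#' Classify a continuous cover raster into low/moderate/high
#'
#' @param grid numeric matrix of cover-index values.
#' @param breaks two increasing break values (e.g. from [jenks_breaks()]).
#' @return Integer matrix (1 = low, 2 = moderate, 3 = high; NA propagated)
#'   with attributes `proportions` (of finite cells) and `n_missing`.
#' @export
classify_cover <- function(grid, breaks) {
  stopifnot(length(breaks) == 2L, breaks[1L] < breaks[2L])
  cl <- matrix(NA_integer_, nrow(grid), ncol(grid))
  fin <- is.finite(grid)
  cl[fin] <- 1L + (grid[fin] > breaks[1L]) + (grid[fin] > breaks[2L])
  tab <- tabulate(cl[fin], 3L)
  structure(cl,
            proportions = stats::setNames(tab / max(1L, sum(fin)), c("low", "moderate", "high")),
            n_missing = sum(!fin))
}

#' Assemble a landscape map
#'
#' @param extent c(xmin, xmax, ymin, ymax) in projected metres.
#' @param roads,hydro line / polygon layers (as from [read_geojson()]) or NULL.
#' @param veg vegetation layer: either `list(kind = "polygons", parts = ...)`
#'   giving grassland polygons (everything else is woodland), or
#'   `list(kind = "raster", grid = <logical matrix TRUE = grassland>,
#'   origin, cellsize)`.
#' @param cover list(grid, origin, cellsize) continuous cover raster.
#' @param road_buffer,hydro_buffer buffer widths (m); defaults 10 and 20.
#' @param cover_sample optional subsample size passed to [jenks_breaks()].
#' @return A `landscape_map` answering point and region habitat queries.
#' @export
landscape_map <- function(extent, roads = NULL, hydro = NULL, veg, cover,
                          road_buffer = 10, hydro_buffer = 20,
                          cover_sample = NULL) {
  stopifnot(length(extent) == 4L, extent[2L] > extent[1L], extent[4L] > extent[3L])
  road_zone <- if (!is.null(roads)) buffer_features(roads, road_buffer)
  hydro_zone <- if (!is.null(hydro)) buffer_features(hydro, hydro_buffer)
  breaks <- jenks_breaks(as.numeric(cover$grid), 3L, sample = cover_sample)[1:2]
  classes <- classify_cover(cover$grid, breaks)
  structure(list(extent = extent, roads = road_zone, hydro = hydro_zone,
                 veg = veg, cover = cover, cover_breaks = breaks,
                 cover_classes = classes,
                 buffer_widths = c(road = road_buffer, hydro = hydro_buffer),
                 crs_note = "planar metric (projected metres)"),
            class = "landscape_map")
}

#' @export
print.landscape_map <- function(x, ...) {
  cat("landscape_map:", paste(round(x$extent), collapse = " "), "m\n")
  cat(sprintf("  buffers: road %g m, hydro %g m\n",
              x$buffer_widths["road"], x$buffer_widths["hydro"]))
  cat(sprintf("  cover breaks: %.3g, %.3g\n", x$cover_breaks[1L], x$cover_breaks[2L]))
  cat("  vegetation layer:", x$veg$kind, "\n")
  invisible(x)
}

raster_value <- function(grid, origin, cellsize, px, py) {
  cx <- pmin(pmax(floor((px - origin[1L]) / cellsize) + 1L, 1L), ncol(grid))
  cy <- pmin(pmax(floor((py - origin[2L]) / cellsize) + 1L, 1L), nrow(grid))
  grid[cbind(cy, cx)]
}

is_grassland <- function(map, px, py) {
  v <- map$veg
  if (v$kind == "raster") {
    as.logical(raster_value(v$grid, v$origin, v$cellsize, px, py))
  } else {
    point_in_rings(px, py, v$parts)
  }
}

#' Attribute points with habitat covariates
#'
#' @param map a `landscape_map`.
#' @param px,py point coordinates (m); must lie inside the study extent.
#' @return Data frame: on_road, on_hydro, veg (grassland/woodland), cover
#'   (low/moderate/high), and the 4-level road x vegetation factor
#'   `road_veg` with reference level `offroad_grass`.
#' @export
attribute_points <- function(map, px, py) {
  e <- map$extent
  out <- px < e[1L] | px > e[2L] | py < e[3L] | py > e[4L]
  if (any(out))
    stop(sprintf("%d point(s) outside the study extent", sum(out)))
  on_road <- if (is.null(map$roads)) rep(FALSE, length(px)) else zone_contains(map$roads, px, py)
  on_hydro <- if (is.null(map$hydro)) rep(FALSE, length(px)) else zone_contains(map$hydro, px, py)
  grass <- is_grassland(map, px, py)
  cov_i <- raster_value(map$cover_classes, map$cover$origin, map$cover$cellsize, px, py)
  rv <- ifelse(on_road,
               ifelse(grass, "onroad_grass", "onroad_wood"),
               ifelse(grass, "offroad_grass", "offroad_wood"))
  data.frame(on_road = on_road, on_hydro = on_hydro,
             veg = factor(ifelse(grass, "grassland", "woodland"),
                          levels = c("grassland", "woodland")),
             cover = factor(c("low", "moderate", "high")[cov_i],
                            levels = c("low", "moderate", "high")),
             road_veg = factor(rv, levels = c("offroad_grass", "onroad_grass",
                                              "offroad_wood", "onroad_wood")))
}

#' @rdname attribute_points
#' @param x,y a single point.
#' @export
attribute_point <- function(map, x, y) attribute_points(map, x, y)

#' Design matrix for selection models
#'
#' Encodes habitat attributes as the model terms used throughout:
#' road x vegetation dummies against the off-road-grassland reference,
#' a hydrological-feature indicator, and high/low cover indicators against
#' moderate cover.
#'
#' @param attrs data frame from [attribute_points()].
#' @return Numeric matrix with columns onroad_grass, offroad_wood,
#'   onroad_wood, hydro, cover_high, cover_low.
#' @export
design_matrix <- function(attrs) {
  cbind(onroad_grass = as.numeric(attrs$road_veg == "onroad_grass"),
        offroad_wood = as.numeric(attrs$road_veg == "offroad_wood"),
        onroad_wood = as.numeric(attrs$road_veg == "onroad_wood"),
        hydro = as.numeric(attrs$on_hydro),
        cover_high = as.numeric(attrs$cover == "high"),
        cover_low = as.numeric(attrs$cover == "low"))
}

#' Vegetation composition of a region
#'
#' Area-weighted grassland/woodland proportions inside a region, by a
#' deterministic quadrature grid clipped to the mapped extent.
#'
#' @param map a `landscape_map`.
#' @param region either a two-column ring matrix or `list(center = c(x, y),
#'   radius = r)` for a circle.
#' @param n_points approximate number of quadrature points (default 2e4).
#' @return Named numeric c(grassland, woodland), summing to 1.
#' @export
region_composition <- function(map, region, n_points = 2e4) {
  if (is.list(region) && !is.null(region$radius)) {
    r <- region$radius; cc <- region$center
    b <- c(cc[1L] - r, cc[1L] + r, cc[2L] - r, cc[2L] + r)
    inside_fun <- function(px, py) (px - cc[1L])^2 + (py - cc[2L])^2 <= r^2
    if (r <= 0) stop("zero-area region")
  } else {
    ring <- as.matrix(region)
    if (polygon_area(ring) <= 0) stop("zero-area region")
    b <- bbox_of(list(ring))
    inside_fun <- function(px, py) point_in_ring(px, py, ring)
  }
  e <- map$extent
  b <- c(max(b[1L], e[1L]), min(b[2L], e[2L]), max(b[3L], e[3L]), min(b[4L], e[4L]))
  if (b[2L] <= b[1L] || b[4L] <= b[3L]) stop("region does not intersect the study extent")
  step <- sqrt((b[2L] - b[1L]) * (b[4L] - b[3L]) / n_points)
  gx <- seq(b[1L] + step / 2, b[2L], by = step)
  gy <- seq(b[3L] + step / 2, b[4L], by = step)
  pts <- expand.grid(x = gx, y = gy)
  keep <- inside_fun(pts$x, pts$y)
  if (!any(keep)) stop("region does not intersect the study extent")
  g <- is_grassland(map, pts$x[keep], pts$y[keep])
  g <- g[!is.na(g)]
  p <- mean(g)
  c(grassland = p, woodland = 1 - p)
}
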