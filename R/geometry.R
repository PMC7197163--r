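# Planar geometry primitives. All coordinates are projected metres; the
# package refuses geographic (lon/lat) input rather than reprojecting.

#' Shoelace area of a polygon ring
#'
#' @param ring two-column matrix of vertex coordinates (closed or open ring).
#' @return Absolute area in square metres.
#' @export
polygon_area <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test (even-odd rule, closed boundary)
#'
#' Vertices on the boundary count as inside: the buffered and mapped zones
#' are closed sets.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param ring two-column vertex matrix of one ring.
#' @return Logical vector.
#' @export
point_in_ring <- function(px, py, ring) {
  ring <- as.matrix(ring)
  # drop duplicated closing vertex if present
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  if (n < 3L) return(rep(FALSE, length(px)))
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  x1 <- ring[, 1L]; y1 <- ring[, 2L]
  x2 <- ring[c(2:n, 1L), 1L]; y2 <- ring[c(2:n, 1L), 2L]
  for (e in seq_len(n)) {
    ax <- x1[e]; ay <- y1[e]; bx <- x2[e]; by <- y2[e]
    crosses <- ((ay > py) != (by > py))
    if (any(crosses)) {
      xint <- ax + (py[crosses] - ay) * (bx - ax) / (by - ay)
      flip <- xint > px[crosses]
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    # boundary membership (distance to segment ~ 0)
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2)) else 0
    d2 <- (px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2
    on_edge <- on_edge | d2 <= 1e-12
  }
  inside | on_edge
}

#' Point membership in a set of rings (even-odd across rings: holes supported)
#' @param px,py point coordinates.
#' @param rings list of two-column vertex matrices.
#' @return Logical vector.
#' @export
point_in_rings <- function(px, py, rings) {
  if (length(rings) == 0L) return(rep(FALSE, length(px)))
  counts <- rep(0L, length(px))
  for (r in rings) {
    # bounding-box prefilter: most points miss most rings
    sel <- px >= min(r[, 1L]) & px <= max(r[, 1L]) &
           py >= min(r[, 2L]) & py <= max(r[, 2L])
    if (!any(sel)) next
    counts[sel] <- counts[sel] + point_in_ring(px[sel], py[sel], r)
  }
  counts %% 2L == 1L
}

# Segment table from a polyline/ring: columns x1,y1,x2,y2
segments_of <- function(coords, close = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) return(matrix(numeric(0), ncol = 4L))
  i <- seq_len(n - 1L)
  segs <- cbind(coords[i, 1L], coords[i, 2L], coords[i + 1L, 1L], coords[i + 1L, 2L])
  if (close && any(coords[1L, ] != coords[n, ]))
    segs <- rbind(segs, c(coords[n, ], coords[1L, ]))
  segs
}

#' Minimum distance from points to a set of line segments
#' @param px,py point coordinates.
#' @param segs four-column matrix (x1, y1, x2, y2), one row per segment.
#' @return Numeric vector of distances in metres.
#' @export
dist_to_segments <- function(px, py, segs) {
  m <- nrow(segs)
  n <- length(px)
  if (m == 0L || n == 0L) return(rep(Inf, n))
  ax <- segs[, 1L]; ay <- segs[, 2L]
  dx <- segs[, 3L] - ax; dy <- segs[, 4L] - ay
  L2 <- dx * dx + dy * dy
  L2[L2 == 0] <- 1    # degenerate segment: distance to its start point
  best <- numeric(n)
  chunk <- max(1L, floor(4e6 / m))
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(n, s + chunk - 1L)
    nc <- length(i)
    A <- outer(px[i], ax, "-")
    B <- outer(py[i], ay, "-")
    Dx <- rep(dx, each = nc); Dy <- rep(dy, each = nc)
    tt <- pmin(1, pmax(0, (A * Dx + B * Dy) / rep(L2, each = nc)))
    d2 <- (A - tt * Dx)^2 + (B - tt * Dy)^2
    best[i] <- d2[cbind(seq_len(nc), max.col(-d2, ties.method = "first"))]
  }
  sqrt(best)
}

#' Regular polygon approximating a circle
#' @param cx,cy centre; @param r radius (m); @param n vertex count.
#' @return Two-column vertex matrix (open ring).
#' @export
circle_ring <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

bbox_of <- function(parts, pad = 0) {
  xs <- unlist(lapply(parts, function(m) m[, 1L]))
  ys <- unlist(lapply(parts, function(m) m[, 2L]))
  c(xmin = min(xs) - pad, xmax = max(xs) + pad,
    ymin = min(ys) - pad, ymax = max(ys) + pad)
}

# Heuristic guard against geographic coordinates: a projected metric frame
# for a multi-kilometre study area never fits inside lon/lat bounds.
assert_planar <- function(parts) {
  b <- bbox_of(parts)
  if (b["xmin"] >= -360 && b["xmax"] <= 360 && b["ymin"] >= -90 && b["ymax"] <= 90)
    stop("coordinates look geographic (degrees); supply projected metres", call. = FALSE)
  invisible(TRUE)
}
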