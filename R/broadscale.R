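# Second-order habitat selection: availability region, random circular
# home-range sampling and the weighted used-available logistic RSF.

#' Radius of the circle with a given area
#'
#' Converts a (median) home-range area to the radius of the equal-area
#' circle used to buffer fixes and to size the randomly placed available
#' home ranges. Reported radii are rounded to the nearest metre; internal
#' arithmetic is unrounded.
#'
#' @param area_ha area in hectares (> 0).
#' @return Radius in metres (unrounded; attribute `reported` holds the
#'   rounded value).
#' @export
circle_radius_from_area <- function(area_ha) {
  if (!is.numeric(area_ha) || any(area_ha <= 0)) stop("area must be positive")
  r <- sqrt(area_ha * 1e4 / pi)
  structure(r, reported = round(r))
}

#' Species availability region
#'
#' Union of the species' 100% MCP over all fixes and a disc of radius
#' `r_median` (radius of the circular median seasonal home range) around
#' every fix.
#'
#' @param xy all fixes of the species (two-column matrix).
#' @param median_hr_area_ha median seasonal home-range area (ha).
#' @return An `avail_region`: hull ring, fixes, radius, bounding box.
#' @export
availability_region <- function(xy, median_hr_area_ha) {
  xy <- as.matrix(xy)
  hull <- mcp(xy)
  r <- as.numeric(circle_radius_from_area(median_hr_area_ha))
  structure(list(hull = hull$ring, fixes = xy, r_median = r,
                 median_hr_area_ha = median_hr_area_ha,
                 bbox = bbox_of(list(xy), pad = r)),
            class = "avail_region")
}

#' Is each point inside the availability region?
#' @param region an `avail_region`; @param px,py coordinates (m).
#' @return Logical vector.
#' @export
region_contains <- function(region, px, py) {
  inside <- point_in_ring(px, py, region$hull)
  todo <- which(!inside)
  if (length(todo)) {
    r2 <- region$r_median^2
    for (i in todo) {
      d2 <- (region$fixes[, 1L] - px[i])^2 + (region$fixes[, 2L] - py[i])^2
      if (any(d2 <= r2)) inside[i] <- TRUE
    }
  }
  inside
}

#' Composition of a circular home range
#' @param map a `landscape_map`; @param cx,cy centre; @param r radius (m);
#' @param focal "woodland" or "grassland"; @param n_points quadrature points.
#' @return Proportion of the focal class within the circle (clipped to the
#'   mapped extent).
#' @export
circle_composition <- function(map, cx, cy, r, focal = c("woodland", "grassland"),
                               n_points = 500) {
  focal <- match.arg(focal)
  comp <- region_composition(map, list(center = c(cx, cy), radius = r),
                             n_points = n_points)
  unname(comp[focal])
}

#' Sample random circular home ranges ("available")
#'
#' Circle centres drawn uniformly within the availability region by
#' rejection sampling over its bounding box; each circle's focal-class
#' composition is computed on the mapped landscape. Circles may overhang
#' the region edge (composition is clipped to the mapped extent), unless
#' `require_containment`.
#'
#' @param region an `avail_region`; @param map a `landscape_map`;
#' @param n circles (default 1000); @param focal focal vegetation class;
#' @param seed RNG seed; @param n_points quadrature points per circle;
#' @param require_containment reject centres closer than r to the region
#'   boundary proxy (centre containment only by default).
#' @return Data frame: x, y, comp (focal proportion), used = FALSE.
#' @export
sample_circle_hrs <- function(region, map, n = 1000L, focal = c("woodland", "grassland"),
                              seed = 1L, n_points = 500, require_containment = FALSE) {
  focal <- match.arg(focal)
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0),
                                 comp = numeric(0), used = logical(0)))
  set.seed(seed)
  b <- region$bbox
  # clip the sampling window to the mapped extent so compositions exist
  e <- map$extent
  b <- c(max(b[1L], e[1L]), min(b[2L], e[2L]), max(b[3L], e[3L]), min(b[4L], e[4L]))
  centres <- matrix(NA_real_, n, 2L)
  got <- 0L; tried <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 100L)
    px <- stats::runif(m, b[1L], b[2L])
    py <- stats::runif(m, b[3L], b[4L])
    ok <- region_contains(region, px, py)
    tried <- tried + m
    if (tried > 1e4 && got / tried < 1e-4) stop("degenerate availability region: acceptance rate < 1e-4")
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n - got))]
      centres[got + seq_along(take), ] <- cbind(px[take], py[take])
      got <- got + length(take)
    }
  }
  comp <- vapply(seq_len(n), function(i)
    circle_composition(map, centres[i, 1L], centres[i, 2L], region$r_median,
                       focal, n_points), numeric(1))
  data.frame(x = centres[, 1L], y = centres[, 2L], comp = comp, used = FALSE)
}

#' Weighted used-available resource selection function
#'
#' Logistic regression of used (1) versus available (0) home ranges on the
#' focal-class composition, with every available record down-weighted by
#' n_used / n_available so the available sample carries the same total
#' weight as the used sample (balanced comparison; avoids inflating
#' precision with the large available sample).
#'
#' @param used_comp focal compositions of observed home ranges.
#' @param avail_comp focal compositions of the random circles.
#' @return An `rsf_fit`: beta (composition coefficient), se, z, p,
#'   intercept, weights used, and a separation flag.
#' @export
fit_weighted_rsf <- function(used_comp, avail_comp) {
  n_used <- length(used_comp); n_avail <- length(avail_comp)
  if (n_used == 0L || n_avail == 0L) stop("both used and available samples required")
  w_avail <- n_used / n_avail
  df <- data.frame(y = rep(c(1, 0), c(n_used, n_avail)),
                   comp = c(used_comp, avail_comp),
                   w = rep(c(1, w_avail), c(n_used, n_avail)))
  fit <- withCallingHandlers(
    stats::glm(y ~ comp, family = stats::binomial(), data = df, weights = df$w),
    warning = function(w) {
      if (grepl("non-integer #successes", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  sep <- !fit$converged || abs(sm["comp", 1L]) > 25
  if (sep) warning("possible separation in the used-available comparison")
  structure(list(beta = sm["comp", 1L], se = sm["comp", 2L],
                 z = sm["comp", 3L], p = sm["comp", 4L],
                 intercept = sm["(Intercept)", 1L],
                 n_used = n_used, n_available = n_avail, w_available = w_avail,
                 separation = sep, glm = fit),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("weighted RSF: beta = %.4g (SE %.4g), z = %.3g, p = %.3g\n",
              x$beta, x$se, x$z, x$p))
  cat(sprintf("  n_used = %d, n_available = %d (weight %.3g each)\n",
              x$n_used, x$n_available, x$w_available))
  invisible(x)
}

#' @export
coef.rsf_fit <- function(object, ...) c(intercept = object$intercept, comp = object$beta)
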