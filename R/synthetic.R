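# Synthetic landscapes and GPS trajectories with known selection structure.
# The generator is the data-generating process the step-selection function
# consistently estimates: candidate endpoints from a gamma/von Mises
# movement kernel, one selected with probability proportional to
# exp(x' beta) under the same covariate encoding the fitter uses.

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; kappa = 0 gives the uniform circle.
#'
#' @param n draws; @param mu mean direction (rad); @param kappa concentration.
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u <- stats::runif(3)
        z <- cos(pi * u[1L])
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) break
      }
      th[i] <- sign(u[3L] - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
    th <- th + mu
  }
  th <- ((th + pi) %% (2 * pi)) - pi
  th[th == -pi] <- pi
  th
}

# separable Gaussian smoothing of a matrix (reflected edges)
smooth_field <- function(m, sigma_cells) {
  half <- max(1L, min(ceiling(3 * sigma_cells), nrow(m) - 1L, ncol(m) - 1L))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
    stats::filter(vp, k, sides = 2)[half + seq_along(v)]
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(t(m), 2L, pad_conv))
}

#' Synthetic landscape configuration
#'
#' Defaults emulate the mapped study regime: ~19% grassland / 81% open
#' woodland from a thresholded smooth random field, sparse unsealed roads
#' whose 10 m buffers cover well under 1% of the area, scattered
#' hydrological polygons near 3-4% after 20 m buffering, and a continuous
#' cover index classified into three Jenks classes.
#'
#' @param extent_m square landscape edge (default 40,000 m, the order of
#'   the real study area).
#' @param grass_frac grassland target fraction (default 0.19).
#' @param n_roads number of road polylines (default 15; a track spacing of
#'   2-3 km keeps roads present within every simulated home range while the
#'   buffered fraction stays below 1% of the area).
#' @param n_hydro number of hydrological polygons (default 60).
#' @param hydro_radius_m range of hydro feature radii (default 300-800 m;
#'   with the 20 m buffer this lands near the mapped ~3.8% hydro fraction).
#' @param corr_len_m correlation length of the random fields (default 6000,
#'   giving broad vegetation mosaics spanning several kilometres, the
#'   regime of the semi-arid study landscape).
#' @param cell_m raster cell edge (default 400 m).
#' @param seed RNG seed.
#' @return Config list for [simulate_landscape()].
#' @export
sim_landscape_config <- function(extent_m = 40000, grass_frac = 0.19,
                                 n_roads = 15L, n_hydro = 60L,
                                 hydro_radius_m = c(300, 800),
                                 corr_len_m = 6000, cell_m = 400, seed = 1L) {
  list(extent_m = extent_m, grass_frac = grass_frac, n_roads = n_roads,
       n_hydro = n_hydro, hydro_radius_m = hydro_radius_m,
       corr_len_m = corr_len_m, cell_m = cell_m, seed = seed)
}

#' Simulate a landscape map
#'
#' @param config from [sim_landscape_config()].
#' @return A `landscape_map` with a raster vegetation layer. Attribute
#'   `composition` reports realized class fractions.
#' @export
simulate_landscape <- function(config = sim_landscape_config()) {
  set.seed(config$seed)
  E <- config$extent_m
  nc <- as.integer(round(E / config$cell_m))
  sig <- config$corr_len_m / config$cell_m
  # vegetation: grassland where a smooth field is below its target quantile
  f <- smooth_field(matrix(stats::rnorm(nc * nc), nc, nc), sig)
  grass <- if (config$grass_frac <= 0) {
    matrix(FALSE, nc, nc)
  } else if (config$grass_frac >= 1) {
    matrix(TRUE, nc, nc)
  } else f <= stats::quantile(f, config$grass_frac)
  # roads: polylines crossing the extent with a midpoint jitter
  roads <- if (config$n_roads > 0) {
    parts <- lapply(seq_len(config$n_roads), function(i) {
      if (i %% 2L == 1L) {
        y0 <- stats::runif(1, 0.1 * E, 0.9 * E)
        mid <- c(stats::runif(1, 0.3 * E, 0.7 * E), y0 + stats::rnorm(1, 0, 0.05 * E))
        rbind(c(0, y0), mid, c(E, y0 + stats::rnorm(1, 0, 0.05 * E)))
      } else {
        x0 <- stats::runif(1, 0.1 * E, 0.9 * E)
        mid <- c(x0 + stats::rnorm(1, 0, 0.05 * E), stats::runif(1, 0.3 * E, 0.7 * E))
        rbind(c(x0, 0), mid, c(x0 + stats::rnorm(1, 0, 0.05 * E), E))
      }
    })
    list(kind = "lines", parts = parts)
  }
  # hydrological features: scattered polygons (discretized circles)
  hydro <- if (config$n_hydro > 0) {
    parts <- lapply(seq_len(config$n_hydro), function(i) {
      r <- stats::runif(1, config$hydro_radius_m[1L], config$hydro_radius_m[2L])
      circle_ring(stats::runif(1, r, E - r), stats::runif(1, r, E - r), r, 24L)
    })
    list(kind = "polygons", parts = parts)
  }
  # continuous cover index on an independent correlated field, scaled 0-100
  cf <- smooth_field(matrix(stats::rnorm(nc * nc), nc, nc), sig / 1.5)
  cf <- (cf - min(cf)) / (max(cf) - min(cf)) * 100
  map <- landscape_map(extent = c(0, E, 0, E), roads = roads, hydro = hydro,
                       veg = list(kind = "raster", grid = grass,
                                  origin = c(0, 0), cellsize = config$cell_m),
                       cover = list(grid = cf, origin = c(0, 0),
                                    cellsize = config$cell_m))
  attr(map, "composition") <- c(
    grassland = mean(grass),
    attr(map$cover_classes, "proportions"))
  map
}

#' Species animal configuration for trajectory simulation
#'
#' Movement kernels are gamma step lengths and von Mises turning angles;
#' true selection coefficients use the standard design terms. Fix schedule
#' and movement cutoffs follow the species presets (2-h fixes / 20 m cutoff
#' for dingoes, 4-h / 35 m for cats).
#'
#' @param species "dingo" or "cat".
#' @param n_steps scheduled fixes to simulate (default 300).
#' @param beta named true selection coefficients; defaults:
#'   onroad_grass 1.5, offroad_wood 0.3, onroad_wood 1.0, hydro 0.5,
#'   cover_high 0.4, cover_low -0.3.
#' @param gamma_shape,gamma_scale step-length kernel (m); defaults: dingo
#'   shape 2 scale 300, cat shape 2 scale 150.
#' @param vm_kappa turning-angle concentration (default 0.5).
#' @param rest_prob probability a scheduled fix is a resting fix (default 0).
#' @param spike_rate probability a recorded fix is a positional spike
#'   exceeding the gallop speed (default 0).
#' @param n_candidates candidate endpoints per step (default 50).
#' @param start start location (default landscape centre).
#' @param seed RNG seed.
#' @return Config list for [simulate_track()].
#' @export
sim_animal_config <- function(species = c("dingo", "cat"), n_steps = 300L,
                              beta = c(onroad_grass = 1.5, offroad_wood = 0.3,
                                       onroad_wood = 1.0, hydro = 0.5,
                                       cover_high = 0.4, cover_low = -0.3),
                              gamma_shape = 2, gamma_scale = NULL,
                              vm_kappa = 0.5, rest_prob = 0, spike_rate = 0,
                              n_candidates = 50L, start = NULL, seed = 1L) {
  species <- match.arg(species)
  if (is.null(gamma_scale)) gamma_scale <- if (species == "dingo") 300 else 150
  params <- screening_params(species)
  list(species = species, n_steps = n_steps, beta = beta,
       gamma_shape = gamma_shape, gamma_scale = gamma_scale,
       vm_kappa = vm_kappa, rest_prob = rest_prob, spike_rate = spike_rate,
       n_candidates = n_candidates, start = start, seed = seed,
       fix_interval_h = params$fix_interval_h,
       move_threshold_m = params$move_threshold_m)
}

#' Simulate one GPS track on a landscape
#'
#' Correlated random walk with habitat selection: at each scheduled fix,
#' C candidate endpoints are drawn from the movement kernel and one is
#' selected with probability proportional to exp(x' beta). Resting bouts
#' (displacement below the species movement cutoff) and positional spike
#' outliers are injected at the configured rates. Candidates outside the
#' extent are resampled (the animal is reflected back into the study area).
#'
#' @param map a `landscape_map`; @param config from [sim_animal_config()].
#' @param animal_id id string; @param sex "M"/"F";
#' @param t0 timestamp of the first fix (default 2014-04-01 00:00 UTC).
#' @return A `gps_track` (release time 25 h before the first fix). The
#'   attribute `truth` stores the generating configuration and per-fix
#'   flags (resting, spike).
#' @export
simulate_track <- function(map, config, animal_id = "sim1", sex = "F",
                           t0 = as.POSIXct("2014-04-01 00:00:00", tz = "UTC")) {
  set.seed(config$seed)
  e <- map$extent
  pos <- config$start %||% c(mean(e[1:2]), mean(e[3:4]))
  bearing <- stats::runif(1, -pi, pi)
  n <- config$n_steps
  C <- config$n_candidates
  bnames <- names(config$beta)
  xs <- ys <- numeric(n)
  resting <- spikes <- logical(n)
  n_reflect <- 0L
  for (i in seq_len(n)) {
    if (stats::runif(1) < config$rest_prob) {
      d <- stats::runif(1, 0, 0.5 * config$move_threshold_m)
      a <- stats::runif(1, -pi, pi)
      cand <- c(pos[1L] + d * cos(a), pos[2L] + d * sin(a))
      cand[1L] <- min(max(cand[1L], e[1L]), e[2L])
      cand[2L] <- min(max(cand[2L], e[3L]), e[4L])
      pos <- cand
      resting[i] <- TRUE
    } else {
      len <- stats::rgamma(C, shape = config$gamma_shape, scale = config$gamma_scale)
      turn <- rvonmises(C, 0, config$vm_kappa)
      br <- bearing + turn
      cx <- pos[1L] + len * cos(br)
      cy <- pos[2L] + len * sin(br)
      out <- cx < e[1L] | cx > e[2L] | cy < e[3L] | cy > e[4L]
      tries <- 0L
      while (any(out)) {
        tries <- tries + 1L
        n_reflect <- n_reflect + sum(out)
        m <- sum(out)
        len2 <- stats::rgamma(m, shape = config$gamma_shape, scale = config$gamma_scale)
        turn2 <- rvonmises(m, 0, config$vm_kappa)
        br[out] <- bearing + turn2
        cx[out] <- pos[1L] + len2 * cos(br[out])
        cy[out] <- pos[2L] + len2 * sin(br[out])
        out <- cx < e[1L] | cx > e[2L] | cy < e[3L] | cy > e[4L]
        if (tries > 200L) { cx[out] <- pos[1L]; cy[out] <- pos[2L]; break }
      }
      X <- design_matrix(attribute_points(map, cx, cy))
      lp <- drop(X[, bnames, drop = FALSE] %*% config$beta)
      pr <- exp(lp - max(lp))
      pick <- sample.int(C, 1L, prob = pr)
      pos <- c(cx[pick], cy[pick])
      bearing <- br[pick]
    }
    xs[i] <- pos[1L]; ys[i] <- pos[2L]
  }
  # positional spikes: recorded (not true) locations displaced far enough
  # to violate the gallop speed at the nominal schedule
  gallop_m <- if (config$species == "dingo") 16e3 else 3.2e3
  spike_d <- 1.5 * gallop_m * config$fix_interval_h
  idx <- which(stats::runif(n) < config$spike_rate)
  idx <- idx[idx > 1L]
  for (i in idx) {
    a <- stats::runif(1, -pi, pi)
    # spiked records may leave the mapped extent, as real positional errors
    # do; the speed filter removes them before any habitat attribution
    xs[i] <- xs[i] + spike_d * cos(a)
    ys[i] <- ys[i] + spike_d * sin(a)
    spikes[i] <- TRUE
  }
  fixes <- data.frame(
    timestamp = t0 + (seq_len(n) - 1L) * config$fix_interval_h * 3600,
    x = xs, y = ys, elevation = 500 + stats::rnorm(n, 0, 5))
  tr <- gps_track(fixes, animal_id = animal_id, species = config$species,
                  sex = sex, fix_interval_h = config$fix_interval_h,
                  release_time = t0 - 25 * 3600)
  attr(tr, "truth") <- list(config = config, resting = resting, spikes = spikes,
                            n_reflected = n_reflect)
  tr
}

#' Simulate home-range centres with a compositional preference
#'
#' Second-order data-generating process: candidate centres are drawn
#' uniformly over the placeable extent and one is kept with probability
#' proportional to exp(beta_focal x focal composition) — the exponential
#' resource selection form the weighted RSF estimates.
#'
#' @param map a `landscape_map`; @param n centres to place;
#' @param r_m home-range circle radius (m);
#' @param beta_focal true selection strength on the focal composition
#'   (e.g. 2 = logit-2 preference);
#' @param focal "grassland" or "woodland"; @param seed RNG seed;
#' @param n_candidates uniform candidate pool size (default 40 x n);
#' @param n_points quadrature points per circle composition.
#' @return Data frame: x, y, comp (focal composition of each kept centre).
#' @export
simulate_hr_centers <- function(map, n, r_m, beta_focal, focal = c("grassland", "woodland"),
                                seed = 1L, n_candidates = 40L * n, n_points = 300) {
  focal <- match.arg(focal)
  set.seed(seed)
  e <- map$extent
  cx <- stats::runif(n_candidates, e[1L] + r_m, e[2L] - r_m)
  cy <- stats::runif(n_candidates, e[3L] + r_m, e[4L] - r_m)
  comp <- vapply(seq_len(n_candidates), function(i)
    circle_composition(map, cx[i], cy[i], r_m, focal, n_points), numeric(1))
  pick <- sample.int(n_candidates, n, prob = exp(beta_focal * comp))
  data.frame(x = cx[pick], y = cy[pick], comp = comp[pick])
}

#' Simulate a population of tracks with individual variation
#'
#' Independent tracks whose selection coefficients deviate from the
#' species-level beta by per-animal Gaussian offsets (applied to the
#' vegetation terms by default, mirroring a random vegetation slope).
#'
#' @param map a `landscape_map`; @param species "dingo" or "cat";
#' @param n_animals number of animals;
#' @param base_config from [sim_animal_config()] (seed field ignored);
#' @param sd_slope SD of per-animal deviations (default 0);
#' @param slope_terms coefficient names receiving the deviation (default
#'   the woodland terms, offroad_wood and onroad_wood);
#' @param seed master seed; per-animal seeds are derived from it.
#' @param t0 timestamp of each track's first fix.
#' @return List: `tracks` (list of `gps_track`), `truth` (species beta,
#'   per-animal beta matrix, seeds, configs).
#' @export
simulate_population <- function(map, species = c("dingo", "cat"), n_animals,
                                base_config = NULL, sd_slope = 0,
                                slope_terms = c("offroad_wood", "onroad_wood"),
                                seed = 1L,
                                t0 = as.POSIXct("2014-04-01 00:00:00", tz = "UTC")) {
  species <- match.arg(species)
  stopifnot(n_animals >= 1L)
  if (is.null(base_config)) base_config <- sim_animal_config(species)
  set.seed(seed)
  seeds <- sample.int(2^30, n_animals)
  devs <- stats::rnorm(n_animals, 0, sd_slope)
  e <- map$extent
  starts <- cbind(stats::runif(n_animals, e[1L] + 0.2 * (e[2L] - e[1L]),
                               e[2L] - 0.2 * (e[2L] - e[1L])),
                  stats::runif(n_animals, e[3L] + 0.2 * (e[4L] - e[3L]),
                               e[4L] - 0.2 * (e[4L] - e[3L])))
  tracks <- vector("list", n_animals)
  beta_mat <- matrix(NA_real_, n_animals, length(base_config$beta),
                     dimnames = list(NULL, names(base_config$beta)))
  for (i in seq_len(n_animals)) {
    cfg <- base_config
    cfg$seed <- seeds[i]
    cfg$start <- starts[i, ]
    cfg$beta[slope_terms] <- cfg$beta[slope_terms] + devs[i]
    beta_mat[i, ] <- cfg$beta
    tracks[[i]] <- simulate_track(map, cfg, animal_id = sprintf("%s%02d", species, i),
                                  sex = sample(c("M", "F"), 1L), t0 = t0)
  }
  list(tracks = tracks,
       truth = list(species = species, beta = base_config$beta,
                    beta_by_animal = beta_mat, sd_slope = sd_slope,
                    slope_terms = slope_terms, seeds = seeds, seed = seed))
}
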