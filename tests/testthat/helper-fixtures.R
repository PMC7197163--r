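# Shared fixtures, built in code. Expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Small deterministic landscape with polygon vegetation:
# 1 km x 1 km, one horizontal road at y = 500, one hydro square at
# (700..800)^2, grassland = left half, cover = 20 x 20 gradient raster.
test_map <- function() cached("test_map", {
  roads <- list(kind = "lines", parts = list(rbind(c(0, 500), c(1000, 500))))
  hydro <- list(kind = "polygons",
                parts = list(rbind(c(700, 700), c(800, 700), c(800, 800), c(700, 800))))
  grass <- list(kind = "polygons",
                parts = list(rbind(c(0, 0), c(500, 0), c(500, 1000), c(0, 1000))))
  cover <- list(grid = matrix(rep(seq(5, 100, length.out = 20), each = 20), 20, 20),
                origin = c(0, 0), cellsize = 50)
  landscape_map(extent = c(0, 1000, 0, 1000), roads = roads, hydro = hydro,
                veg = grass, cover = cover)
})

# Default synthetic landscape, shared across tests that need realism.
sim_map <- function() cached("sim_map", simulate_landscape(sim_landscape_config(seed = 42)))

# A hand-built track: n fixes on the species schedule starting at t0.
make_track <- function(x, y, species = "dingo", elevation = NULL,
                       t0 = as.POSIXct("2014-05-01 00:00:00", tz = "UTC"),
                       interval_h = NULL, animal_id = "a1",
                       release_time = t0 - 48 * 3600) {
  n <- length(x)
  if (is.null(interval_h)) interval_h <- if (species == "dingo") 2 else 4
  if (is.null(elevation)) elevation <- rep(500, n)
  gps_track(data.frame(timestamp = t0 + (seq_len(n) - 1L) * interval_h * 3600,
                       x = x, y = y, elevation = elevation),
            animal_id = animal_id, species = species,
            fix_interval_h = interval_h, release_time = release_time)
}

# Directly constructed conditional-logistic choice sets (no geometry):
# per stratum 1 used + K controls with the standard design columns, used
# alternative drawn by softmax of the true linear predictor. Fast path for
# fitter, random-effect and autocorrelation tests.
make_choice_data <- function(n_animals, strata_per_animal, beta, K = 20L,
                             sd_slope = 0, slope_terms = c("offroad_wood", "onroad_wood"),
                             seed = 1L) {
  set.seed(seed)
  rows <- vector("list", n_animals * strata_per_animal)
  k <- 0L
  t0 <- as.POSIXct("2014-05-01 00:00:00", tz = "UTC")
  for (a in seq_len(n_animals)) {
    b <- beta
    dev <- stats::rnorm(1, 0, sd_slope)
    b[slope_terms] <- b[slope_terms] + dev
    for (s in seq_len(strata_per_animal)) {
      m <- K + 1L
      wood <- stats::rbinom(m, 1, 0.6)
      road <- stats::rbinom(m, 1, 0.15)
      X <- cbind(onroad_grass = road * (1 - wood), offroad_wood = wood * (1 - road),
                 onroad_wood = road * wood, hydro = stats::rbinom(m, 1, 0.2),
                 cover_high = stats::rbinom(m, 1, 0.35),
                 cover_low = stats::rbinom(m, 1, 0.25))
      lp <- drop(X %*% b[colnames(X)])
      pick <- sample.int(m, 1L, prob = exp(lp))
      k <- k + 1L
      rows[[k]] <- data.frame(stratum = k, animal_id = sprintf("a%02d", a),
                              timestamp = t0 + s * 7200,
                              used = as.integer(seq_len(m) == pick), X)
    }
  }
  out <- do.call(rbind, rows)
  out$veg_wood <- out$offroad_wood + out$onroad_wood
  out
}

true_beta <- c(onroad_grass = 1.5, offroad_wood = 0.3, onroad_wood = 1.0,
               hydro = 0.5, cover_high = 0.4, cover_low = -0.3)

# exhaustive search over contiguous k-partitions of sorted values: the
# independent optimum the dynamic programme must match
jenks_oracle <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  best <- list(ssq = Inf)
  cuts <- utils::combn(n - 1L, k - 1L)
  for (j in seq_len(ncol(cuts))) {
    ends <- c(cuts[, j], n)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    ssq <- sum(vapply(seq_len(k), function(c) {
      x <- v[starts[c]:ends[c]]
      sum((x - mean(x))^2)
    }, numeric(1)))
    if (ssq < best$ssq) best <- list(ssq = ssq, ends = ends)
  }
  v[best$ends[-k]]
}

# Screened steps pooled over a small simulated population (cached).
sim_steps <- function() cached("sim_steps", {
  map <- sim_map()
  pop <- simulate_population(map, "dingo", 3,
                             base_config = sim_animal_config("dingo", n_steps = 150),
                             sd_slope = 0, seed = 99)
  steps <- NULL
  for (tr in pop$tracks) {
    params <- screening_params("dingo", window_end = max(tr$fixes$timestamp) + 1)
    steps <- rbind(steps, build_steps(screen_track(tr, params, 500)))
  }
  steps
})
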