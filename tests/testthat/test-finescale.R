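test_that("empirical movement distributions pool steps and guard small samples", {
  steps <- data.frame(animal_id = rep(c("a", "b"), c(20, 15)),
                      length_m = rep(120, 35),
                      turn = c(NA, rep(0.2, 34)))
  d <- empirical_move_dists(steps, "dingo")
  expect_equal(d$n_steps, 35L)
  expect_equal(length(d$lengths), 35L)
  expect_equal(length(d$angles), 34L)
  # degenerate distribution: the sampler can only return the single value
  expect_true(all(sample(d$lengths, 50, replace = TRUE) == 120))
  expect_error(empirical_move_dists(steps[1:10, ], "dingo"), "at least 30")
})

test_that("control steps follow the empirical kernel and respect the extent", {
  d <- structure(list(lengths = 100, angles = 0,
                      pairs = cbind(length = 100, angle = 0),
                      species = "dingo", n_steps = 31L), class = "move_dists")
  expect_equal(nrow(generate_control_steps(c(0, 0), 0.3, d, K = 0)), 0L)
  set.seed(1)
  pts <- generate_control_steps(c(0, 0), pi / 4, d, K = 20)
  # single length, zero turn: all controls collinear at distance 100
  expect_equal(sqrt(rowSums(pts^2)), rep(100, 20))
  expect_equal(unique(round(atan2(pts[, 2], pts[, 1]), 10)), round(pi / 4, 10))
  # distributional check: resampled lengths match the source sample
  steps <- data.frame(animal_id = "a", length_m = rgamma(400, 2, scale = 150),
                      turn = rvonmises(400, 0, 0.6))
  dist2 <- empirical_move_dists(steps, "dingo")
  set.seed(2)
  draws <- replicate(40, generate_control_steps(c(0, 0), 0, dist2, K = 20))
  lens <- sqrt(draws[, 1, ]^2 + draws[, 2, ]^2)
  ks <- suppressWarnings(ks.test(as.numeric(lens), dist2$lengths))
  expect_gt(ks$p.value, 0.01)
})

test_that("choice sets have one used and K controls attributed on the map", {
  steps <- sim_steps()
  map <- sim_map()
  dists <- empirical_move_dists(steps, "dingo")
  cs <- build_choice_sets(steps[1:40, ], dists, map, K = 20, seed = 2)
  counts <- table(cs$stratum)
  expect_true(all(counts == 21L))
  expect_equal(as.vector(tapply(cs$used, cs$stratum, sum)), rep(1, 40))
  expect_equal(levels(cs$road_veg)[1], "offroad_grass")
  expect_true(all(cs$veg_wood == (cs$offroad_wood | cs$onroad_wood)))
})

test_that("the conditional logistic likelihood at zero is uniform choice", {
  d <- make_choice_data(2, 25, true_beta, seed = 3)
  fit <- fit_clogit(d)
  expect_equal(fit$loglik_null, -50 * log(21))
})

test_that("the Newton fit matches a grid-search maximizer on a small problem", {
  set.seed(4)
  d <- do.call(rbind, lapply(1:3, function(s) {
    x <- rbinom(6, 1, 0.5)
    data.frame(stratum = s, used = as.integer(seq_len(6) == sample(6, 1, prob = exp(0.7 * x))),
               x = x)
  }))
  # ensure the covariate varies within strata and the optimum is finite
  d$x[d$used == 1][1] <- 1; d$x[d$used == 1][2] <- 0
  ll <- function(b) sum(vapply(split(d, d$stratum), function(s)
    b * s$x[s$used == 1] - log(sum(exp(b * s$x))), numeric(1)))
  grid <- seq(-4, 4, by = 1e-3)
  co <- grid[which.max(vapply(grid, ll, numeric(1)))]
  fine <- seq(co - 2e-3, co + 2e-3, by = 1e-5)
  co <- fine[which.max(vapply(fine, ll, numeric(1)))]
  fit <- fit_clogit(d, used ~ x)
  expect_equal(unname(coef(fit)), co, tolerance = 1e-4)
})

test_that("the fit agrees with the stratified Cox (clogit) oracle", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  d <- make_choice_data(4, 40, true_beta, seed = 5)
  fit <- fit_clogit(d)
  or <- clogit(used ~ onroad_grass + offroad_wood + onroad_wood +
                 hydro + cover_high + cover_low + strata(stratum), data = d)
  expect_equal(unname(coef(fit)), unname(coef(or)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(or)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(or)), tolerance = 1e-8)
})

test_that("stratum-constant structure is rejected or cancels", {
  d <- make_choice_data(2, 30, true_beta, seed = 6)
  d$const <- as.numeric(factor(d$animal_id))   # constant within every stratum
  expect_error(fit_clogit(d, used ~ const), "inestimable")
  # adding a stratum-constant shift to a covariate leaves the fit unchanged
  fit1 <- fit_clogit(d, used ~ hydro + cover_high)
  d2 <- d
  d2$hydro <- d2$hydro + 5 * d2$stratum
  fit2 <- fit_clogit(d2, used ~ hydro + cover_high)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("summary reports odds ratios consistent with the coefficients", {
  d <- make_choice_data(3, 40, true_beta, seed = 7)
  fit <- fit_clogit(d)
  sm <- summary(fit)$table
  expect_equal(sm$odds_ratio, exp(sm$beta))
  expect_equal(sm$ci_lo, exp(sm$beta - 1.96 * sm$se))
  # internal consistency of the odds-ratio framing
  expect_equal(exp(log(18.22)), 18.22)
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), unname(coef(fit) - qnorm(0.975) * fit$se))
})

test_that("deviance residuals follow the one-event Cox closed form", {
  d <- make_choice_data(2, 30, true_beta * 0, seed = 8)
  # beta = 0 data: fit close to zero, but check the exact beta = 0 residual
  # through the formula at p = 1/21
  p <- 1 / 21
  expected <- sign(1 - p) * sqrt(-2 * ((1 - p) + log(p)))
  fit <- fit_clogit(d)
  # direct evaluation oracle on the fitted probabilities
  r <- residuals(fit, type = "deviance")
  pu <- fit$p_used
  expect_equal(r, sign(1 - pu) * sqrt(-2 * ((1 - pu) + log(pu))), tolerance = 1e-12)
  expect_equal(mean(abs(r - expected) < 0.5), 1)  # near the uniform-choice value
  # perfect-prediction limit
  expect_equal(sign(1 - (1 - 1e-12)) * sqrt(-2 * ((1 - (1 - 1e-12)) + log(1 - 1e-12))),
               0, tolerance = 1e-5)
})

test_that("random vegetation slopes are detected and the intercept cancellation reported", {
  d0 <- make_choice_data(6, 60, true_beta, sd_slope = 0, seed = 9)
  f0 <- fit_clogit_ranef(d0)
  expect_equal(f0$ranef_sd, 0)
  expect_match(f0$ranef_note, "cancels")
  fx <- fit_clogit(d0)
  expect_equal(coef(f0), coef(fx), tolerance = 1e-6)
  expect_error(fit_clogit_ranef(d0[d0$animal_id == "a01", ]), "at least 2")
  # with real slope heterogeneity the variance estimate moves off zero
  hits <- 0L
  for (k in 1:3) {
    dk <- make_choice_data(15, 100, true_beta, sd_slope = 0.8, seed = 20 + k)
    fk <- fit_clogit_ranef(dk)
    hits <- hits + (fk$ranef_sd > 0)
  }
  expect_gte(hits, 2L)
})

test_that("diel and sex subsets split strata and skip undersized groups", {
  d <- make_choice_data(4, 40, true_beta, seed = 10)
  # force all used fixes to local noon (04:00 UTC at 121.56 E)
  d$timestamp <- as.POSIXct("2014-05-10 04:00:00", tz = "UTC") +
    3600 * 24 * (as.integer(factor(d$stratum)) %% 28)
  fits <- subset_fits(d, by = "diel")
  expect_true("diurnal" %in% names(fits))
  expect_false("nocturnal" %in% names(fits))
  expect_s3_class(fits$diurnal, "ssf_fit")
  # sex subsets: 3-animal female group has 120 strata, keep; shrink to force skip
  sex <- c(a01 = "M", a02 = "M", a03 = "F", a04 = "F")
  fits2 <- subset_fits(d[d$stratum %in% unique(d$stratum)[1:45], ],
                       by = "sex", sex_table = sex)
  expect_s3_class(fits2$M, "ssf_fit")
  expect_true(is.character(fits2$F) || is.character(fits2$M) ||
              all(vapply(fits2, inherits, TRUE, "ssf_fit")))
})

test_that("solar elevation separates local day from night at the site", {
  # 04:00 UTC = local noon at 121.56 E; 16:00 UTC = local midnight
  noon <- solar_elevation(as.POSIXct("2014-05-10 04:00:00", tz = "UTC"), -26.23, 121.56)
  midnight <- solar_elevation(as.POSIXct("2014-05-10 16:00:00", tz = "UTC"), -26.23, 121.56)
  expect_gt(noon, 20)
  expect_lt(midnight, -20)
})

test_that("feature correlations flag duplicates and report degenerate columns", {
  d <- make_choice_data(2, 30, true_beta, seed = 11)
  d$dup <- d$hydro
  d$flat <- 1
  fc <- feature_correlations(d, cols = c("hydro", "dup", "cover_high", "flat"),
                             threshold = 0.7)
  expect_equal(fc$r["hydro", "dup"], 1)
  expect_true(all(diag(fc$r)[1:3] == 1))
  expect_equal(fc$r, t(fc$r))
  expect_true("flat" %in% fc$zero_variance)
  expect_true(any(fc$flagged$a == "hydro" & fc$flagged$b == "dup"))
})
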