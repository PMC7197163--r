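test_that("reference bandwidth follows the bivariate-normal plug-in rule", {
  # exact axis variances of 4 by construction
  base <- scale(matrix(rnorm(64 * 2), 64, 2))
  xy <- base * 2
  expect_equal(reference_bandwidth(xy), 2 * 64^(-1 / 6), tolerance = 1e-12)
  # scale equivariance
  expect_equal(reference_bandwidth(xy * 2), 2 * reference_bandwidth(xy), tolerance = 1e-12)
  set.seed(3)
  z <- cbind(rnorm(40, sd = 120), rnorm(40, sd = 80))
  expect_equal(reference_bandwidth(z),
               sqrt((var(z[, 1]) + var(z[, 2])) / 2) * 40^(-1 / 6), tolerance = 1e-12)
  expect_error(reference_bandwidth(cbind(1:10, 1:10 * 0)), "variance")
  expect_error(reference_bandwidth(cbind(1:3, 4:6)), "at least 5")
})

test_that("the utilisation distribution conserves mass and matches brute force", {
  set.seed(8)
  xy <- cbind(rnorm(50, sd = 30), rnorm(50, sd = 30))
  h <- 20
  ud <- kde_ud(xy, h, cell_size = 5)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  # slow double loop over cells and points
  nc <- ncol(ud$mass); nr <- nrow(ud$mass)
  dens <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    cx <- ud$origin[1] + (cc - 0.5) * ud$cellsize
    cy <- ud$origin[2] + (r - 0.5) * ud$cellsize
    d2 <- (xy[, 1] - cx)^2 + (xy[, 2] - cy)^2
    dens[r, cc] <- mean(exp(-d2 / (2 * h^2))) / (2 * pi * h^2)
  }
  mass <- dens * ud$cellsize^2
  expect_lt(max(abs(mass / sum(mass) - ud$mass)), 1e-10)
  expect_error(kde_ud(xy, h, cell_size = 15), "cell_size")
})

test_that("a single-point UD is symmetric with the mode at the point", {
  ud <- kde_ud(cbind(10, -5), h = 2, cell_size = 0.4)
  top <- which(ud$mass == max(ud$mass), arr.ind = TRUE)
  cx <- ud$origin[1] + (top[1, 2] - 0.5) * ud$cellsize
  cy <- ud$origin[2] + (top[1, 1] - 0.5) * ud$cellsize
  expect_lt(abs(cx - 10), ud$cellsize)
  expect_lt(abs(cy + 5), ud$cellsize)
})

test_that("two distant points split the mass evenly", {
  ud <- kde_ud(rbind(c(0, 0), c(400, 0)), h = 10, cell_size = 2)
  cx <- ud$origin[1] + (seq_len(ncol(ud$mass)) - 0.5) * ud$cellsize
  left <- sum(ud$mass[, cx < 200])
  expect_equal(left, 0.5, tolerance = 0.01)
})

test_that("isopleths follow the chi-square closed form and are monotone", {
  ud <- kde_ud(cbind(0, 0), h = 1, cell_size = 0.05)
  hr95 <- isopleth(ud, 0.95)
  expect_equal(hr95$area_ha * 1e4, pi * qchisq(0.95, 2), tolerance = 0.03)
  hr50 <- isopleth(ud, 0.50)
  expect_lt(hr50$area_ha, hr95$area_ha)
  expect_equal(hr50$area_ha * 1e4, pi * qchisq(0.50, 2), tolerance = 0.03)
  expect_error(isopleth(ud, 1.2), "level")
})

test_that("a uniform UD selects exactly the requested fraction of cells", {
  ud <- structure(list(mass = matrix(1 / 400, 20, 20), origin = c(0, 0),
                       cellsize = 10, h = 25, n = 1L), class = "ud")
  hr <- isopleth(ud, 0.25)
  expect_equal(length(hr$cells), 100L)
  expect_equal(hr$cells, 1:100)   # deterministic tie-break by cell index
})

test_that("coarse and fine grids agree on the 95% area once cells are fine enough", {
  set.seed(14)
  xy <- cbind(rnorm(80, sd = 100), rnorm(80, sd = 100))
  h <- reference_bandwidth(xy)
  a4 <- isopleth(kde_ud(xy, h, cell_size = h / 4), 0.95)$area_ha
  a8 <- isopleth(kde_ud(xy, h, cell_size = h / 8), 0.95)$area_ha
  expect_equal(a4, a8, tolerance = 0.02)
})

test_that("the 95% KDE area oversmooths the true Gaussian ellipse from above", {
  set.seed(15)
  xy <- cbind(rnorm(400, sd = 100), rnorm(400, sd = 100))
  h <- reference_bandwidth(xy)
  a <- isopleth(kde_ud(xy, h, cell_size = h / 4), 0.95)$area_ha * 1e4
  expect_gt(a, pi * qchisq(0.95, 2) * 100^2)
})

test_that("MCP matches the shoelace value and an orientation oracle", {
  m <- mcp(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(m$area_m2, 6)
  m2 <- mcp(rbind(c(0, 0), c(4, 0), c(0, 3), c(1, 1)))   # interior point
  expect_equal(m2$area_m2, 6)
  expect_error(mcp(cbind(1:5, 2 * (1:5))), "collinear")
  set.seed(6)
  xy <- cbind(runif(60), runif(60))
  hull_idx <- sort(unique(as.vector(grDevices::chull(xy))))
  # oracle: i-j is a hull edge iff all points lie on one side of the line
  on_hull <- rep(FALSE, 60)
  for (i in 1:59) for (j in (i + 1):60) {
    d <- (xy[, 1] - xy[i, 1]) * (xy[j, 2] - xy[i, 2]) -
         (xy[, 2] - xy[i, 2]) * (xy[j, 1] - xy[i, 1])
    if (all(d >= -1e-12) || all(d <= 1e-12)) on_hull[c(i, j)] <- TRUE
  }
  expect_equal(hull_idx, which(on_hull))
})

test_that("asymptote analysis passes stationary use and fails non-stabilizing ranges", {
  set.seed(23)
  xy <- cbind(rnorm(200, sd = 50), rnorm(200, sd = 50))
  res <- asymptote_analysis(xy, increment = 25, n_reps = 3, seed = 1)
  expect_true(res$pass)
  expect_equal(res$curve$area_ratio[nrow(res$curve)], 1, tolerance = 1e-9)
  expect_gt(res$fix_fraction_inside, 0.75)
  # heavy-tailed excursions: the apparent range keeps growing with sample
  # size, so the area never settles into the stability band
  set.seed(24)
  xy2 <- cbind(rcauchy(200, scale = 30), rcauchy(200, scale = 30))
  res2 <- asymptote_analysis(xy2, increment = 25, n_reps = 3, seed = 1)
  expect_false(res2$pass)
  # the one-sided reading is recoverable as an option
  expect_true(asymptote_analysis(xy, increment = 25, n_reps = 3, seed = 1,
                                 rule = "reach")$pass)
})

test_that("group area comparison matches closed forms and handles degeneracy", {
  same <- compare_group_areas(rep(c(10, 20, 30), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$estimate, 0)
  expect_equal(same$p, 1)
  tenfold <- compare_group_areas(c(10, 10, 100, 100), c("a", "a", "b", "b"))
  expect_equal(tenfold$estimate, 1)
  set.seed(2)
  a <- rlnorm(8, 3, 0.4); b <- rlnorm(9, 4, 0.4)
  res <- compare_group_areas(c(a, b), rep(c("a", "b"), c(8, 9)))
  la <- log10(a); lb <- log10(b)
  est <- mean(lb) - mean(la)
  sp2 <- (sum((la - mean(la))^2) + sum((lb - mean(lb))^2)) / 15
  se <- sqrt(sp2 * (1 / 8 + 1 / 9))
  expect_equal(res$estimate, est, tolerance = 1e-12)
  expect_equal(res$se, se, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(est / se), 15), tolerance = 1e-12)
  expect_error(compare_group_areas(c(-1, 2, 3, 4), c("a", "a", "b", "b")), "log10")
})
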