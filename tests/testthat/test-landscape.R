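test_that("buffering a straight road gives rectangle-plus-caps area", {
  layer <- list(kind = "lines", parts = list(rbind(c(0, 0), c(1000, 0))))
  zone <- buffer_features(layer, 10)
  expect_s3_class(zone, "buffer_zone")
  a <- zone_area(zone, cell = 0.5)
  expect_equal(a, 1000 * 20 + pi * 100, tolerance = 0.01)
})

test_that("buffering an empty layer yields an empty zone", {
  zone <- buffer_features(list(kind = "lines", parts = list()), 10)
  expect_equal(zone_area(zone), 0)
  expect_equal(zone_contains(zone, 1, 1), FALSE)
})

test_that("self-crossing polyline buffer matches a Monte-Carlo area estimate", {
  line <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  zone <- buffer_features(list(kind = "lines", parts = list(line)), 10)
  a <- zone_area(zone, cell = 0.25)
  seg_len <- sum(sqrt(rowSums((line[-1, ] - line[-4, ])^2)))
  expect_lt(a, seg_len * 20 + 3 * pi * 100)  # overlap makes it smaller than the sum
  set.seed(4)
  px <- runif(2e5, -15, 115); py <- runif(2e5, -15, 115)
  mc <- mean(zone_contains(zone, px, py)) * 130^2
  expect_equal(a, mc, tolerance = 0.02)
})

test_that("geographic-looking coordinates are rejected", {
  layer <- list(kind = "lines", parts = list(rbind(c(121.5, -26.2), c(121.6, -26.3))))
  expect_error(buffer_features(layer, 10), "geographic")
})

test_that("jenks breaks split obviously gapped data and reject degenerate input", {
  br <- jenks_breaks(c(1, 2, 11, 12, 21, 22), 3)
  expect_equal(br, c(2, 12))
  expect_error(jenks_breaks(c(5, 5, 5, 5), 3), "distinct")
})

test_that("jenks equals the exhaustive-search optimum for small n and k", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(8:15, 1)
    k <- sample(2:4, 1)
    v <- round(runif(n, 0, 100), 3)
    expect_equal(jenks_breaks(v, k), jenks_oracle(v, k),
                 info = sprintf("seed %d n %d k %d", seed, n, k))
  }
})

test_that("cover classification matches direct counting and propagates NAs", {
  cl <- classify_cover(matrix(1:9, 3, 3), c(3, 6))
  expect_equal(unname(attr(cl, "proportions")), rep(1 / 3, 3))
  cl2 <- classify_cover(matrix(5, 4, 4), c(3, 6))
  expect_true(all(cl2 == 2L))
  set.seed(2)
  g <- matrix(rnorm(400), 20, 20)
  g[c(3, 77)] <- NA
  cl3 <- classify_cover(g, c(-0.5, 0.5))
  fin <- g[is.finite(g)]
  expect_equal(unname(attr(cl3, "proportions")),
               c(mean(fin <= -0.5), mean(fin > -0.5 & fin <= 0.5), mean(fin > 0.5)))
  expect_equal(attr(cl3, "n_missing"), 2L)
})

test_that("point attribution honours buffers, vegetation and the factor coding", {
  map <- test_map()
  a <- attribute_point(map, 100, 508)    # 8 m from the road centreline
  expect_true(a$on_road)
  expect_equal(as.character(a$road_veg), "onroad_grass")
  b <- attribute_point(map, 100, 513)    # 13 m away: outside the 10 m buffer
  expect_false(b$on_road)
  expect_equal(as.character(b$road_veg), "offroad_grass")
  expect_equal(levels(b$road_veg)[1L], "offroad_grass")
  w <- attribute_point(map, 750, 750)    # inside the hydro square, right half
  expect_true(w$on_hydro)
  expect_equal(as.character(w$veg), "woodland")
  expect_error(attribute_points(map, 1500, 500), "outside")
  # deterministic and idempotent
  expect_identical(attribute_point(map, 321, 654), attribute_point(map, 321, 654))
})

test_that("attribution agrees with a slow per-point geometric oracle", {
  map <- test_map()
  set.seed(11)
  px <- runif(400, 1, 999); py <- runif(400, 1, 999)
  got <- attribute_points(map, px, py)
  seg_dist <- function(x, y, a, b) {
    L2 <- sum((b - a)^2)
    tt <- max(0, min(1, sum((c(x, y) - a) * (b - a)) / L2))
    sqrt(sum((c(x, y) - (a + tt * (b - a)))^2))
  }
  in_poly <- function(x, y, ring) {
    n <- nrow(ring); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((ring[i, 2] > y) != (ring[j, 2] > y) &&
          x < ring[i, 1] + (y - ring[i, 2]) * (ring[j, 1] - ring[i, 1]) /
                (ring[j, 2] - ring[i, 2]))
        inside <- !inside
      j <- i
    }
    inside
  }
  for (i in seq_along(px)) {
    road <- seg_dist(px[i], py[i], c(0, 500), c(1000, 500)) <= 10
    hring <- rbind(c(700, 700), c(800, 700), c(800, 800), c(700, 800))
    hyd <- in_poly(px[i], py[i], hring) ||
      min(vapply(1:4, function(e) {
        a <- hring[e, ]; b <- hring[e %% 4 + 1, ]
        seg_dist(px[i], py[i], a, b)
      }, numeric(1))) <= 20
    grass <- px[i] <= 500
    expect_equal(got$on_road[i], road)
    expect_equal(got$on_hydro[i], hyd)
    expect_equal(as.character(got$veg[i]), if (grass) "grassland" else "woodland")
  }
})

test_that("region composition is exact on simple regions and sums to one", {
  map <- test_map()
  sq <- rbind(c(250, 100), c(750, 100), c(750, 300), c(250, 300))
  comp <- region_composition(map, sq, n_points = 4e4)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_equal(unname(comp["grassland"]), 0.5, tolerance = 0.01)
  wood <- region_composition(map, rbind(c(600, 50), c(900, 50), c(900, 200), c(600, 200)))
  expect_equal(unname(wood["woodland"]), 1.0)
  expect_error(region_composition(map, rbind(c(1, 1), c(1, 1), c(1, 1))), "zero-area")
})

test_that("composition of an irregular region matches a Monte-Carlo oracle", {
  map <- test_map()
  ring <- circle_ring(480, 420, 260, 48)
  comp <- region_composition(map, ring, n_points = 1e5)
  set.seed(21)
  px <- runif(3e5, 220, 740); py <- runif(3e5, 160, 680)
  keep <- point_in_ring(px, py, ring)
  mc <- mean(px[keep] <= 500)
  expect_equal(unname(comp["grassland"]), mc, tolerance = 0.01)
})
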