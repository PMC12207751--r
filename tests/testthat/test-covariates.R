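test_that("distance to a target set matches the brute-force oracle", {
  g <- build_grid(c(0, 80, 0, 80), 4)
  expect_error(distance_to_set(g, cbind(numeric(0), numeric(0))), "empty")
  # single target at the origin: 3-4-5 triangle at centre (6, 10)
  d <- distance_to_set(g, cbind(6 - 3, 10 - 4))
  cc <- cell_centres(g)
  k <- which(cc$x == 6 & cc$y == 10)
  expect_equal(d[k], 5, tolerance = 1e-12)
  # a centre lying on the target has distance zero
  d0 <- distance_to_set(g, cbind(6, 10))
  expect_equal(d0[k], 0)
  # random target cloud vs exhaustive min over vertices
  set.seed(2)
  tg <- cbind(runif(37, 0, 80), runif(37, 0, 80))
  d <- distance_to_set(g, tg)
  for (k in sample(nrow(cc), 25)) {
    oracle <- min(sqrt((cc$x[k] - tg[, 1])^2 + (cc$y[k] - tg[, 2])^2))
    expect_equal(d[k], oracle, tolerance = 1e-9)
  }
})

test_that("terrain gradient is exact on planes and matches a finite-difference oracle", {
  g <- build_grid(c(0, 80, 0, 80), 4)
  cc <- cell_centres(g)
  flat <- matrix(3.7, g$nx, g$ny)
  expect_lt(max(abs(terrain_gradient(flat, 4))), 1e-12)
  ramp <- matrix(2 * cc$x, g$nx, g$ny)            # f = 2x per km
  gr <- terrain_gradient(ramp, 4)
  expect_equal(gr[2:(g$nx - 1), ], matrix(2, g$nx - 2, g$ny), tolerance = 1e-12)
  # linearity
  set.seed(3)
  f1 <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  plane <- matrix(0.5 * cc$x - 0.2 * cc$y, g$nx, g$ny)
  # gradient of a plane is constant; Horn weights are exact on planes
  gp <- terrain_gradient(plane, 4)
  expect_equal(gp[5, 5], sqrt(0.5^2 + 0.2^2), tolerance = 1e-12)
  # interior cells vs straightforward central-difference Sobel oracle
  gr1 <- terrain_gradient(f1, 4)
  for (k in 1:15) {
    i <- sample(2:(g$nx - 1), 1); j <- sample(2:(g$ny - 1), 1)
    gx <- (f1[i + 1, j - 1] + 2 * f1[i + 1, j] + f1[i + 1, j + 1] -
             f1[i - 1, j - 1] - 2 * f1[i - 1, j] - f1[i - 1, j + 1]) / (8 * 4)
    gy <- (f1[i - 1, j + 1] + 2 * f1[i, j + 1] + f1[i + 1, j + 1] -
             f1[i - 1, j - 1] - 2 * f1[i, j - 1] - f1[i + 1, j - 1]) / (8 * 4)
    expect_equal(gr1[i, j], sqrt(gx^2 + gy^2), tolerance = 1e-10)
  }
  # missing neighbours propagate
  f1[10, 10] <- NA
  expect_true(is.na(terrain_gradient(f1, 4)[11, 10]))
})

test_that("IDW interpolation follows the weighted formula with exact-hit rule", {
  src <- data.frame(x = c(0, 2), y = c(0, 0), value = c(10, 20))
  expect_equal(idw_append(src, data.frame(x = 1, y = 0)), 15)
  expect_equal(idw_append(src, data.frame(x = 0, y = 0)), 10)
  expect_error(idw_append(src[0, ], data.frame(x = 1, y = 0)), "source")
  expect_true(is.na(idw_append(src, data.frame(x = 50, y = 50),
                               max_radius = 10)))
  set.seed(4)
  src5 <- data.frame(x = runif(5), y = runif(5), value = rnorm(5))
  q <- data.frame(x = runif(7), y = runif(7))
  got <- idw_append(src5, q, power = 2)
  for (k in seq_len(7)) {
    d <- sqrt((src5$x - q$x[k])^2 + (src5$y - q$y[k])^2)
    w <- d^-2
    expect_equal(got[k], sum(w * src5$value) / sum(w), tolerance = 1e-12)
  }
})

test_that("temporal matching maps days to 8-day composite windows", {
  expect_equal(composite_window(195), c(193, 200))
  expect_equal(composite_window(1), c(1, 8))
  expect_equal(composite_window(8), c(1, 8))
  expect_equal(composite_window(9), c(9, 16))
  layers <- list("193" = matrix(1, 2, 2), "201" = matrix(2, 2, 2))
  expect_equal(temporal_match(layers, 195), matrix(1, 2, 2))
  expect_error(temporal_match(layers, 100), "no composite")
  daily <- setNames(lapply(193:200, function(d) matrix(35, 2, 2)),
                    as.character(193:200))
  expect_equal(temporal_match(daily, 195, daily = TRUE), matrix(35, 2, 2))
  expect_error(temporal_match(daily[1:5], 195, daily = TRUE), "cover")
})

test_that("colony proximity score follows pairs / d^2 with the d_min clamp", {
  # open sea with a tiny island hosting the colony
  cfg <- world_config(extent = c(0, 80, 0, 80),
                      land_spec = list(list(x = 38, y = 38, rx = 1, ry = 1)))
  w <- gen_environment(cfg, seed = 1)
  colony <- data.frame(name = "A", x = 37.9, y = 36, pairs = 100)
  sc <- colony_proximity_score(w, colony)
  expect_length(which(as.vector(w$land)), 1L)
  # the colony snaps to the uniquely nearest sea cell, centre (38, 34),
  # id 170; its own distance is clamped at cell/2 = 2 km
  expect_equal(sc[170], 100 / 4, tolerance = 1e-12)
  # a cell 8 km straight down the same column: pairs / 8^2
  expect_equal(sc[130], 100 / 8^2, tolerance = 1e-12)
  # a cell 10 km away has no straight over-sea row; octile distance applies
  expect_true(all(is.na(sc[as.vector(w$land)])))
})

test_that("land-avoiding distances equal a brute-force Dijkstra around a barrier", {
  # 20 x 20 grid with a wall forcing a detour
  cfg <- world_config(extent = c(0, 80, 0, 80),
                      land_spec = list(list(x = 40, y = 36, rx = 3.9, ry = 30)))
  w <- gen_environment(cfg, seed = 1)
  colony_xy <- c(58, 10)   # east of the wall; snapped to nearest sea cell
  d_pkg <- sea_distance_km(w, rbind(colony_xy))
  # independent O(V^2) Dijkstra over the same 8-connected sea graph
  sea <- which(!as.vector(w$land))
  idx <- match(seq_len(n_cells(w$grid)), sea)
  nx <- w$grid$nx
  edges <- NULL
  for (v in sea) {
    i <- (v - 1) %% nx + 1; j <- (v - 1) %/% nx + 1
    for (s in list(c(1, 0, 4), c(0, 1, 4), c(1, 1, 4 * sqrt(2)),
                   c(1, -1, 4 * sqrt(2)))) {
      i2 <- i + s[1]; j2 <- j + s[2]
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > w$grid$ny) next
      u <- (j2 - 1) * nx + i2
      if (is.na(idx[u])) next
      edges <- rbind(edges, c(idx[v], idx[u], s[3]))
    }
  }
  cc <- cell_centres(w$grid)
  src <- sea[which.min((cc$x[sea] - colony_xy[1])^2 +
                         (cc$y[sea] - colony_xy[2])^2)]
  d_or <- oracle_dijkstra(length(sea), edges, match(src, sea))
  expect_equal(d_pkg[sea, 1], d_or, tolerance = 1e-12)
  # scores from those distances match the closed formula exactly
  colonies <- data.frame(name = "A", x = colony_xy[1], y = colony_xy[2],
                         pairs = 250)
  # colony must sit on land for the public API; use the wall itself
  colonies2 <- data.frame(name = "A", x = 40, y = 36, pairs = 250)
  sc <- colony_proximity_score(w, colonies2)
  d2 <- pmax(sea_distance_km(w, cbind(40, 36)), 2)
  expect_equal(sc[sea], 250 / d2[sea, 1]^2, tolerance = 1e-12)
  # removing the barrier never increases any land-avoiding distance
  w_open <- gen_environment(world_config(extent = c(0, 80, 0, 80),
                                         land_spec = list()), seed = 1)
  d_open <- sea_distance_km(w_open, rbind(colony_xy))
  expect_true(all(d_open[sea, 1] <= d_pkg[sea, 1] + 1e-12))
})

test_that("Box-Cox transforms round-trip and improve normality", {
  set.seed(5)
  x <- rlnorm(400, 0, 0.9)
  for (l in c(-1.15, 0, 0.14, 1)) {
    bc <- boxcox_fit(x, lambda = l)
    expect_equal(boxcox_inverse(bc, bc$y), x, tolerance = 1e-10)
    xf <- rexp(31) + 0.05
    expect_equal(boxcox_inverse(bc, boxcox_apply(bc, xf)), xf,
                 tolerance = 1e-10)
  }
  expect_equal(boxcox_fit(5, lambda = 1)$y, 4)
  expect_equal(boxcox_fit(exp(1), lambda = 0)$y, 1)
  # estimated lambda: skewness shrinks toward zero on log-normal data
  bc <- boxcox_fit(x)
  expect_lt(abs(bc$lambda), 0.3)   # log-normal: lambda near 0
  expect_lt(abs(sample_skewness(bc$y)), abs(sample_skewness(x)))
  # shift handling for non-positive input
  xneg <- x - 2
  bcn <- boxcox_fit(xneg)
  expect_equal(bcn$shift, 1 - min(xneg))
  expect_equal(boxcox_inverse(bcn, bcn$y), xneg, tolerance = 1e-10)
})

test_that("estimated lambda agrees with the MASS profile-likelihood oracle", {
  skip_if_not_installed("MASS")
  set.seed(6)
  x <- rgamma(300, shape = 2, rate = 0.5)
  bc <- boxcox_fit(x)
  prof <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  l_mass <- prof$x[which.max(prof$y)]
  expect_lt(abs(bc$lambda - l_mass), 0.02)
})

test_that("auto Box-Cox stores transforms and reapplies the same lambda", {
  s <- quick_survey(seed = 12)
  cv <- build_covariates(s$world)
  cv$chl_a <- exp(3 * log(pmax(cv$chl_a, 1e-6)))  # force strong skew
  tcv <- auto_boxcox(cv, vars = c("chl_a"), skew_threshold = 0.5)
  tf <- attr(tcv, "boxcox")
  expect_true("chl_a" %in% names(tf))
  new <- data.frame(chl_a = c(0.5, 1.2))
  out <- reapply_boxcox(tcv, new)
  expect_equal(out$chl_a, boxcox_apply(tf$chl_a, new$chl_a))
  # the stored lambda is reused, not re-estimated: inject a distinct lambda
  tf$chl_a$lambda <- 0.77
  attr(tcv, "boxcox") <- tf
  out2 <- reapply_boxcox(tcv, new)
  expect_equal(out2$chl_a, boxcox_apply(tf$chl_a, new$chl_a))
  expect_false(isTRUE(all.equal(out$chl_a, out2$chl_a)))
})
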