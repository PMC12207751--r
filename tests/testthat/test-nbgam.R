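test_that("negative-binomial log-likelihood matches closed forms", {
  # Poisson limit at y = 0, mu = 1
  expect_equal(nb_loglik(0, 1, Inf), -1)
  expect_equal(nb_loglik(0, 1, 1e12), -1, tolerance = 1e-6)
  # direct formula at y = 2, mu = 2, theta = 1
  y <- 2; mu <- 2; th <- 1
  direct <- log(th^th * mu^y * gamma(y + th) /
                  (gamma(th) * factorial(y) * (mu + th)^(y + th)))
  expect_equal(nb_loglik(y, mu, th), direct, tolerance = 1e-12)
  # the likelihood in mu is maximised at the observed count
  lls <- vapply(seq(2, 9, by = 0.25), function(m) nb_loglik(5, m, 2), 0)
  expect_equal(seq(2, 9, by = 0.25)[which.max(lls)], 5)
  expect_error(nb_loglik(-1, 1, 1), "non-negative")
  expect_error(nb_loglik(1, -1, 1), "positive")
  expect_error(nb_loglik(1, 1, 0), "theta")
})

test_that("a k = 5 spline yields 4 centred columns with a diagonal double penalty", {
  set.seed(1)
  d <- data.frame(xv = runif(100))
  b <- build_basis(s_tp("xv", k = 5), d)
  expect_equal(ncol(b$X), 4L)
  expect_equal(unname(colMeans(b$X)), rep(0, 4), tolerance = 1e-12)
  expect_length(b$penalties, 2L)       # wiggliness + null-space shrinkage
  expect_error(build_basis(s_tp("xv", k = 50), d[1:20, , drop = FALSE]),
               "lower k")
  expect_error(s_tp("xv", k = 2), "k must be")
})

test_that("with both penalties at infinity the smooth collapses to zero", {
  set.seed(2)
  n <- 300
  d <- data.frame(count = rpois(n, 2), effort_km2 = rep(1, n),
                  xv = runif(n))
  ft <- dsm_gam(d, smooths = list(s_tp("xv")), sp = c(1e12, 1e12))
  cl <- ft$design$term_cols[["s(xv)"]]
  sm <- ft$design$X[, cl, drop = FALSE] %*% ft$beta[cl]
  expect_lt(max(abs(sm)), 1e-6)
  expect_lt(sum(ft$F_diag[cl]), 1e-4)
})

test_that("intercept-only fit recovers the closed-form null estimate", {
  set.seed(3)
  a <- rep(2.5, 150)
  y <- rpois(150, 1.3 * a)
  d <- data.frame(count = y, effort_km2 = a)
  for (fam in list(list(family = "nb", theta = 2), list(family = "poisson"))) {
    ft <- do.call(dsm_gam, c(list(data = d), fam))
    expect_equal(unname(ft$beta[1]), log(mean(y) / 2.5), tolerance = 1e-8)
  }
})

test_that("theta -> infinity reproduces the Poisson fit", {
  set.seed(4)
  n <- 250
  x <- runif(n); a <- runif(n, 0.5, 2)
  y <- rpois(n, exp(0.2 + 0.9 * x) * a)
  d <- data.frame(count = y, effort_km2 = a, xv = x)
  ft <- dsm_gam(d, para = "xv", family = "nb", theta = 1e8, gamma = 1)
  or <- stats::glm(count ~ xv + offset(log(effort_km2)),
                   family = stats::poisson(), data = d)
  expect_lt(max(abs(ft$beta - coef(or))), 1e-4)
})

test_that("the offset contract shifts only the intercept", {
  set.seed(5)
  n <- 400
  x <- runif(n); a <- runif(n, 0.5, 2)
  y <- rnbinom(n, size = 2, mu = exp(-0.5 + sin(2 * pi * x)) * a)
  d <- data.frame(count = y, effort_km2 = a, xv = x)
  f1 <- dsm_gam(d, smooths = list(s_tp("xv")), theta = 2, sp = c(1, 1))
  d2 <- d; d2$effort_km2 <- d$effort_km2 * 7
  f2 <- dsm_gam(d2, smooths = list(s_tp("xv")), theta = 2, sp = c(1, 1))
  expect_equal(unname(f2$beta[1] - f1$beta[1]), -log(7), tolerance = 1e-6)
  expect_equal(unname(f2$beta[-1]), unname(f1$beta[-1]), tolerance = 1e-6)
})

test_that("prediction reproduces training fits and scales exactly with the offset", {
  set.seed(6)
  n <- 300
  d <- data.frame(count = rnbinom(n, size = 2, mu = 1),
                  effort_km2 = runif(n, 0.5, 2),
                  xv = runif(n), fac = sample(c("a", "b"), n, TRUE))
  ft <- dsm_gam(d, smooths = list(s_tp("xv")), para = "fac")
  expect_equal(predict(ft, d), ft$fitted, tolerance = 1e-10)
  expect_equal(predict(ft, d, offset_km2 = 2 * d$effort_km2), 2 * ft$fitted,
               tolerance = 1e-10)
  dbad <- d; dbad$fac[1] <- "c"
  expect_error(predict(ft, dbad), "unknown level")
  dout <- d; dout$xv[1] <- 2
  expect_error(predict(ft, dout), "support")
  expect_silent(predict(ft, dout, extrapolate = TRUE))
})

test_that("deviance explained is zero for the null model and grows with signal", {
  set.seed(7)
  n <- 500
  x <- runif(n)
  d <- data.frame(count = rnbinom(n, size = 2, mu = exp(-0.5 + 1.5 * x)),
                  effort_km2 = rep(1, n), xv = x)
  f0 <- dsm_gam(d, theta = 2)
  expect_equal(f0$dev_expl, 0, tolerance = 1e-7)
  f1 <- dsm_gam(d, smooths = list(s_tp("xv")), theta = 2)
  expect_gt(f1$dev_expl, 0.01)
  expect_lte(f1$dev_expl, 1)
  expect_lte(f1$deviance, f0$deviance + 1e-8)
})

test_that("effective degrees of freedom respect their bounds per term", {
  set.seed(8)
  n <- 600
  d <- data.frame(count = rnbinom(n, size = 2,
                                  mu = exp(-0.2 + sin(2 * pi * runif(n)))),
                  effort_km2 = rep(1, n))
  d$xv <- runif(n); d$zv <- runif(n)
  d$fac <- sample(c("lo", "hi"), n, TRUE)
  ft <- dsm_gam(d, smooths = list(s_tp("xv"), s_by("zv", "fac"),
                                  s_re("fac")))
  for (lab in names(ft$design$term_cols)) {
    cl <- ft$design$term_cols[[lab]]
    edf <- sum(ft$F_diag[cl])
    expect_gte(edf, -1e-8)
    expect_lte(edf, length(cl) + 1e-8)
  }
  expect_lte(ft$edf_total, ncol(ft$design$X))
})

test_that("the recovered smooth tracks a known sine effect", {
  set.seed(9)
  n <- 1200
  x <- runif(n); a <- runif(n, 0.5, 2)
  y <- rnbinom(n, size = 2, mu = exp(-1 + sin(2 * pi * x)) * a)
  d <- data.frame(count = y, effort_km2 = a, xv = x)
  ft <- dsm_gam(d, smooths = list(s_tp("xv")))
  cl <- ft$design$term_cols[["s(xv)"]]
  sm <- ft$design$X[, cl, drop = FALSE] %*% ft$beta[cl]
  expect_gt(stats::cor(sm, sin(2 * pi * x)), 0.95)
  expect_gt(ft$theta, 0.8)
  expect_lt(ft$theta, 5)
})

test_that("smooth fits agree closely with the mgcv reference on shared data", {
  skip_if_not_installed("mgcv")
  set.seed(10)
  n <- 800
  x <- runif(n); a <- runif(n, 0.5, 2)
  y <- rnbinom(n, size = 2, mu = exp(-0.8 + sin(2 * pi * x)) * a)
  d <- data.frame(count = y, effort_km2 = a, xv = x)
  ours <- dsm_gam(d, smooths = list(s_tp("xv")))
  ref <- mgcv::gam(count ~ s(xv, k = 5, bs = "ts") + offset(log(effort_km2)),
                   family = mgcv::nb(), data = d, method = "REML",
                   gamma = 1.2)
  mu_ref <- stats::predict(ref, type = "response")
  expect_gt(stats::cor(ours$fitted, mu_ref), 0.98)
  expect_lt(abs(ours$dev_expl - summary(ref)$dev.expl), 0.05)
})

test_that("fits error cleanly on invalid inputs", {
  d <- data.frame(count = c(1, 2), effort_km2 = c(1, 0))
  expect_error(dsm_gam(d), "effort")
  d2 <- data.frame(count = c(0.5, 1), effort_km2 = c(1, 1))
  expect_error(dsm_gam(d2), "integer")
  d3 <- data.frame(count = c(1, 2), effort_km2 = c(1, 1), xv = c(1, NA))
  expect_error(dsm_gam(d3, para = "xv"), "finite")
})
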