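test_that("winsorisation caps at the interpolated quantile and preserves ranks", {
  x <- c(rep(0, 40), 1000)
  cap <- oracle_quantile(x, 0.975)
  w <- winsorise(x)
  expect_equal(max(w), cap)
  expect_equal(w[1:40], x[1:40])
  # all-equal vector unchanged
  expect_equal(winsorise(rep(3, 17)), rep(3, 17))
  expect_error(winsorise(numeric(0)), "empty")
  set.seed(1)
  y <- rnbinom(200, size = 1, mu = 2)
  wy <- winsorise(y)
  expect_equal(max(wy), oracle_quantile(y, 0.975))
  expect_true(all(wy <= max(y)))
  # ranks of non-capped values unchanged
  keep <- y < oracle_quantile(y, 0.975)
  expect_equal(rank(wy[keep]), rank(y[keep]))
})

test_that("an intercept-only fit gives the closed-form whole-area total", {
  set.seed(2)
  n <- 200
  d <- data.frame(count = rpois(n, 2), effort_km2 = rep(1.6, n),
                  x = runif(n), y = runif(n))
  ft <- dsm_gam(d, theta = 5)
  pred <- d[1:50, ]
  est <- estimate_total(ft, pred, cell_area_km2 = 16)
  expect_equal(est$total,
               round(50 * 16 * exp(unname(ft$beta[1]))))
  expect_equal(est$total, round(est$total_unrounded))
  expect_true(all(est$cell_cv >= 0))
  # round-trip: the rounded total matches the per-cell sum to 0.5
  expect_lte(abs(est$total - sum(est$cell_pred)), 0.5)
})

test_that("prediction-grid construction standardizes conditions and reuses lambdas", {
  s <- quick_survey(seed = 3)
  cv <- auto_boxcox(build_covariates(s$world), vars = "chl_a",
                    skew_threshold = -1)   # force the transform
  pred <- build_prediction_grid(s$world, training_covariates = cv)
  expect_equal(nrow(pred), sum(!s$world$land))
  expect_true(all(pred$mean_ss == 0))
  expect_true(all(pred$altitude == "low"))
  expect_true(all(pred$julian_day == 195))
  tf <- attr(cv, "boxcox")
  raw <- build_covariates(s$world, year = "mean")
  expect_equal(pred$chl_a, boxcox_apply(tf$chl_a, raw$chl_a))
})

test_that("per-cell CV falls when the training sample grows", {
  make <- function(n, seed) {
    set.seed(seed)
    x <- runif(n)
    data.frame(count = rnbinom(n, size = 2, mu = exp(-0.5 + x)),
               effort_km2 = runif(n, 0.8, 1.6), xv = x)
  }
  d1 <- make(300, 4); d4 <- make(1200, 5)
  f1 <- dsm_gam(d1, smooths = list(s_tp("xv")), theta = 2)
  f4 <- dsm_gam(d4, smooths = list(s_tp("xv")), theta = 2)
  pr <- data.frame(xv = seq(0.05, 0.95, length.out = 40))
  e1 <- estimate_total(f1, pr)
  e4 <- estimate_total(f4, pr)
  expect_lt(stats::median(e4$cell_cv), stats::median(e1$cell_cv))
})

test_that("bootstrap intervals are reproducible, ordered and nested across levels", {
  s <- quick_survey(seed = 6, broad_spacing_km = 8)
  fit <- dsm_gam(s$records, smooths = list(s_tp("depth")))
  pred <- build_prediction_grid(s$world)
  b1 <- bootstrap_ci(fit, s$records, pred, B = 120, seed = 9)
  b2 <- bootstrap_ci(fit, s$records, pred, B = 120, seed = 9)
  expect_equal(b1$ci, b2$ci, tolerance = 1e-9)
  expect_lt(b1$ci[1], b1$ci[2])
  # nesting of percentile pairs on the same bootstrap sample
  q90 <- c(quantile(b1$boot_totals, 0.05, type = 7),
           quantile(b1$boot_totals, 0.95, type = 7))
  expect_gte(q90[1], b1$ci[1] - 1e-9)
  expect_lte(q90[2], b1$ci[2] + 1e-9)
  expect_error(bootstrap_ci(fit, s$records, pred, B = 50), "B must be")
})

test_that("a degenerate dataset yields a zero-width bootstrap interval", {
  d <- data.frame(count = rep(2L, 80), effort_km2 = rep(1, 80))
  ft <- dsm_gam(d, theta = 10)
  pred <- d[1:10, , drop = FALSE]
  bc <- bootstrap_ci(ft, d, pred, B = 100, seed = 1, cell_area_km2 = 1)
  expect_equal(unname(diff(bc$ci)), 0, tolerance = 1e-9)
})

test_that("the parametric bootstrap mode gives a comparable, cheaper interval", {
  s <- quick_survey(seed = 7, broad_spacing_km = 8)
  fit <- dsm_gam(s$records, smooths = list(s_tp("depth")))
  pred <- build_prediction_grid(s$world)
  bp <- bootstrap_ci(fit, s$records, pred, B = 400, seed = 3,
                     method = "parametric")
  expect_lt(bp$ci[1], fit_total <- bp$total_unrounded * 1.0001)
  expect_gt(bp$ci[2], bp$total_unrounded * 0.999)
  expect_equal(bp$n_failed, 0L)
})

test_that("validation splits are disjoint, exhaustive and correctly sized", {
  n <- 1000
  with_seed(1, {
    tr <- sample.int(n, round(0.8 * n))
    te <- setdiff(seq_len(n), tr)
    expect_length(tr, 800L)
    expect_length(te, 200L)
    expect_length(intersect(tr, te), 0L)
    expect_setequal(c(tr, te), seq_len(n))
  })
  s <- quick_survey(seed = 8, intercept = -0.8)
  fit <- dsm_gam(s$records, smooths = list(s_tp("depth")))
  vr <- validate_split(fit, s$records, n_iter = 8, seed = 2)
  expect_equal(vr$n_iter, 8L)
  expect_true(all(is.finite(vr$rel_error)))
  expect_gte(vr$share_within_5, 0)
  expect_lte(vr$share_within_10, 1)
  expect_error(validate_split(fit, s$records[1:30, ], n_iter = 2), "50")
})
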