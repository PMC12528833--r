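test_that("effective range matches empirical central quantiles", {
  set.seed(12)
  u <- runif(1e6, -1, 1)
  r <- effective_deviation_range(u)
  expect_equal(r$lo, -0.98, tolerance = 0.005)
  expect_equal(r$hi, 0.98, tolerance = 0.005)
  z <- rnorm(1e6)
  rz <- effective_deviation_range(z)
  expect_equal(rz$lo, qnorm(0.01), tolerance = 0.01)
  expect_equal(rz$hi, qnorm(0.99), tolerance = 0.01)
  # degenerate and undersized inputs
  expect_warning(rd <- effective_deviation_range(rep(0.2, 200)), "degenerate")
  expect_equal(c(rd$lo, rd$hi), c(0.2, 0.2))
  expect_error(effective_deviation_range(rnorm(50)), "at least 100")
  # coverage is configurable
  r80 <- effective_deviation_range(u, coverage = 0.8)
  expect_equal(r80$lo, -0.8, tolerance = 0.01)
})

test_that("the slope threshold is the population SD of in-range mean KE", {
  lev <- seq(-0.4, 0.4, by = 0.05)
  flat <- fx_make_landscape(lev, rep(2, length(lev)))
  rng <- effective_range(-0.2, 0.2)
  expect_equal(kels_threshold(flat, rng), 0)
  # linear landscape over 5 in-range levels: closed-form population SD
  lin <- fx_make_landscape(lev, 3 + 0.7 * lev)
  rng5 <- effective_range(-0.101, 0.101)   # levels -0.1 .. 0.1
  vals <- 3 + 0.7 * seq(-0.1, 0.1, by = 0.05)
  expect_equal(kels_threshold(lin, rng5),
               sqrt(mean((vals - mean(vals))^2)))
  expect_error(kels_threshold(lin, effective_range(0.001, 0.04)),
               "fewer than 2")
})

test_that("the safe range recovers a constructed plateau exactly", {
  lev <- seq(-0.4, 0.4, by = 0.05)
  ke <- numeric(length(lev))
  plateau <- lev >= 0.05 - 1e-9 & lev <= 0.35 + 1e-9
  ke[plateau] <- 1                                   # dead flat on [0.05, 0.35]
  ke[!plateau] <- 1 + 10 * pmax(0.05 - lev[!plateau], lev[!plateau] - 0.35)
  ls <- fx_make_landscape(lev, ke)
  rng <- effective_range(-0.4, 0.4)
  kp <- kels_predict(ls, threshold = 1, range = rng)
  # central differences at the plateau's outermost levels feel the steep
  # limbs, so the qualifying run is the plateau interior [0.1, 0.3]
  expect_equal(kp$safe_range, c(0.1, 0.3))
  expect_equal(kp$kels_pred, 0.2)
  expect_false(kp$degenerate)
})

test_that("a symmetric parabolic landscape predicts zero deviation", {
  lev <- seq(-0.4, 0.4, by = 0.05)
  ls <- fx_make_landscape(lev, 5 * lev^2)
  rng <- effective_range(-0.4, 0.4)
  # threshold admitting the central five levels: |10 * lev| < thr
  kp <- kels_predict(ls, threshold = 1.3, range = rng)
  expect_equal(kp$kels_pred, 0)
  expect_equal(kp$safe_range, c(-0.1, 0.1))
})

test_that("equal-length safe-range ties follow the documented rules", {
  lev <- seq(-0.3, 0.3, by = 0.05)                   # 13 levels
  # two flat shelves of equal length; the right shelf has lower KE
  ke <- c(2, 2, 2, 5, 9, 5, 1, 1, 1, 5, 9, 5, 2)    # shelves at idx 1:3, 7:9
  ke <- rev(c(2, 2, 2, 5, 9, 5, 1, 1, 1, 5, 9, 5, 2))
  ls <- fx_make_landscape(lev, c(5, 2, 2, 2, 5, 9, 5, 1, 1, 1, 5, 9, 5))
  # runs below a generous threshold: idx 2:4 (KE 2) and idx 8:10 (KE 1)
  kp <- kels_predict(ls, threshold = 15, range = effective_range(-0.31, 0.31))
  expect_equal(kp$kels_pred, 0.1)                    # lower-KE run wins
  # even-length run: the median is the lower-middle grid level
  ke2 <- c(7, 5, 3, 1, 1, 1, 1, 1, 1, 3, 5, 7, 9)
  ls2 <- fx_make_landscape(lev, ke2)
  kp2 <- kels_predict(ls2, threshold = 25, range = effective_range(-0.31, 0.31))
  expect_equal(kp2$safe_range, c(-0.15, 0.1))        # 6 qualifying levels
  expect_equal(kp2$kels_pred, -0.05)                 # lower-middle of the run
})

test_that("enlarging the threshold never shrinks the safe range", {
  set.seed(13)
  lev <- seq(-0.4, 0.4, length.out = 33)
  for (i in 1:10) {
    ke <- abs(cumsum(rnorm(33)))
    ls <- fx_make_landscape(lev, ke)
    rng <- effective_range(-0.4, 0.4)
    widths <- vapply(c(0.5, 1, 2, 4, 8), function(thr) {
      kp <- tryCatch(kels_predict(ls, thr, rng), error = function(e) NULL)
      if (is.null(kp)) -1 else kp$safe_range[2] - kp$safe_range[1]
    }, numeric(1))
    expect_true(all(diff(widths) >= -1e-12))
  }
})

test_that("prediction fails loudly when no level is below threshold", {
  lev <- seq(-0.4, 0.4, by = 0.05)
  steep <- fx_make_landscape(lev, 10 + 10 * lev)
  rng <- effective_range(-0.4, 0.4)
  expect_error(kels_predict(steep, threshold = 1e-6, range = rng),
               "below the threshold")
  kp <- kels_predict(steep, threshold = 1e-6, range = rng, fallback = "flattest")
  expect_true(kp$degenerate)
  expect_equal(kp$safe_range[1], kp$safe_range[2])
})

test_that("minimum-KE prediction takes the argmin with documented tie-breaks", {
  lev <- seq(-0.4, 0.4, by = 0.05)
  ke <- 3 + (lev + 0.15)^2
  expect_equal(minke_predict(fx_make_landscape(lev, ke)), -0.15)
  # tie at exactly +/- 0.1: negative level wins
  ke2 <- (abs(lev) - 0.1)^2
  expect_equal(minke_predict(fx_make_landscape(lev, ke2)), -0.1)
  # joint-space landscapes (jitter off) predict 0 for every submovement
  expect_true(all(vapply(fx_joint_landscapes(), minke_predict, numeric(1)) == 0))
})

test_that("resampled RMSE comparison behaves on analytic cases", {
  obs <- seq(-0.3, 0.3, length.out = 19)
  set.seed(14)
  out <- compare_predictions(list(perfect = obs, shifted = obs + 0.05),
                             observed = obs)
  expect_equal(nrow(out), 2 * 5 * 20)
  expect_true(all(out$rmse[out$method == "perfect"] == 0))
  expect_equal(out$rmse[out$method == "shifted"], rep(0.05, 100))
  # identical partitions across methods within a repeat, reproducible by seed
  set.seed(15)
  a <- compare_predictions(list(x = obs + 0.1, y = obs - 0.1), obs)
  set.seed(15)
  b <- compare_predictions(list(x = obs + 0.1, y = obs - 0.1), obs)
  expect_identical(a, b)
  expect_error(compare_predictions(list(x = 1:3 / 10), observed = 1:3 / 10,
                                   n_folds = 5), "fewer submovements")
})

test_that("predicted-vs-observed change correlation on analytic cases", {
  early <- seq(-0.2, 0.2, length.out = 10)
  pred <- rep(0.1, 10)
  chg <- pred - early
  out <- predicted_vs_observed_change(early, pred, chg)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 1)
  out2 <- predicted_vs_observed_change(early, pred, -chg)
  expect_equal(out2$r, -1)
  expect_error(predicted_vs_observed_change(rep(0, 5), rep(0.1, 5), rnorm(5)),
               "degenerate variance")
})
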