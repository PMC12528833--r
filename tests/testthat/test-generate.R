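test_that("noiseless trials reproduce drawn deviations and onsets", {
  lay <- fx_layout()
  geom <- fx_geom()
  cfg <- generator_config(n_sessions = 1L, trial_sd = 1e-9, speed_noise_sd = 0,
                          hold_noise_sd = 0, duration_sd = 0, seed = 5L)
  dev <- c("C>T1" = 0, "T1>T2" = -0.3, "T2>T3" = 0.15)
  set.seed(5)
  tr <- generate_trial(lay, geom, c("T1", "T2", "T3"), cfg, mean_dev = dev)
  sl <- section_submovements(tr)
  truth <- attr(tr, "truth")
  expect_equal(truth$deviation, unname(dev), tolerance = 1e-6)
  m <- measure_trial(tr, geom)
  expect_equal(m$hand_dev, truth$deviation, tolerance = 1e-3)
  # straight submovement measured as straight and onset at the hold boundary
  expect_lt(abs(m$hand_dev[1]), 1e-3)
  expect_lt(abs(sl[[1]]$onset - 0.25), 5e-3)
  # streams are 1 kHz and events sit inside them
  expect_equal(unique(round(diff(tr$streams$t), 9)), 0.001)
  expect_true(all(tr$events >= 0 & tr$events <= max(tr$streams$t)))
})

test_that("trials are bit-identical under the same seed", {
  lay <- fx_layout()
  geom <- fx_geom()
  cfg <- generator_config(seed = 6L)
  g <- function() {
    set.seed(42)
    generate_trial(lay, geom, c("T2", "T4", "T6"), cfg,
                   mean_dev = c("C>T2" = 0.1))
  }
  expect_identical(g(), g())
})

test_that("studies respect the block design and drift law", {
  lay <- fx_layout()
  geom <- fx_geom()
  cfg <- generator_config(n_sessions = 2L, trials_per_session = 80L,
                          deviation_initial = 0.3, deviation_target = 0.1,
                          drift_rate = 0.5, seed = 11L)
  st <- generate_study(cfg, lay, geom)
  expect_length(st$trials, 160L)
  # 5 trials per sequence per 40-trial block
  seq_ids <- vapply(st$trials[1:40], `[[`, integer(1), "sequence_id")
  expect_equal(as.integer(table(seq_ids)), rep(5L, 8L))
  seq_ids2 <- vapply(st$trials[41:80], `[[`, integer(1), "sequence_id")
  expect_equal(as.integer(table(seq_ids2)), rep(5L, 8L))
  # exponential approach of the per-session mean toward the target
  ts <- st$truth_session
  expect_equal(unique(ts$mean_dev[ts$session_id == "S001"]), 0.3)
  expect_equal(unique(ts$mean_dev[ts$session_id == "S002"]), 0.2)
  # ground truth rows: one per submovement per session, KE recorded
  expect_equal(nrow(ts), 2L * 19L)
  expect_true(all(ts$mean_ke_J > 0))
  expect_equal(nrow(st$truth_trials), 3L * 160L)
  # reproducibility of the whole study
  st2 <- generate_study(cfg, lay, geom)
  expect_identical(st$truth_trials, st2$truth_trials)
})

test_that("every generated trial sections cleanly and measures close to truth", {
  lay <- fx_layout()
  geom <- fx_geom()
  cfg <- generator_config(n_sessions = 1L, trials_per_session = 40L,
                          deviation_initial = -0.1, deviation_target = -0.1,
                          seed = 12L)
  st <- generate_study(cfg, lay, geom, process = function(tr)
    measure_trial(tr, geom))
  expect_equal(nrow(st$records), 120L)
  expect_true(all(is.finite(st$records$hand_dev)))
  expect_true(all(st$records$ke_J > 0))
  # measured deviations track the drawn ones tightly despite noise
  expect_gt(cor(st$records$hand_dev, st$truth_trials$deviation), 0.995)
  expect_lt(mean(abs(st$records$hand_dev - st$truth_trials$deviation)), 5e-3)
})

test_that("per-session deviation estimates are unbiased across seeds", {
  lay <- fx_layout()
  geom <- fx_geom()
  true_mean <- 0.12
  errs <- vapply(1:8, function(s) {
    cfg <- generator_config(n_sessions = 1L, trials_per_session = 40L,
                            deviation_initial = true_mean,
                            deviation_target = true_mean, trial_sd = 0.05,
                            seed = 100L + s)
    st <- generate_study(cfg, lay, geom,
                         process = function(tr) measure_trial(tr, geom))
    mean(st$records$hand_dev) - true_mean
  }, numeric(1))
  # |bias| below 2 SE of the pooled estimate (0.05 / sqrt(120 * 8))
  expect_lt(abs(mean(errs)), 2 * 0.05 / sqrt(120 * 8))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(trials_per_session = 50L))
  expect_error(generator_config(duration_mean = 1.4, duration_sd = 0.1))
  expect_error(generator_config(drift_rate = 1.5))
  expect_error(generator_config(trial_sd = 0))
})
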