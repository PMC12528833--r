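# shared fixtures, computed lazily once per test run
.fx <- new.env(parent = emptyenv())

fx_geom <- function() arm_geometry()
fx_layout <- function() default_layout("E")

fx_cached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# deterministic joint-space landscapes, endpoint jitter off
fx_joint_landscapes <- function() fx_cached("joint_ls",
  build_landscapes(fx_layout(), fx_geom(), space = "joint", n_replicates = 0L))

# jittered hand-space landscapes under a fixed seed
fx_hand_landscapes <- function() fx_cached("hand_ls",
  kelscape:::with_seed(1001L,
    build_landscapes(fx_layout(), fx_geom(), space = "hand",
                     n_replicates = 100L)))

# the end-to-end drifting study and its full analysis (the heavy fixture):
# drift targets are the safe-range medians of the hand-space landscapes under
# a stipulated J-like effective range, initial means are offset from them
fx_endtoend <- function() fx_cached("endtoend", {
  geom <- fx_geom()
  lay <- fx_layout()
  seed <- 1L
  lss <- kelscape:::with_seed(seed + 1000L,
    build_landscapes(lay, geom, space = "hand", n_replicates = 100L))
  rng <- effective_range(-0.4, 0.4)
  targets <- vapply(names(lss), function(id)
    kels_predict(lss[[id]], kels_threshold(lss[[id]], rng), rng,
                 fallback = "flattest")$kels_pred, numeric(1L))
  init <- kelscape:::with_seed(seed + 500L,
                               targets + stats::runif(length(targets), -0.25, 0.25))
  init <- pmin(pmax(init, -0.45), 0.45)
  cfg <- generator_config(n_sessions = 20L, deviation_initial = init,
                          deviation_target = targets, drift_rate = 0.15,
                          seed = seed)
  list(targets = targets, init = init, cfg = cfg,
       report = run_full_analysis(cfg, lay, geom))
})

# a small constructed landscape from explicit values
fx_make_landscape <- function(levels, mean_ke, sd_ke = rep(0, length(levels)),
                              space = "hand", id = "fixture") {
  kelscape:::new_ke_landscape(levels, mean_ke, sd_ke, id, space, 0L)
}

# analytic bell-speed stream: zero hold then a raised-cosine speed bulge
# whose foot (first strictly positive acceleration) is exactly at t = foot_s
fx_bell_speed <- function(foot_s = 0.3, dur_s = 0.6, peak = 0.2,
                          dt = 0.001, tail_s = 0.2) {
  t <- seq(0, foot_s + dur_s + tail_s, by = dt)
  v <- numeric(length(t))
  inside <- t >= foot_s & t <= foot_s + dur_s
  v[inside] <- peak * 0.5 * (1 - cos(2 * pi * (t[inside] - foot_s) / dur_s))
  data.frame(t = t, speed = v)
}
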