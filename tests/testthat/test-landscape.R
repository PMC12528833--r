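test_that("deviation grid is validated", {
  g <- deviation_grid()
  expect_length(g, 33L)
  expect_equal(sum(g == 0), 1L)
  expect_equal(as.numeric(g), -rev(as.numeric(g)))
  expect_error(deviation_grid(-0.5, 0.5, n = 32), "exactly one 0")
  expect_error(deviation_grid(-0.3, 0.5, n = 33))
})

test_that("joint-space landscapes attain their minimum at zero deviation", {
  lss <- fx_joint_landscapes()
  expect_length(lss, 19L)
  for (ls in lss) {
    expect_equal(ls$deviation[which.min(ls$mean_ke)], 0)
    # KE grows monotonically with |deviation| on each side of 0
    i0 <- which(ls$deviation == 0)
    expect_true(all(diff(ls$mean_ke[i0:nrow(ls)]) > 0))
    expect_true(all(diff(ls$mean_ke[1:i0]) < 0))
    expect_true(all(ls$sd_ke == 0))
  }
})

test_that("joint-space landscapes are symmetric, hand-space ones need not be", {
  geom <- fx_geom()
  lay <- fx_layout()
  lj <- build_ke_landscape(target_position(lay, "C"), target_position(lay, "T2"),
                           space = "joint", geom = geom, n_replicates = 0L)
  expect_equal(lj$mean_ke, rev(lj$mean_ke), tolerance = 1e-10)
  lh <- build_ke_landscape(target_position(lay, "C"), target_position(lay, "T2"),
                           space = "hand", geom = geom, n_replicates = 0L)
  expect_gt(max(abs(lh$mean_ke - rev(lh$mean_ke))), 1e-3)
})

test_that("jittered landscapes are reproducible under a fixed seed", {
  geom <- fx_geom()
  lay <- fx_layout()
  b <- function() {
    set.seed(99)
    build_ke_landscape(target_position(lay, "C"), target_position(lay, "T1"),
                       space = "hand", geom = geom, n_replicates = 5L)
  }
  expect_identical(b(), b())
  ls <- b()
  expect_true(all(ls$sd_ke > 0))
  expect_identical(attr(ls, "n_replicates"), 5L)
})

test_that("unreachable deviation levels are reported by level", {
  geom <- fx_geom()
  # a chord near the rim of the workspace: extreme curvature leaves the annulus
  expect_error(
    build_ke_landscape(c(0, 0.345), c(0.05, 0.345), space = "hand",
                       geom = geom, grid = deviation_grid(-3, 3, 7),
                       n_replicates = 0L),
    "deviation level")
})

test_that("model-estimated KE of an observed shape matches direct computation", {
  geom <- fx_geom()
  pr <- make_time_profile()
  path <- simulate_path(c(0, 0.21), c(0, 0.25), 0, 501)
  a <- estimate_ke_for_observed_shape(as.data.frame(list(u = path[, 1], v = path[, 2])),
                                      geom, pr)
  # independent route: re-time the same shape, transform, differentiate, sum
  tr <- time_path(path, pr, space = "hand")
  jp <- inverse_kinematics(geom, tr$u, tr$v)
  b <- kinetic_energy(angular_velocities(
    trajectory(tr$t, jp[, 1], jp[, 2], space = "joint")), geom)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("estimated KE is invariant to the input shape's sampling density", {
  geom <- fx_geom()
  pr <- make_time_profile()
  p1 <- simulate_path(c(0.02, 0.22), c(-0.02, 0.26), 0.3, 501)
  p2 <- simulate_path(c(0.02, 0.22), c(-0.02, 0.26), 0.3, 1001)
  k1 <- estimate_ke_for_observed_shape(as.data.frame(list(u = p1[, 1], v = p1[, 2])), geom, pr)
  k2 <- estimate_ke_for_observed_shape(as.data.frame(list(u = p2[, 1], v = p2[, 2])), geom, pr)
  expect_equal(k1, k2, tolerance = 1e-3)
})

test_that("halving the total duration scales KE by four (sampled-sum convention)", {
  geom <- fx_geom()
  path <- simulate_path(c(0, 0.21), c(0.03, 0.25), 0.1, 501)
  shape <- as.data.frame(list(u = path[, 1], v = path[, 2]))
  k1 <- estimate_ke_for_observed_shape(shape, geom, make_time_profile())
  k2 <- estimate_ke_for_observed_shape(shape, geom,
                                       make_time_profile(total_duration = 0.5))
  expect_gt(k2, k1)
  expect_equal(k2 / k1, 4, tolerance = 1e-10)
})

test_that("landscape list flattens to the landscape table schema", {
  tab <- as_landscape_table(fx_joint_landscapes())
  expect_equal(nrow(tab), 19L * 33L)
  expect_setequal(unique(tab$submovement_id),
                  submovement_catalog(fx_layout())$submovement_id)
  expect_true(all(tab$space == "joint"))
})
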