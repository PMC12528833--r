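test_that("forward kinematics matches the exoskeleton convention", {
  geom <- fx_geom()
  # collinear: both segment direction angles 0, lengths add
  expect_equal(unname(forward_kinematics(geom, 0, 0)), cbind(0.36, 0))
  # both segment direction angles pi/2
  expect_equal(unname(forward_kinematics(geom, pi / 2, pi)), cbind(0, 0.36),
               tolerance = 1e-12)
  # shoulder offset translates the hand
  g2 <- arm_geometry(shoulder = c(0.1, -0.2))
  expect_equal(unname(forward_kinematics(g2, 0, 0)), cbind(0.46, -0.2))
})

test_that("hand distance from the shoulder stays within the reachable annulus", {
  geom <- fx_geom()
  set.seed(11)
  th_s <- runif(1000, -pi, pi)
  th_e <- runif(1000, -pi, pi)
  hp <- forward_kinematics(geom, th_s, th_e)
  r <- sqrt(hp[, 1]^2 + hp[, 2]^2)
  expect_true(all(r >= abs(geom$L1 - geom$L2) - 1e-12))
  expect_true(all(r <= geom$L1 + geom$L2 + 1e-12))
})

test_that("inverse kinematics inverts forward kinematics on the open branch", {
  geom <- fx_geom()
  expect_equal(unname(inverse_kinematics(geom, 0.36, 0)), cbind(0, 0))
  set.seed(21)
  th_s <- runif(1000, -pi, pi)
  gam <- runif(1000, 1e-2, pi - 1e-2)   # elbow-open branch interior
  th_e <- 2 * th_s + gam
  hp <- forward_kinematics(geom, th_s, th_e)
  back <- inverse_kinematics(geom, hp[, 1], hp[, 2])
  expect_lt(max(abs(back[, "theta_s"] - th_s)), 1e-9)
  expect_lt(max(abs(back[, "theta_e"] - th_e)), 1e-9)
  # and forward of the recovered angles reproduces the hand exactly
  hp2 <- forward_kinematics(geom, back[, 1], back[, 2])
  expect_lt(max(abs(hp2 - hp)), 1e-9)
})

test_that("inverse kinematics honours the branch switch", {
  open <- fx_geom()
  closed <- arm_geometry(ik_branch = "closed")
  p <- c(0.05, 0.22)
  a_open <- inverse_kinematics(open, p[1], p[2])
  a_closed <- inverse_kinematics(closed, p[1], p[2])
  g_open <- a_open[, "theta_e"] - 2 * a_open[, "theta_s"]
  g_closed <- a_closed[, "theta_e"] - 2 * a_closed[, "theta_s"]
  expect_gt(g_open, 0)
  expect_lt(g_closed, 0)
  expect_equal(unname(forward_kinematics(closed, a_closed[, 1], a_closed[, 2])),
               cbind(p[1], p[2]), tolerance = 1e-9)
})

test_that("unreachable targets are rejected", {
  geom <- fx_geom()
  expect_error(inverse_kinematics(geom, 1.0, 0), "unreachable")
  expect_error(inverse_kinematics(geom, 0.01, 0), "unreachable")  # inside annulus hole
  # boundary within tolerance is accepted
  expect_silent(inverse_kinematics(geom, geom$L1 + geom$L2, 0))
})

test_that("angular velocities are interval-centred finite differences", {
  # linear ramp in shoulder angle, constant elbow
  t <- seq(0, 1, by = 0.01)
  tr <- trajectory(t, 0.7 * t, rep(0.5, length(t)), space = "joint")
  av <- angular_velocities(tr)
  expect_equal(nrow(av), length(t) - 1)
  expect_equal(av$omega_s, rep(0.7, length(t) - 1))
  expect_equal(av$omega_e, rep(0, length(t) - 1))
  expect_equal(av$t, t[-length(t)] + diff(t) / 2)

  # quadratic angle: interval velocity matches the derivative at the midpoint
  tq <- trajectory(t, t^2, t * 0, space = "joint")
  avq <- angular_velocities(tq)
  expect_equal(avq$omega_s, 2 * avq$t, tolerance = 1e-10)

  # non-uniform sampling honoured
  tn <- c(0, 0.1, 0.4, 0.5)
  trn <- trajectory(tn, c(0, 1, 4, 5), rep(0, 4), space = "joint")
  expect_equal(angular_velocities(trn)$omega_s, c(10, 10, 10))

  expect_error(angular_velocities(data.frame(t = c(0, 0, 1), u = 1:3, v = 1:3)),
               "strictly increasing")
})

test_that("kinetic energy is the stated quadratic sum", {
  geom <- fx_geom()
  z <- data.frame(omega_s = rep(0, 50), omega_e = rep(0, 50))
  expect_equal(kinetic_energy(z, geom), 0)
  v1 <- data.frame(omega_s = rep(1, 100), omega_e = rep(0, 100))
  expect_equal(kinetic_energy(v1, geom), 100 * 0.5 * geom$Is)
  expect_equal(observed_ke(v1, geom), kinetic_energy(v1, geom))
  # quadratic form: doubling velocities quadruples KE
  set.seed(31)
  v <- data.frame(omega_s = rnorm(200), omega_e = rnorm(200))
  v2 <- data.frame(omega_s = 2 * v$omega_s, omega_e = 2 * v$omega_e)
  expect_equal(kinetic_energy(v2, geom), 4 * kinetic_energy(v, geom))
  # time reversal invariance and additivity over concatenation
  vr <- v[nrow(v):1, ]
  expect_equal(kinetic_energy(vr, geom), kinetic_energy(v, geom))
  expect_equal(kinetic_energy(rbind(v, v2), geom),
               kinetic_energy(v, geom) + kinetic_energy(v2, geom))
})

test_that("rigid-rod inertia is derived from masses and lengths", {
  g <- arm_geometry(L1 = 0.1, L2 = 0.2, m1 = 0.5, m2 = 0.25)
  expect_equal(g$Is, 0.5 * 0.1^2)
  expect_equal(g$Ie, 0.25 * 0.2^2)
  expect_error(arm_geometry(L1 = -1), "L1")
})
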