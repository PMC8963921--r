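test_that("numeric differentiation matches closed forms", {
  rate <- 100
  tt <- seq(0, 3, by = 1 / rate)

  k0 <- differentiate_kinematics(matrix(0.7, length(tt), 4), rate)
  expect_equal(k0$dtheta, matrix(0, length(tt), 4), ignore_attr = TRUE)
  expect_equal(k0$ddtheta, matrix(0, length(tt), 4), ignore_attr = TRUE)

  lin <- differentiate_kinematics(matrix(0.5 * tt, ncol = 1)[, c(1, 1, 1, 1)], rate)
  interior <- 3:(length(tt) - 2)
  expect_equal(lin$dtheta[interior, 1], rep(0.5, length(interior)), tolerance = 1e-10)
  expect_equal(max(abs(lin$ddtheta[interior, 1])), 0, tolerance = 1e-8)

  sine <- differentiate_kinematics(matrix(sin(2 * pi * tt), ncol = 1)[, c(1, 1, 1, 1)], rate)
  expect_equal(max(sine$ddtheta[interior, 1]), (2 * pi)^2, tolerance = 0.01)

  expect_error(differentiate_kinematics(matrix(0, 3, 4), rate),
               class = "sts_validation_error")
})

test_that("viscous resistance follows the joint-type branches", {
  body <- body_model(1.7, 65, d = c(2, 1, 1), d4_ext = 10, d4_flex = 20)
  th <- matrix(0, 1, 4); dth <- matrix(0, 1, 4)

  dth[1, 1] <- 0.5
  expect_equal(viscous_resistance(th, dth, body)[1, 1], 1.0, ignore_attr = TRUE)

  # lumbar dead zone: |theta_4| <= 0.0314 gives zero resistance
  th2 <- matrix(c(0, 0, 0, 0.02), 1)
  expect_equal(viscous_resistance(th2, matrix(0, 1, 4), body)[1, 4], 0,
               ignore_attr = TRUE)
  th3 <- matrix(c(0, 0, 0, 0.1), 1)
  expect_equal(viscous_resistance(th3, matrix(0, 1, 4), body)[1, 4], 1.0,
               ignore_attr = TRUE)
  th4 <- matrix(c(0, 0, 0, -0.1), 1)
  expect_equal(viscous_resistance(th4, matrix(0, 1, 4), body)[1, 4], -2.0,
               ignore_attr = TRUE)

  expect_equal(viscous_resistance(matrix(0, 1, 4), matrix(0, 1, 4), body),
               matrix(0, 1, 4), ignore_attr = TRUE)
})

test_that("inverse dynamics vanishes for a massless chain", {
  tiny <- list(mass = list(shank = 1e-12, thigh = 1e-12, pelvis = 1e-12, hat = 1e-12))
  body <- body_model(1.7, 65, fractions = tiny, d = c(0, 0, 0),
                     d4_ext = 0, d4_flex = 0)
  tt <- seq(0, 1, by = 0.01)
  kin <- kinematics(matrix(sin(tt), ncol = 1)[, c(1, 1, 1, 1)],
                    matrix(cos(tt), ncol = 1)[, c(1, 1, 1, 1)],
                    matrix(-sin(tt), ncol = 1)[, c(1, 1, 1, 1)], tt)
  expect_lt(max(abs(inverse_dynamics(kin, NULL, body))), 1e-8)
})

test_that("static postures reproduce the independent moment-balance oracle", {
  body <- body_model(1.7, 65, d = c(0, 0, 0), d4_ext = 0, d4_flex = 0)
  postures <- list(c(-0.10, 1.67, -1.57, 0),
                   c(0.2, -0.4, 0.3, -0.2),
                   c(0, 0, 0, 0.5))
  for (th in postures) {
    kin <- kinematics(matrix(th, 5, 4, byrow = TRUE), matrix(0, 5, 4),
                      matrix(0, 5, 4), seq(0, 0.04, by = 0.01))
    Tj <- inverse_dynamics(kin, NULL, body)
    expect_equal(as.numeric(Tj[3, ]), static_torque_oracle(th, body),
                 tolerance = 1e-8)
  }
})

test_that("ankle torque matches the closed-form compound pendulum when distal mass vanishes", {
  fr <- list(mass = list(shank = 0.093, thigh = 1e-12, pelvis = 1e-12, hat = 1e-12))
  body <- body_model(1.7, 65, fractions = fr, d = c(0, 0, 0),
                     d4_ext = 0, d4_flex = 0)
  tt <- seq(0, 2, by = 0.01)
  th1 <- 0.4 * sin(2 * pi * 0.7 * tt) + 0.2
  dth1 <- 0.4 * 2 * pi * 0.7 * cos(2 * pi * 0.7 * tt)
  ddth1 <- -0.4 * (2 * pi * 0.7)^2 * sin(2 * pi * 0.7 * tt)
  z <- numeric(length(tt))
  kin <- kinematics(cbind(th1, z, z, z), cbind(dth1, z, z, z),
                    cbind(ddth1, z, z, z), tt)
  Tj <- inverse_dynamics(kin, NULL, body)
  seg <- body$segments["shank", ]
  expected <- pendulum_torque_oracle(th1, ddth1, seg$mass, seg$com, seg$inertia)
  expect_equal(as.numeric(Tj[, 1]), expected, tolerance = 1e-6)
  expect_lt(max(abs(Tj[, 2:4])), 1e-6)
})

test_that("torques are affine in the applied external forces", {
  body <- body_model(1.7, 65)
  tt <- seq(0, 1, by = 0.01)
  n <- length(tt)
  kin <- kinematics(matrix(0.3 * sin(tt), ncol = 1)[, c(1, 1, 1, 1)],
                    matrix(0.3 * cos(tt), ncol = 1)[, c(1, 1, 1, 1)],
                    matrix(-0.3 * sin(tt), ncol = 1)[, c(1, 1, 1, 1)], tt)
  f1 <- external_forces(hip = cbind(10 * sin(tt), 200 + 50 * cos(tt)))
  f2 <- external_forces(hip = 2 * f1$hip)
  T0 <- inverse_dynamics(kin, NULL, body)
  T1 <- inverse_dynamics(kin, f1, body)
  T2 <- inverse_dynamics(kin, f2, body)
  expect_equal(T2 - T1, T1 - T0, tolerance = 1e-9)
})

test_that("joint power balances mechanical energy without resistance or external forces", {
  body <- body_model(1.7, 65, d = c(0, 0, 0), d4_ext = 0, d4_flex = 0)
  cfg <- stable_swing_config()
  kin <- gen_kinematics(cfg, rate = 1000)
  Tj <- inverse_dynamics(kin, NULL, body)
  power <- rowSums(Tj * kin$dtheta)
  E <- chain_energy(kin, body)
  n <- length(E)
  dEdt <- (E[3:n] - E[1:(n - 2)]) / (2 / 1000)
  interior <- 2:(n - 1)
  expect_equal(power[interior], dEdt, tolerance = 1e-4 * max(abs(power)))
})

test_that("re-integrating inverse-dynamics torques reproduces the trajectory", {
  # gravitationally stable smooth swing: the open-loop initial-value problem
  # is well conditioned there, so the residual measures implementation error
  body <- body_model(1.7, 65, d = c(3, 3, 3))
  kin <- gen_kinematics(stable_swing_config(), rate = 100)
  Tj <- inverse_dynamics(kin, NULL, body)
  th <- forward_simulate_chain(Tj, kin$time, NULL, body,
                               kin$theta[1, ], kin$dtheta[1, ])
  expect_lt(max(abs(th - kin$theta)), 1e-3)
})

test_that("inverse dynamics implied accelerations are exact on STS kinematics", {
  body <- body_model(1.7, 65)
  kin <- gen_kinematics(synth_config(), rate = 100)
  Tj <- inverse_dynamics(kin, NULL, body)
  coefs <- stsnorm:::chain_coefs(body)
  for (i in c(2, 100, 250)) {
    phi <- cumsum(kin$theta[i, ]); phid <- cumsum(kin$dtheta[i, ])
    tm <- stsnorm:::chain_terms(phi, phid, coefs)
    psi <- as.numeric(viscous_resistance(kin$theta[i, , drop = FALSE],
                                         kin$dtheta[i, , drop = FALSE], body))
    yv <- Tj[i, ] - psi
    q <- c(yv[1:3] - yv[2:4], yv[4])
    phidd <- solve(tm$A, q - tm$b - tm$G)
    expect_equal(phidd, cumsum(kin$ddtheta[i, ]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})
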