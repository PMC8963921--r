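test_that("simulated torques decompose into passive plus activation-linear parts", {
  toy <- toy_problem()
  ms <- toy$muscles
  # zero activation limit: pure passive torque
  tau0 <- simulate_torques(toy$envelopes, rep(0, 4), toy$kin, ms)
  tens <- muscle_tensions(matrix(0, nrow(toy$envelopes), 4,
                                 dimnames = list(NULL, names(ms))),
                          toy$kin$theta, toy$kin$dtheta, ms)
  expect_equal(tau0, torques_from_tensions(tens$passive, ms))

  # doubling one muscle's scale doubles exactly its active contribution
  a1 <- c(0.5, 0.5, 0.5, 0.5); a2 <- c(1.0, 0.5, 0.5, 0.5)
  d1 <- simulate_torques(toy$envelopes, a1, toy$kin, ms) - tau0
  d2 <- simulate_torques(toy$envelopes, a2, toy$kin, ms) - tau0
  expect_equal(d2[, "ankle"], 2 * d1[, "ankle"], tolerance = 1e-12)
  expect_equal(d2[, "knee"], d1[, "knee"], tolerance = 1e-12)

  expect_error(simulate_torques(toy$envelopes, rep(5, 4), toy$kin, ms),
               class = "sts_bound_error")
})

test_that("closed-loop: generator torques are reproduced exactly at the true scales", {
  tr <- gen_trial(synth_config(seed = 4, noise_sd = 0))
  # envelopes such that envelope * alpha = ground-truth activation
  env <- sweep(tr$truth$activations, 2, tr$truth$alpha, `/`)
  tau <- simulate_torques(env, tr$truth$alpha, tr$truth$kin, muscle_set())
  expect_equal(max(abs(tau - tr$truth$torques)), 0, tolerance = 1e-8)
})

test_that("extrema objective matches its definition", {
  n <- 50
  A <- cbind(sin(1:n / 5), cos(1:n / 5), (1:n) / n, -(1:n) / n)
  expect_equal(objective_Z(A, A), 0)

  B <- A; B[, 2] <- B[, 2] - (max(B[, 2]) - 0)  # shift so max differs
  B2 <- A
  B2[which.max(A[, 3]), 3] <- max(A[, 3]) + 1   # one joint's max off by 1
  expect_equal(objective_Z(A, B2), 1)

  C <- A + 1  # every max and min off by 1
  expect_equal(objective_Z(A, C), 8)
})

test_that("optimizer recovers identifiable toy scales against the grid oracle", {
  toy <- toy_problem()
  fit <- optimize_scales(toy$envelopes, toy$T_jnt, toy$kin, toy$muscles,
                         config = list(seed = 11))
  oracle <- toy_grid_oracle(toy)
  expect_equal(unname(fit$alpha), oracle, tolerance = 0.01)
  expect_equal(unname(fit$alpha), toy$alpha_star, tolerance = 0.01)
  # optimizer at least as good as the grid optimum (within grid resolution)
  z_oracle <- objective_Z(toy$T_jnt, toy$torque_fn(oracle))
  expect_lte(fit$Z, z_oracle + 1e-6)
})

test_that("optimum sits at identity when envelopes equal the target activations", {
  toy <- toy_problem(alpha_star = c(1, 1, 1, 1))
  fit <- optimize_scales(toy$envelopes, toy$T_jnt, toy$kin, toy$muscles,
                         config = list(seed = 2))
  expect_equal(unname(fit$alpha), rep(1, 4), tolerance = 0.01)
  expect_lt(fit$Z, 1e-8)
})

test_that("normalized activation keeps r = 1 and threshold-crossing times", {
  tr <- gen_trial(synth_config(seed = 6))
  env <- tr$truth$envelopes[seq(1, 301, by = 3), ]
  kin <- tr$truth$kin
  idx <- seq(1, 301, by = 3)
  kin_s <- kinematics(kin$theta[idx, ], kin$dtheta[idx, ], kin$ddtheta[idx, ],
                      kin$time[idx])
  Tt <- tr$truth$torques[idx, ]
  fit <- optimize_scales(env, Tt, kin_s, muscle_set(), config = list(seed = 3))
  for (nm in colnames(env)) {
    expect_equal(cor(fit$m_hat[, nm], env[, nm]), 1, tolerance = 1e-9)
    # on/off timing: crossings of any fraction of own peak coincide
    thr_m <- 0.25 * max(fit$m_hat[, nm])
    thr_e <- 0.25 * max(env[, nm])
    expect_identical(which(fit$m_hat[, nm] > thr_m), which(env[, nm] > thr_e))
  }
  expect_error(
    optimize_scales(matrix(0, 10, 2, dimnames = list(NULL, c("TA", "SOL"))),
                    Tt, kin_s, muscle_set(), config = list(seed = 1)),
    class = "sts_degenerate_error")
})

test_that("static optimization solves the single-muscle case algebraically", {
  ms <- toy_muscles()[1]
  class(ms) <- "muscle_set"
  n <- 9
  u <- seq(0, 1, length.out = n)
  theta <- matrix(0, n, 4)
  kin <- kinematics(theta, theta, theta, u)
  m_star <- 0.3 + 0.4 * sin(pi * u)
  # torque this activation produces: alpha path at l_hat = 1, v_hat = 0
  Tk <- cbind(0.05 * (1000 * m_star + 1000 / exp(5)), 0, 0, 0)
  colnames(Tk) <- joint_names()
  so <- static_optimization_baseline(Tk, kin, ms)
  expect_equal(as.numeric(so$activations), m_star, tolerance = 1e-4)
  expect_true(all(so$feasible))
})

test_that("static optimization splits load equally between identical muscles", {
  ms <- toy_muscles()[c(1, 1)]
  names(ms) <- c("A1", "A2"); ms$A2$name <- "A2"
  class(ms) <- "muscle_set"
  n <- 7
  kin <- kinematics(matrix(0, n, 4), matrix(0, n, 4), matrix(0, n, 4),
                    seq_len(n))
  Tk <- cbind(rep(40, n), 0, 0, 0)
  colnames(Tk) <- joint_names()
  so <- static_optimization_baseline(Tk, kin, ms)
  expect_equal(so$activations[, "A1"], so$activations[, "A2"], tolerance = 1e-4)

  # target equal to pure passive torque: zero activation suffices
  Tp <- cbind(rep(1000 / exp(5) * 0.05 * 2, n), 0, 0, 0)
  colnames(Tp) <- joint_names()
  so0 <- static_optimization_baseline(Tp, kin, ms)
  expect_lt(max(so0$activations), 1e-4)
})

test_that("fit metrics report correlation, peak error and torque relative error", {
  n <- 60
  ref <- cbind(a = abs(sin(1:n / 9)), b = abs(cos(1:n / 7)))
  m1 <- evaluate_fit(ref, ref, tau_sim = cbind(1:n, 1:n, 1:n, 1:n),
                     tau_ref = cbind(1:n, 1:n, 1:n, 1:n))
  expect_equal(unname(m1$pearson_r), c(1, 1))
  expect_equal(unname(m1$rmse_of_peaks), c(0, 0))
  expect_equal(unname(m1$percent_re), rep(0, 4))

  m2 <- evaluate_fit(0.5 * ref, ref)
  expect_equal(unname(m2$pearson_r), c(1, 1))
  expect_equal(unname(m2$rmse_of_peaks), unname(0.5 * apply(ref, 2, max)))

  tau_s <- cbind(rep(110, n), 1:n, 1:n, 1:n)
  tau_r <- cbind(rep(100, n), 1:n, 1:n, 1:n)
  m3 <- evaluate_fit(ref, ref, tau_s, tau_r)
  expect_equal(unname(m3$percent_re[1]), 10)

  expect_warning(mz <- evaluate_fit(cbind(rep(1, 5)), cbind(1:5)), "zero-variance")
  expect_true(is.na(mz$pearson_r[1]))
})
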