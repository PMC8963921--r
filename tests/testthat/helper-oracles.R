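# Independent oracles and small fixtures shared across tests.

# Independent static gravitational joint torques: explicit planar geometry,
# moments of distal-segment weights about each joint. Kept free of the
# package's Lagrangian machinery on purpose.
static_torque_oracle <- function(theta, body) {
  s <- body$segments
  phi <- cumsum(theta)
  # joint positions: joint 1 at origin, segment direction (-sin, cos)
  jx <- c(0, cumsum(-s$length[1:3] * sin(phi[1:3])))
  # segment COM x-positions
  cx <- jx + (-s$com * sin(phi))
  vapply(1:4, function(j) {
    sum(s$mass[j:4] * 9.81 * (cx[j:4] - jx[j]))
  }, 0)
}

# Closed-form torque of a single compound pendulum about the root joint
pendulum_torque_oracle <- function(theta1, ddtheta1, mass, com, inertia) {
  (inertia + mass * com^2) * ddtheta1 - mass * 9.81 * com * sin(theta1)
}

# Four independent single-joint muscles, one per joint (identifiable toy)
toy_muscles <- function(fmax = 1000) {
  arms <- list(A1 = c(0.05, 0, 0, 0), K1 = c(0, -0.05, 0, 0),
               H1 = c(0, 0, 0.05, 0), L1 = c(0, 0, 0, 0.05))
  ms <- lapply(names(arms), function(nm) {
    list(name = nm, fmax = fmax, l_opt = 0.1, v_max = 0.5,
         r = stats::setNames(arms[[nm]], joint_names()),
         l_ref = 0.1, theta_ref = stats::setNames(numeric(4), joint_names()))
  })
  structure(stats::setNames(ms, names(arms)), class = "muscle_set")
}

# Static toy problem: at the reference posture f_fl = f_fv = 1, so each
# joint's torque is alpha_k * r_k * fmax * e_k(t) plus a constant passive
# term fmax / e^5. Closed form, independent of the package's Hill code.
toy_problem <- function(alpha_star = c(1.2, 0.7, 1.5, 0.9), n = 101) {
  u <- seq(0, 1, length.out = n)
  env <- cbind(A1 = 0.5 * exp(-((u - 0.3) / 0.1)^2),
               K1 = 0.6 * exp(-((u - 0.5) / 0.12)^2),
               H1 = 0.4 * exp(-((u - 0.6) / 0.1)^2),
               L1 = 0.5 * exp(-((u - 0.4) / 0.15)^2))
  muscles <- toy_muscles()
  r_diag <- c(0.05, -0.05, 0.05, 0.05)
  passive <- 1000 / exp(5) * r_diag  # constant per joint at l_hat = 1
  torque <- function(alpha) {
    tau <- sapply(1:4, function(k) alpha[k] * r_diag[k] * 1000 * env[, k] + passive[k])
    colnames(tau) <- joint_names()
    tau
  }
  theta <- matrix(0, n, 4)
  kin <- kinematics(theta, theta, theta, u)
  list(envelopes = env, muscles = muscles, kin = kin,
       alpha_star = alpha_star, T_jnt = torque(alpha_star), torque_fn = torque)
}

# Brute-force per-muscle grid search for the toy problem (the joints are
# decoupled, so the objective separates muscle by muscle)
toy_grid_oracle <- function(toy, grid = exp(seq(log(0.01), log(10), length.out = 4000))) {
  vapply(1:4, function(k) {
    Tk <- toy$T_jnt[, k]
    best <- NA; best_z <- Inf
    r_fm <- c(0.05, -0.05, 0.05, 0.05)[k] * 1000
    pas <- 1000 / exp(5) * c(0.05, -0.05, 0.05, 0.05)[k]
    emax <- max(toy$envelopes[, k])
    for (a in grid) {
      if (a * emax > 1) next
      tau <- a * r_fm * toy$envelopes[, k] + pas
      z <- (max(Tk) - max(tau))^2 + (min(Tk) - min(tau))^2
      if (z < best_z) { best_z <- z; best <- a }
    }
    best
  }, 0)
}

# Smooth swing about the hanging equilibrium: a gravitationally stable
# configuration in which open-loop re-integration is well conditioned
stable_swing_config <- function() {
  synth_config(theta_sit = c(pi, 0.30, -0.20, 0.20),
               theta_stand = c(pi + 0.25, 0.05, 0.10, 0.35),
               lumbar_flex_amp = 0.05, padding = 0)
}
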