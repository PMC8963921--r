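#' Differentiate joint-angle series
#'
#' Builds the kinematics bundle (angles with first and second time
#' derivatives) required by inverse dynamics. Angles may optionally be
#' smoothed with a centered moving average before differencing; derivatives
#' use central differences on interior samples and one-sided differences at
#' the endpoints.
#'
#' @param theta Matrix or data.frame, one column per joint (rad), ordered
#'   ankle, knee, hip, lumbar.
#' @param rate Sampling rate, Hz.
#' @param smoothing_window Odd window length (samples) for the moving
#'   average; 1 disables smoothing.
#' @return A `kinematics` object: list with `theta`, `dtheta`, `ddtheta`
#'   (n x 4 matrices) and `time` (s).
#' @export
differentiate_kinematics <- function(theta, rate, smoothing_window = 1L) {
  theta <- as.matrix(theta)
  if (nrow(theta) < 5L) {
    sts_error("need at least 5 samples to differentiate", "sts_validation_error")
  }
  stopifnot_finite(theta, "joint angles")
  if (smoothing_window > 1L) {
    k <- as.integer(smoothing_window)
    if (k %% 2L == 0L) k <- k + 1L
    w <- rep(1 / k, k)
    theta <- apply(theta, 2, function(col) {
      pad <- (k - 1L) %/% 2L
      ext <- c(rep(col[1], pad), col, rep(col[length(col)], pad))
      as.numeric(stats::filter(ext, w, sides = 2))[(pad + 1L):(pad + length(col))]
    })
  }
  d1 <- apply(theta, 2, num_deriv, dt = 1 / rate)
  d2 <- apply(d1, 2, num_deriv, dt = 1 / rate)
  kinematics(theta, d1, d2, (seq_len(nrow(theta)) - 1L) / rate)
}

num_deriv <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Construct a kinematics bundle from known derivatives
#'
#' Used when derivatives are available in closed form (e.g. from the
#' synthetic generator's polynomial trajectories) instead of numeric
#' differentiation.
#'
#' @param theta,dtheta,ddtheta n x 4 matrices (rad, rad/s, rad/s^2).
#' @param time Time axis, s.
#' @return A `kinematics` object.
#' @export
kinematics <- function(theta, dtheta, ddtheta, time) {
  theta <- as.matrix(theta); dtheta <- as.matrix(dtheta); ddtheta <- as.matrix(ddtheta)
  if (!all(dim(theta) == dim(dtheta)) || !all(dim(theta) == dim(ddtheta)) ||
      nrow(theta) != length(time)) {
    sts_error("kinematics series have mismatched lengths", "sts_validation_error")
  }
  stopifnot_finite(cbind(theta, dtheta, ddtheta), "kinematics")
  colnames(theta) <- colnames(dtheta) <- colnames(ddtheta) <- joint_names()
  structure(list(theta = theta, dtheta = dtheta, ddtheta = ddtheta, time = time),
            class = "kinematics")
}

#' External reaction forces acting on the chain
#'
#' Holds the seat (hip plate) reaction applied to the pelvis and the summed
#' foot-plate reaction. With the ankle as the grounded root and the foot not
#' modeled, foot forces act at the ground link: their generalized torque on
#' the chain is identically zero (their Jacobian vanishes), so they are
#' carried as data (for balance checks and reporting) but do not enter the
#' joint-torque balance. The hip force acts at the seat-contact point on the
#' pelvis segment and must be zero from seat-off onward.
#'
#' @param hip n x 2 matrix `[fx, fy]` (N) of the seat reaction on the pelvis.
#' @param feet n x 2 matrix `[fx, fy]` (N), both feet summed.
#' @return An `external_forces` object.
#' @export
external_forces <- function(hip, feet = NULL) {
  hip <- as.matrix(hip)
  if (ncol(hip) != 2L) sts_error("hip force must be n x 2", "sts_validation_error")
  if (is.null(feet)) feet <- matrix(0, nrow(hip), 2) else feet <- as.matrix(feet)
  stopifnot_finite(hip, "hip force"); stopifnot_finite(feet, "foot force")
  structure(list(hip = hip, feet = feet), class = "external_forces")
}

# Chain geometry helpers ------------------------------------------------------
# Absolute segment angles phi_j = cumsum(theta)_j, measured CCW from vertical;
# segment direction d(phi) = (-sin phi, cos phi). r_ij = distance from joint j
# to the COM of segment i along the chain: L_j for j < i, com_i for j = i.

GRAV <- 9.81

chain_params <- function(body) {
  s <- body$segments
  list(L = s$length, m = s$mass, a = s$com, I = s$inertia)
}

# r matrix: r[i, j] as above (0 for j > i)
chain_r_matrix <- function(cp) {
  r <- matrix(0, 4, 4)
  for (i in 1:4) {
    if (i > 1) r[i, 1:(i - 1)] <- cp$L[1:(i - 1)]
    r[i, i] <- cp$a[i]
  }
  r
}

# P[j,k] = sum_i m_i r_ij r_ik ; w[j] = sum_i m_i r_ij  (posture-independent)
chain_coefs <- function(body) {
  cp <- chain_params(body)
  r <- chain_r_matrix(cp)
  P <- t(r) %*% (cp$m * r)
  w <- as.numeric(t(r) %*% cp$m)
  list(cp = cp, P = P, w = w)
}

# Per-sample generalized dynamics in absolute coordinates:
# A(phi) phidd + b(phi, phid) + G(phi) = Q
chain_terms <- function(phi, phid, coefs) {
  cs <- outer(phi, phi, function(a, b) cos(a - b))
  sn <- outer(phi, phi, function(a, b) sin(a - b))
  A <- coefs$P * cs + diag(coefs$cp$I)
  b <- as.numeric((coefs$P * sn) %*% (phid^2))
  G <- -GRAV * coefs$w * sin(phi)
  list(A = A, b = b, G = G)
}

# Generalized force of the seat reaction (applied on the pelvis segment at
# seat_offset from the hip joint): Q_j = f . rho_j d'(phi_j), j = 1..3.
seat_generalized_force <- function(phi, f, body) {
  rho <- c(body$segments$length[1:2], body$seat_offset, 0)
  dxp <- -cos(phi); dyp <- -sin(phi)
  rho * (f[1] * dxp + f[2] * dyp)
}

#' Joint viscous/elastic resistance
#'
#' Velocity-proportional resistance at ankle, knee and hip
#' (`psi_k = d_k * dtheta_k`), and angle-proportional resistance at the
#' lumbar joint with separate extension/flexion coefficients outside a
#' +/-0.0314 rad dead zone (`psi_4 = d4_ext * theta_4` for
#' `theta_4 > 0.0314`, `d4_flex * theta_4` for `theta_4 < -0.0314`, 0
#' inside the band). The dead band keeps the neutral lumbar posture
#' resistance-free; the piecewise map is not continuous at the band edges,
#' which is accepted as defined.
#'
#' @param theta,dtheta n x 4 matrices of joint angles (rad) and angular
#'   velocities (rad/s).
#' @param body A [body_model()] supplying `d`, `d4_ext`, `d4_flex`.
#' @return n x 4 matrix of resistance torques (N m).
#' @export
viscous_resistance <- function(theta, dtheta, body) {
  theta <- as.matrix(theta); dtheta <- as.matrix(dtheta)
  psi <- matrix(0, nrow(theta), 4, dimnames = list(NULL, joint_names()))
  for (k in 1:3) psi[, k] <- body$d[k] * dtheta[, k]
  th4 <- theta[, 4]
  psi[, 4] <- ifelse(th4 > 0.0314, body$d4_ext * th4,
                     ifelse(th4 < -0.0314, body$d4_flex * th4, 0))
  psi
}

#' Inverse dynamics of the four-link chain
#'
#' Computes joint torques at ankle, knee, hip and lumbar from kinematics and
#' external forces:
#' `T = I(theta) theta_dd + H(theta, theta_d) + g(theta) + Psi - Phi`,
#' assembled per sample from the planar chain Lagrangian in absolute segment
#' angles and mapped to joint coordinates. `Psi` is the joint resistance of
#' [viscous_resistance()]; `Phi` is the generalized torque of the external
#' (seat) reaction.
#'
#' @param kin A `kinematics` object ([differentiate_kinematics()] or
#'   [kinematics()]).
#' @param forces An [external_forces()] object with the same number of rows,
#'   or `NULL` for no external forces.
#' @param body A [body_model()].
#' @return n x 4 matrix of joint torques (N m), columns ankle, knee, hip,
#'   lumbar.
#' @export
inverse_dynamics <- function(kin, forces, body) {
  n <- nrow(kin$theta)
  if (!is.null(forces) && nrow(forces$hip) != n) {
    sts_error("kinematics and forces have different lengths", "sts_validation_error")
  }
  coefs <- chain_coefs(body)
  phi <- t(apply(kin$theta, 1, cumsum))
  phid <- t(apply(kin$dtheta, 1, cumsum))
  phidd <- t(apply(kin$ddtheta, 1, cumsum))
  psi <- viscous_resistance(kin$theta, kin$dtheta, body)
  Tj <- matrix(0, n, 4, dimnames = list(NULL, joint_names()))
  for (t in seq_len(n)) {
    tm <- chain_terms(phi[t, ], phid[t, ], coefs)
    q <- as.numeric(tm$A %*% phidd[t, ]) + tm$b + tm$G
    if (!is.null(forces)) {
      q <- q - seat_generalized_force(phi[t, ], forces$hip[t, ], body)
    }
    # map generalized forces from absolute to joint coordinates: reverse cumsum
    Tj[t, ] <- rev(cumsum(rev(q))) + psi[t, ]
  }
  if (!all(is.finite(Tj))) sts_error("non-finite joint torques", "sts_numerical_error")
  Tj
}

#' Forward integration of the chain under prescribed joint torques
#'
#' Integrates the same planar four-link chain forward in time under given
#' joint-torque and seat-force trajectories, from the trial's initial state.
#' Used as the dynamics-residual consistency check against
#' [inverse_dynamics()] (re-integrating inverse-dynamics torques must
#' reproduce the measured angles).
#'
#' @param torques n x 4 matrix of joint torques (N m) on `time`.
#' @param time Time axis, s.
#' @param forces [external_forces()] on the same axis, or `NULL`.
#' @param body A [body_model()].
#' @param theta0,dtheta0 Initial joint angles (rad) and velocities (rad/s).
#' @param method [deSolve::ode()] integrator (default `"lsoda"`).
#' @return n x 4 matrix of simulated joint angles on `time`.
#' @export
forward_simulate_chain <- function(torques, time, forces, body, theta0, dtheta0,
                                   method = "lsoda") {
  coefs <- chain_coefs(body)
  # natural cubic splines: the re-integration IVP amplifies interpolation
  # error exponentially, so torque interpolation must be high order
  tfun <- lapply(1:4, function(k) splinefun(time, torques[, k], method = "natural"))
  ffun <- if (is.null(forces)) NULL else
    lapply(1:2, function(k) splinefun(time, forces$hip[, k], method = "natural"))
  deriv <- function(t, y, parms) {
    phi <- y[1:4]; phid <- y[5:8]
    theta <- c(phi[1], diff(phi)); dtheta <- c(phid[1], diff(phid))
    Tj <- vapply(tfun, function(f) f(t), 0)
    psi <- as.numeric(viscous_resistance(matrix(theta, 1), matrix(dtheta, 1), body))
    # joint -> absolute generalized force: q = L^{-T} (T - psi): x_j = y_j - y_{j+1}
    yv <- Tj - psi
    q <- c(yv[1:3] - yv[2:4], yv[4])
    tm <- chain_terms(phi, phid, coefs)
    if (!is.null(ffun)) {
      q <- q + seat_generalized_force(phi, c(ffun[[1]](t), ffun[[2]](t)), body)
    }
    phidd <- solve(tm$A, q - tm$b - tm$G)
    list(c(phid, phidd))
  }
  y0 <- c(cumsum(theta0), cumsum(dtheta0))
  sol <- deSolve::ode(y0, time, deriv, parms = NULL, method = method,
                      rtol = 1e-11, atol = 1e-11)
  phi <- sol[, 2:5, drop = FALSE]
  theta <- cbind(phi[, 1], phi[, 2] - phi[, 1], phi[, 3] - phi[, 2], phi[, 4] - phi[, 3])
  colnames(theta) <- joint_names()
  theta
}

#' Mechanical energy of the chain
#'
#' Kinetic plus gravitational potential energy per sample; used in energy-
#' balance sanity checks (with zero resistance and no external force, total
#' joint power must equal the energy derivative).
#'
#' @param kin A `kinematics` object.
#' @param body A [body_model()].
#' @return Numeric vector of total mechanical energy (J).
#' @export
chain_energy <- function(kin, body) {
  coefs <- chain_coefs(body)
  cp <- coefs$cp
  r <- chain_r_matrix(cp)
  phi <- t(apply(kin$theta, 1, cumsum))
  phid <- t(apply(kin$dtheta, 1, cumsum))
  vapply(seq_len(nrow(phi)), function(t) {
    tm <- chain_terms(phi[t, ], phid[t, ], coefs)
    ke <- 0.5 * as.numeric(phid[t, ] %*% tm$A %*% phid[t, ])
    com_y <- as.numeric(r %*% cos(phi[t, ]))
    ke + GRAV * sum(cp$m * com_y)
  }, 0)
}
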