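#' Muscle length and velocity kinematics
#'
#' Maps joint kinematics to normalized muscle fiber length and contraction
#' velocity through the constant-moment-arm linearization
#' `l(t) = l_ref - sum_k r_k (theta_k(t) - theta_ref_k)`, `l_hat = l / l_opt`,
#' `v = -dl/dt`, `v_hat = v / v_max`. Positive `v_hat` means shortening
#' (concentric contraction). Normalized length is clamped above 0.1 with a
#' warning if the geometry would drive it lower.
#'
#' @param theta,dtheta n x 4 matrices of joint angles (rad) and velocities
#'   (rad/s).
#' @param muscle One element of a [muscle_set()].
#' @return List with `l_hat` and `v_hat` numeric series.
#' @export
#' @examples
#' ms <- muscle_set()
#' muscle_kinematics(matrix(0, 3, 4), matrix(0, 3, 4), ms$VAS)
muscle_kinematics <- function(theta, dtheta, muscle) {
  if (muscle$l_opt <= 0) sts_error("l_opt must be positive", "sts_validation_error")
  theta <- as.matrix(theta); dtheta <- as.matrix(dtheta)
  stopifnot_finite(muscle$r, "moment arms")
  dl <- as.numeric(sweep(theta, 2, muscle$theta_ref) %*% muscle$r)
  l <- muscle$l_ref - dl
  l_hat <- l / muscle$l_opt
  if (any(l_hat <= 0.1)) {
    warning(sprintf("muscle %s: normalized length clamped at 0.1", muscle$name))
    l_hat <- pmax(l_hat, 0.1)
  }
  v <- as.numeric(dtheta %*% muscle$r)  # -dl/dt; shortening positive
  list(l_hat = l_hat, v_hat = v / muscle$v_max)
}

#' Contractile-element force-length relation
#'
#' `f_fl = exp(-(l_hat - 1)^2)`: unimodal, maximal (1) at optimal fiber
#' length, symmetric about it.
#'
#' @param l_hat Normalized fiber length (unitless).
#' @return Scaling factor in (0, 1].
#' @export
force_length <- function(l_hat) {
  stopifnot_finite(l_hat, "l_hat")
  exp(-(l_hat - 1)^2)
}

#' Contractile-element force-velocity relation
#'
#' `f_fv = 1 + tanh(3 v_hat)`: 1 at isometric conditions, approaching 2 for
#' fast shortening (`v_hat > 0`) and 0 for fast lengthening.
#'
#' @param v_hat Normalized contraction velocity (positive = shortening).
#' @return Scaling factor in (0, 2).
#' @export
force_velocity <- function(v_hat) {
  stopifnot_finite(v_hat, "v_hat")
  1 + tanh(3 * v_hat)
}

#' Parallel-element passive force
#'
#' Passive elastic force recruited when the fiber stretches past its optimal
#' length: 0 below `l_hat = 1`, `fmax * exp(10 (l_hat - 1)) / exp(5)` for
#' `1 <= l_hat <= 1.5` (reaching exactly `fmax` at 1.5), and saturating at
#' `fmax` beyond.
#'
#' @param l_hat Normalized fiber length.
#' @param fmax Isometric maximum force, N.
#' @return Passive force in `[0, fmax]`, N.
#' @export
passive_force <- function(l_hat, fmax) {
  if (fmax <= 0) sts_error("fmax must be positive", "sts_validation_error")
  # exponential branch meets fmax exactly at l_hat = 1.5; the cap realizes
  # the saturation branch and keeps the map monotone at the boundary
  ifelse(l_hat < 1, 0, pmin(fmax * exp(10 * (l_hat - 1)) / exp(5), fmax))
}

#' Contractile-element active force
#'
#' `F_CE = fmax * f_fl * f_fv * m_hat` for normalized activation
#' `m_hat` in `[0, 1]`.
#'
#' @param muscle One element of a [muscle_set()] (supplies `fmax`).
#' @param f_fl,f_fv Force-length and force-velocity factors.
#' @param m_hat Normalized activation series in `[0, 1]`.
#' @return Active force, N.
#' @export
active_force <- function(muscle, f_fl, f_fv, m_hat) {
  if (any(m_hat < -1e-12 | m_hat > 1 + 1e-12)) {
    sts_error("activation must lie in [0, 1]", "sts_validation_error")
  }
  muscle$fmax * f_fl * f_fv * pmin(pmax(m_hat, 0), 1)
}

#' Muscle tensions from activations and kinematics
#'
#' Evaluates the Hill model for every muscle: active force
#' ([active_force()]) plus passive force ([passive_force()]), with
#' length/velocity factors from [muscle_kinematics()].
#'
#' @param activations n x n_muscle matrix of normalized activations
#'   (columns named by muscle).
#' @param theta,dtheta n x 4 joint kinematics matrices.
#' @param muscles A [muscle_set()].
#' @return List with `tension`, `active`, `passive`: n x n_muscle matrices (N).
#' @export
muscle_tensions <- function(activations, theta, dtheta, muscles) {
  activations <- as.matrix(activations)
  out_a <- out_p <- matrix(0, nrow(activations), length(muscles),
                           dimnames = list(NULL, names(muscles)))
  for (nm in names(muscles)) {
    mk <- muscle_kinematics(theta, dtheta, muscles[[nm]])
    ffl <- force_length(mk$l_hat)
    ffv <- force_velocity(mk$v_hat)
    out_a[, nm] <- active_force(muscles[[nm]], ffl, ffv, activations[, nm])
    out_p[, nm] <- passive_force(mk$l_hat, muscles[[nm]]$fmax)
  }
  list(tension = out_a + out_p, active = out_a, passive = out_p)
}

#' Joint torques from muscle tensions
#'
#' `tau_k(t) = sum_i r_ki F_i(t)`: tensions mapped through the signed
#' moment-arm matrix.
#'
#' @param tensions n x n_muscle matrix of tensions (N), columns named by
#'   muscle.
#' @param muscles A [muscle_set()] (order must match the columns).
#' @return n x 4 matrix of joint torques (N m).
#' @export
torques_from_tensions <- function(tensions, muscles) {
  tensions <- as.matrix(tensions)
  R <- moment_arm_matrix(muscles)
  if (ncol(tensions) != ncol(R)) {
    sts_error("tension columns do not match the muscle set", "sts_validation_error")
  }
  tau <- tensions %*% t(R)
  colnames(tau) <- joint_names()
  tau
}
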