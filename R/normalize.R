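#' Template activation profile for the iliopsoas
#'
#' The iliopsoas (IL) is modeled but has no surface-EMG channel. The
#' normalizer represents its activation as a fixed bell-shaped profile over
#' motion progress — active during the hip-flexion phase around seat-off —
#' whose amplitude is a free, bounded optimization variable. Excluded from
#' all accuracy metrics.
#'
#' @param n Number of samples in the trial window.
#' @param center Peak location as a fraction of the window (default 0.35).
#' @param width Gaussian width as a fraction of the window (default 0.10).
#' @return Numeric profile of length `n` with unit peak.
#' @export
il_template <- function(n, center = 0.35, width = 0.10) {
  u <- seq(0, 1, length.out = n)
  exp(-0.5 * ((u - center) / width)^2)
}

# Precompute the affine torque decomposition at fixed kinematics:
# tau_k(t) = sum_i alpha_i * r_ki * gain_i(t) * e_i(t) + passive_k(t),
# gain_i(t) = fmax_i * f_fl(t) * f_fv(t).
torque_gains <- function(envelopes, kin, muscles) {
  envelopes <- as.matrix(envelopes)
  n <- nrow(envelopes)
  gain <- passive <- matrix(0, n, length(muscles),
                            dimnames = list(NULL, names(muscles)))
  for (nm in names(muscles)) {
    mk <- muscle_kinematics(kin$theta, kin$dtheta, muscles[[nm]])
    gain[, nm] <- muscles[[nm]]$fmax * force_length(mk$l_hat) * force_velocity(mk$v_hat)
    passive[, nm] <- passive_force(mk$l_hat, muscles[[nm]]$fmax)
  }
  R <- moment_arm_matrix(muscles)
  list(active_coef = gain * envelopes,  # per unit alpha, n x n_muscle
       gain = gain,
       passive_torque = passive %*% t(R),  # n x 4
       R = R, envelopes = envelopes)
}

tau_from_alpha <- function(gains, alpha) {
  tau <- gains$active_coef %*% (t(gains$R) * alpha) + gains$passive_torque
  colnames(tau) <- joint_names()
  tau
}

#' Forward-simulate joint torques from scaled envelopes
#'
#' Applies the candidate scale factors to the envelopes
#' (`m_hat_i = alpha_i * e_i`), evaluates the Hill model and maps tensions to
#' joint torques. Scaled activations must stay within `[0, 1]`.
#'
#' @param envelopes n x n_muscle matrix of activation envelopes, one column
#'   per muscle in `muscles` (include an IL column, e.g. [il_template()],
#'   when using the full 11-muscle set).
#' @param alpha Positive scale factor per muscle.
#' @param kin A `kinematics` object on the same grid.
#' @param muscles A [muscle_set()].
#' @return n x 4 matrix of simulated joint torques (N m).
#' @export
simulate_torques <- function(envelopes, alpha, kin, muscles) {
  envelopes <- as.matrix(envelopes)
  if (any(alpha < 0)) sts_error("alpha must be non-negative", "sts_validation_error")
  m_hat <- sweep(envelopes, 2, alpha, `*`)
  if (any(m_hat > 1 + 1e-9)) {
    sts_error("scaled activation exceeds 1: bound violation", "sts_bound_error")
  }
  tens <- muscle_tensions(pmin(m_hat, 1), kin$theta, kin$dtheta, muscles)
  torques_from_tensions(tens$tension, muscles)
}

#' Torque-extrema matching objective
#'
#' `Z = ||Tmax - tau_max||^2 + ||Tmin - tau_min||^2`, where the extrema are
#' the per-joint maxima and minima over the trial window stacked into
#' 4-vectors and the norm is Euclidean.
#'
#' @param T_jnt,tau_sim n x 4 torque matrices on the same time base (N m).
#' @return Scalar objective value, (N m)^2.
#' @export
objective_Z <- function(T_jnt, tau_sim) {
  T_jnt <- as.matrix(T_jnt); tau_sim <- as.matrix(tau_sim)
  if (!all(dim(T_jnt) == dim(tau_sim))) {
    sts_error("torque series have mismatched shapes", "sts_validation_error")
  }
  dmax <- apply(T_jnt, 2, max) - apply(tau_sim, 2, max)
  dmin <- apply(T_jnt, 2, min) - apply(tau_sim, 2, min)
  sum(dmax^2) + sum(dmin^2)
}

#' Find per-muscle EMG scale factors by torque matching
#'
#' The core normalization: finds positive scale factors `alpha` such that
#' the forward-simulated joint-torque extrema match the inverse-dynamics
#' torques ([objective_Z()]), subject to `0 <= alpha_i e_i(t) <= 1`. Because
#' each normalized activation is a pure positive rescaling of its measured
#' envelope, it preserves a perfect positive correlation (Pearson r = 1) and
#' identical on/off timing with the measurement — the defining constraint of
#' the method. The (under-determined) problem is regularized by
#' `eps * ||alpha - 1||^2` with a tiny default `eps` for reproducibility.
#'
#' The solver is deterministic: a fixed lattice of feasible starting points
#' (global multiples of 1 plus seeded log-uniform draws) is refined by
#' box-constrained quasi-Newton descent in log-alpha, the best start is
#' polished by Nelder-Mead, and ties are broken by the smallest `||alpha||`.
#'
#' Muscles without an EMG channel (the IL column, auto-added when
#' `muscles` contains IL but `envelopes` does not) use the fixed
#' [il_template()] profile with a free amplitude.
#'
#' @param envelopes n x m matrix of measured envelopes (columns named by
#'   muscle; non-negative).
#' @param T_jnt n x 4 inverse-dynamics joint torques (N m).
#' @param kin A `kinematics` object on the same grid.
#' @param muscles A [muscle_set()].
#' @param config List of solver settings: `eps` (regularization, default
#'   1e-9), `alpha_min` (default 1e-3), `alpha_max` (default 100),
#'   `n_random_starts` (default 8), `seed` (default 1), `maxit`
#'   (default 400), `correlation` (`"scaling"`, the pure-rescaling
#'   constraint; an affine variant is not offered because it would break
#'   resting-baseline semantics).
#' @return A `normalization_result`: list with `alpha` (named scale
#'   factors), `m_hat` (n x n_muscle normalized activations), `tau_sim`,
#'   `Z` (objective without the regularization term), `converged`,
#'   `diagnostics` (per-start values, clipping flags).
#' @export
optimize_scales <- function(envelopes, T_jnt, kin, muscles, config = list()) {
  cfg <- modifyList(list(eps = 1e-9, alpha_min = 1e-3, alpha_max = 100,
                         n_random_starts = 8L, seed = 1L, maxit = 400L,
                         correlation = "scaling"), config)
  envelopes <- as.matrix(envelopes)
  if (any(envelopes < 0)) sts_error("envelopes must be non-negative", "sts_validation_error")
  if (all(envelopes == 0)) {
    sts_error("all envelopes are zero: degenerate input", "sts_degenerate_error")
  }
  stopifnot_finite(T_jnt, "inverse-dynamics torques")

  measured <- colnames(envelopes)
  if ("IL" %in% names(muscles) && !"IL" %in% measured) {
    envelopes <- cbind(envelopes, IL = il_template(nrow(envelopes)))
  }
  envelopes <- envelopes[, names(muscles), drop = FALSE]

  peaks <- apply(envelopes, 2, max)
  ub <- ifelse(peaks > 0, pmin(cfg$alpha_max, 1 / peaks), cfg$alpha_max)
  lb <- rep(cfg$alpha_min, length(ub))
  infeasible <- ub <= lb
  if (any(infeasible)) {
    warning("upper activation bound below alpha_min for: ",
            paste(names(ub)[infeasible], collapse = ", "))
    ub[infeasible] <- lb[infeasible] * 1.0001
  }

  gains <- torque_gains(envelopes, kin, muscles)
  obj_log <- function(x) {
    a <- exp(x)
    objective_Z(T_jnt, tau_from_alpha(gains, a)) + cfg$eps * sum((a - 1)^2)
  }

  # deterministic start lattice
  clip <- function(a) pmin(pmax(a, lb), ub)
  starts <- lapply(c(0.25, 0.5, 1, 2), function(s) clip(rep(s, length(ub))))
  if (cfg$n_random_starts > 0) {
    rs <- local_runif((cfg$n_random_starts) * length(ub), seed = cfg$seed)
    rmat <- matrix(rs, ncol = length(ub))
    for (i in seq_len(nrow(rmat))) {
      starts[[length(starts) + 1L]] <-
        clip(exp(log(lb) + rmat[i, ] * (log(ub) - log(lb))))
    }
  }

  fits <- lapply(starts, function(a0) {
    optim(log(a0), obj_log, method = "L-BFGS-B",
          lower = log(lb), upper = log(ub),
          control = list(maxit = cfg$maxit, factr = 1e4))
  })
  vals <- vapply(fits, `[[`, 0, "value")
  norms <- vapply(fits, function(f) sum(exp(f$par)^2), 0)
  best <- order(vals, norms)[1]
  # Nelder-Mead polish (projected back into bounds)
  polish <- optim(fits[[best]]$par,
                  function(x) obj_log(pmin(pmax(x, log(lb)), log(ub))),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
  par <- pmin(pmax(polish$par, log(lb)), log(ub))
  alpha <- setNames(exp(par), names(muscles))

  m_hat <- sweep(envelopes, 2, alpha, `*`)
  clipped <- m_hat > 1
  if (any(clipped)) {
    warning(sprintf("%d activation samples clipped at 1", sum(clipped)))
    m_hat <- pmin(m_hat, 1)
  }
  tau_sim <- tau_from_alpha(gains, alpha)
  structure(
    list(alpha = alpha, m_hat = m_hat, tau_sim = tau_sim,
         Z = objective_Z(T_jnt, tau_sim),
         converged = polish$convergence == 0 || fits[[best]]$convergence == 0,
         diagnostics = list(start_values = vals, chosen_start = best,
                            clipped_samples = sum(clipped),
                            alpha_upper = ub, measured = measured)),
    class = "normalization_result"
  )
}

# seeded uniform draws without touching the global RNG stream
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n)
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("Torque-matched EMG normalization\n")
  cat("alpha:\n"); print(round(x$alpha, 4))
  cat(sprintf("Z = %.6g (N m)^2, converged: %s\n", x$Z, x$converged))
  invisible(x)
}

#' Static-optimization baseline
#'
#' The conventional per-time-step muscle force distribution: at every sample
#' minimize the sum of squared activations subject to the four joint-torque
#' equalities `sum_i r_ki (F_CE_i(m_i) + F_PE_i) = T_k` and `0 <= m <= 1`.
#' Since active force is linear in activation at fixed kinematics, each step
#' is a box-constrained quadratic program (solved with [kernlab::ipop()]).
#' Steps where the equalities cannot be met within bounds fall back to a
#' bounded least-squares solution and are flagged.
#'
#' @param T_jnt n x 4 joint-torque targets (N m).
#' @param kin A `kinematics` object on the same grid.
#' @param muscles A [muscle_set()].
#' @param tol Torque-residual tolerance (N m) above which a step is flagged
#'   infeasible.
#' @return An `so_result`: list with `activations` (n x n_muscle),
#'   `residuals` (n x 4 torque residuals, N m), `feasible` (logical per
#'   step).
#' @export
static_optimization_baseline <- function(T_jnt, kin, muscles, tol = 1e-3) {
  T_jnt <- as.matrix(T_jnt)
  stopifnot_finite(T_jnt, "torque targets")
  n <- nrow(T_jnt)
  nm <- length(muscles)
  gains <- torque_gains(matrix(1, n, nm, dimnames = list(NULL, names(muscles))),
                        kin, muscles)
  act <- matrix(0, n, nm, dimnames = list(NULL, names(muscles)))
  res <- matrix(0, n, 4, dimnames = list(NULL, joint_names()))
  feas <- logical(n)
  lsq <- function(A, b) {  # bounded least-squares fallback
    fit <- optim(rep(0.5, nm), function(m) sum((A %*% m - b)^2),
                 method = "L-BFGS-B", lower = rep(0, nm), upper = rep(1, nm),
                 control = list(maxit = 500))
    fit$par
  }
  for (t in seq_len(n)) {
    A <- gains$R * rep(gains$gain[t, ], each = 4)       # 4 x nm
    b <- T_jnt[t, ] - as.numeric(gains$passive_torque[t, ])
    m <- tryCatch({
      sol <- kernlab::ipop(c = rep(0, nm), H = 2 * diag(nm),
                           A = A, b = b, l = rep(0, nm), u = rep(1, nm),
                           r = rep(0, 4), sigf = 9, maxiter = 100)
      pmin(pmax(kernlab::primal(sol), 0), 1)
    }, error = function(e) NULL)
    if (is.null(m) || max(abs(A %*% m - b)) > tol) {
      m2 <- lsq(A, b)
      if (is.null(m) || sum((A %*% m2 - b)^2) < sum((A %*% m - b)^2)) m <- m2
    }
    act[t, ] <- m
    res[t, ] <- as.numeric(A %*% m - b)
    feas[t] <- max(abs(res[t, ])) <= tol
  }
  structure(list(activations = act, residuals = res, feasible = feas),
            class = "so_result")
}

#' Simulation accuracy metrics
#'
#' Compares simulated and reference activation profiles per muscle
#' (Pearson r over motion progress; peak-amplitude error, i.e. the
#' within-muscle error between the peak values) and, when torque series are
#' supplied, the percentage relative error between simulated and reference
#' joint-torque maxima.
#'
#' @param simulated,reference n x m activation matrices on the same grid.
#' @param tau_sim,tau_ref Optional n x 4 torque matrices for the joint %RE.
#' @param peak_mode `"peaks"` (default; absolute error between the two peak
#'   amplitudes) or `"pointwise"` (root-mean-square error across the whole
#'   profile).
#' @return List with `pearson_r` and `rmse_of_peaks` (named per muscle) and,
#'   if torques were given, `percent_re` (named per joint, %).
#' @export
evaluate_fit <- function(simulated, reference, tau_sim = NULL, tau_ref = NULL,
                         peak_mode = c("peaks", "pointwise")) {
  peak_mode <- match.arg(peak_mode)
  simulated <- as.matrix(simulated); reference <- as.matrix(reference)
  if (!all(dim(simulated) == dim(reference))) {
    sts_error("activation matrices have mismatched shapes", "sts_validation_error")
  }
  r <- vapply(seq_len(ncol(simulated)), function(i) {
    if (sd(simulated[, i]) == 0 || sd(reference[, i]) == 0) {
      warning("zero-variance series: correlation undefined")
      return(NA_real_)
    }
    cor(simulated[, i], reference[, i])
  }, 0)
  rmse <- vapply(seq_len(ncol(simulated)), function(i) {
    if (peak_mode == "peaks") abs(max(simulated[, i]) - max(reference[, i]))
    else sqrt(mean((simulated[, i] - reference[, i])^2))
  }, 0)
  names(r) <- names(rmse) <- colnames(simulated)
  out <- list(pearson_r = r, rmse_of_peaks = rmse)
  if (!is.null(tau_sim) && !is.null(tau_ref)) {
    tmax_s <- apply(as.matrix(tau_sim), 2, max)
    tmax_r <- apply(as.matrix(tau_ref), 2, max)
    out$percent_re <- setNames(100 * abs(tmax_s - tmax_r) / abs(tmax_r), joint_names())
  }
  out
}
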