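#' Configuration for the synthetic sit-to-stand generator
#'
#' Bundles everything the generator needs to produce self-consistent
#' synthetic trials with known ground truth: anthropometry, sit/stand
#' postures, four synergy templates (spatial weights and Gaussian temporal
#' bumps), per-muscle true scale factors, EMG noise level and rates.
#'
#' Defaults describe a realistic unassisted sit-to-stand: a 3 s trial with
#' seat-off at 1 s, an adult subject (1.70 m, 65 kg), knee extending from
#' about 96 degrees of flexion, hip from 90 degrees, a lumbar flexion
#' excursion of 0.35 rad peaking mid-rise, four synergy bumps at 15/40/65/85%
#' of motion progress (lumbar flexion, hip raise, body extension, posture
#' control) and 5% multiplicative EMG noise.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param height,mass Subject anthropometry (m, kg).
#' @param duration Trial (motion) length, s; the analysis window.
#' @param padding Extra recorded tail (s) after the motion ends, so the
#'   3 s window around the detected seat-off always fits inside the
#'   recording; postures and forces hold their final values through it.
#' @param seat_off Seat-off time, s.
#' @param theta_sit,theta_stand Joint postures (rad), ankle/knee/hip/lumbar.
#' @param lumbar_flex_amp Peak lumbar flexion excursion (rad) of the
#'   flexion-then-extension bump superimposed on the lumbar trajectory.
#' @param synergy_W 10 x 4 spatial template matrix (defaults to
#'   [synergy_reference_templates()]).
#' @param synergy_centers,synergy_widths,synergy_levels Temporal bump
#'   centers and widths (% progress) and amplitudes per synergy.
#' @param alpha_true Named positive true scale factors; envelopes are
#'   `m_hat / alpha_true` (IL's entry is its template amplitude).
#' @param noise_sd Multiplicative EMG noise standard deviation.
#' @param emg_rate,angle_rate,force_rate Stream sample rates, Hz.
#' @param carrier_freq Carrier frequency (Hz) used to synthesize raw EMG
#'   inside the 40-400 Hz pass band.
#' @param hip_load_frac Fraction of body weight on the seat before rising.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, height = 1.70, mass = 65,
                         duration = 3, padding = 0.1, seat_off = 1,
                         theta_sit = c(-0.10, 1.67, -1.57, 0),
                         theta_stand = c(0, 0, 0, 0),
                         lumbar_flex_amp = 0.35,
                         synergy_W = NULL,
                         synergy_centers = c(15, 40, 65, 85),
                         synergy_widths = c(9, 9, 10, 12),
                         synergy_levels = c(0.80, 0.85, 0.80, 0.60),
                         alpha_true = NULL,
                         noise_sd = 0.05,
                         emg_rate = 2000, angle_rate = 100, force_rate = 2000,
                         carrier_freq = 120,
                         hip_load_frac = 0.6) {
  if (duration <= 0) sts_error("duration must be positive", "sts_validation_error")
  if (noise_sd < 0) sts_error("noise sd must be non-negative", "sts_validation_error")
  if (hip_load_frac >= 1 || hip_load_frac <= 0) {
    sts_error("hip load fraction must be in (0, 1): feet would be unloaded",
              "sts_config_error")
  }
  if (is.null(synergy_W)) synergy_W <- synergy_reference_templates()
  if (is.null(alpha_true)) {
    alpha_true <- c(TA = 2.0, SOL = 1.6, GAS = 2.4, RF = 1.8, VAS = 1.5,
                    BFL = 2.2, BFS = 2.6, GMAX = 1.4, RA = 2.0, ES = 1.7,
                    IL = 0.30)
  }
  if (any(alpha_true <= 0)) sts_error("alpha_true must be positive", "sts_validation_error")
  structure(as.list(environment()), class = "synth_config")
}

# Minimum-jerk quintic and derivatives on u in [0, 1]
mj_s <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3
mj_s1 <- function(u) 30 * u^4 - 60 * u^3 + 30 * u^2
mj_s2 <- function(u) 120 * u^3 - 180 * u^2 + 60 * u

#' Generate minimum-jerk sit-to-stand joint trajectories
#'
#' Each joint follows a minimum-jerk quintic from its sit posture to its
#' stand posture over the trial (zero velocity and acceleration at both
#' ends). The lumbar joint additionally carries a flexion-then-extension
#' bump (`-amp * 4 s (1 - s)`), so the trunk flexes forward before
#' extending — the hallmark lumbar sequence of sit-to-stand. All
#' derivatives are evaluated from the closed-form polynomials, not by
#' finite differences.
#'
#' @param config A [synth_config()].
#' @param rate Sampling rate, Hz (default the config's kinematics rate).
#' @return A `kinematics` object covering the trial.
#' @export
gen_kinematics <- function(config, rate = config$angle_rate) {
  D <- config$duration
  tt <- seq(0, D + config$padding, by = 1 / rate)
  u <- pmin(tt / D, 1)  # hold the stand posture through the padding
  s <- mj_s(u); s1 <- mj_s1(u) / D; s2 <- mj_s2(u) / D^2
  th <- dth <- ddth <- matrix(0, length(tt), 4)
  for (k in 1:4) {
    dlt <- config$theta_stand[k] - config$theta_sit[k]
    th[, k] <- config$theta_sit[k] + dlt * s
    dth[, k] <- dlt * s1
    ddth[, k] <- dlt * s2
  }
  # lumbar flexion bump: b = 4 s (1 - s), db/dt = 4 s'(1 - 2 s), ...
  A <- config$lumbar_flex_amp
  b <- 4 * s * (1 - s)
  b1 <- 4 * s1 * (1 - 2 * s)
  b2 <- 4 * s2 * (1 - 2 * s) - 8 * s1^2
  th[, 4] <- th[, 4] - A * b
  dth[, 4] <- dth[, 4] - A * b1
  ddth[, 4] <- ddth[, 4] - A * b2
  kinematics(th, dth, ddth, tt)
}

#' Generate ground-truth synergy activations
#'
#' Temporal patterns are Gaussian bumps at the configured centers; the
#' activation matrix is `M = W C` clipped to `[0, 1]` (default templates do
#' not clip).
#'
#' @param config A [synth_config()].
#' @param n Number of time samples across the trial.
#' @param progress Optional explicit motion-progress vector (0-100%)
#'   overriding the uniform grid of length `n`.
#' @return List with `M` (muscles x n activation matrix), `W` (10 x 4),
#'   `C` (4 x n) and `progress` (0-100%).
#' @export
gen_activations <- function(config, n = 101L, progress = NULL) {
  if (any(config$synergy_W < 0)) {
    sts_error("spatial templates must be non-negative", "sts_validation_error")
  }
  p <- if (is.null(progress)) seq(0, 100, length.out = n) else progress
  n <- length(p)
  C <- t(vapply(1:4, function(j) {
    config$synergy_levels[j] *
      exp(-0.5 * ((p - config$synergy_centers[j]) / config$synergy_widths[j])^2)
  }, numeric(n)))
  M <- pmin(pmax(config$synergy_W %*% C, 0), 1)
  list(M = M, W = config$synergy_W, C = C, progress = p)
}

#' Generate one noisy synthetic activation matrix
#'
#' The ground-truth activation matrix with i.i.d. multiplicative noise
#' (`M * (1 + eta)`, `eta ~ N(0, noise_sd)`), clipped at zero. Used for
#' synergy-extraction studies where the full recording pipeline is not
#' needed.
#'
#' @param config A [synth_config()].
#' @param seed Seed for the noise draw.
#' @param n Time samples.
#' @return Muscles x n non-negative matrix.
#' @export
gen_activation_matrix <- function(config, seed = config$seed, n = 101L) {
  act <- gen_activations(config, n)
  eta <- local_rnorm(length(act$M), seed = seed, sd = config$noise_sd)
  pmax(act$M * (1 + matrix(eta, nrow(act$M))), 0)
}

local_rnorm <- function(n, seed, sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rnorm(n, sd = sd)
}

#' Generate a complete synthetic sit-to-stand trial
#'
#' Produces raw-format streams (EMG, joint angles, reaction forces) plus the
#' full ground truth. Construction:
#'
#' * kinematics from [gen_kinematics()];
#' * ground-truth activations `m_hat*` from the synergy templates (plus a
#'   scaled [il_template()] for IL);
#' * ground-truth torques as the Hill-model torques at `m_hat*` on the
#'   generated kinematics (the quantity the torque-matching optimizer can
#'   reproduce exactly at `alpha = alpha_true`);
#' * hip vertical force as a smooth quintic unloading of `hip_load_frac`
#'   of body weight, crossing the 10 N seat-off threshold exactly at the
#'   configured seat-off time; feet carry the quasi-static remainder of
#'   body weight (reaction forces are consistent with static vertical
#'   balance, not full dynamics);
#' * raw EMG as the true envelope (`m_hat*/alpha_true`, with multiplicative
#'   noise) amplitude-modulating a rectification-compensated carrier inside
#'   the 40-400 Hz band, so preprocessing recovers the envelope.
#'
#' @param config A [synth_config()].
#' @param seed Seed for the noise draws (default the config seed).
#' @return A `synth_trial`: list with `recording` (the raw-stream list that
#'   [preprocess_trial()] consumes), `truth` (list: `kin`, `activations`
#'   (n x 11 on the kinematics grid), `envelopes` (n x 10 noise-free),
#'   `alpha`, `W`, `C`, `torques` (n x 4 N m), `seat_off_time`) and
#'   `config`.
#' @export
gen_trial <- function(config = synth_config(), seed = config$seed) {
  muscles <- muscle_set()
  kin <- gen_kinematics(config)
  n <- nrow(kin$theta)

  act <- gen_activations(config, progress = 100 * pmin(kin$time / config$duration, 1))
  m_true <- t(act$M)                       # n x 10
  colnames(m_true) <- rownames(act$M)
  m_true <- m_true[, measured_muscle_names(), drop = FALSE]
  m_all <- cbind(m_true, IL = config$alpha_true[["IL"]] * il_template(n))

  alpha <- config$alpha_true[colnames(m_all)]
  torques_true <- simulate_torques(sweep(m_all, 2, alpha, `/`), alpha, kin, muscles)

  env_true <- sweep(m_true, 2, alpha[colnames(m_true)], `/`)

  # raw EMG: envelope-modulated carrier; pi/2 compensates rectified-mean loss
  t_emg <- seq(0, config$duration + config$padding, by = 1 / config$emg_rate)
  carrier <- (pi / 2) * sin(2 * pi * config$carrier_freq * t_emg)
  noise <- matrix(local_rnorm(length(t_emg) * ncol(env_true), seed = seed,
                              sd = config$noise_sd),
                  length(t_emg))
  src_t <- kin$time
  emg <- as.data.frame(lapply(seq_len(ncol(env_true)), function(i) {
    env_i <- approx(src_t, env_true[, i], xout = t_emg, rule = 2)$y
    env_i * (1 + noise[, i]) * carrier
  }))
  names(emg) <- colnames(env_true)

  # seat unloading: quintic from hip_load_frac * weight, hitting 10 N at seat-off
  W0 <- config$hip_load_frac * config$mass * GRAV
  if (W0 <= 10) sts_error("seat load below seat-off threshold", "sts_config_error")
  t_a <- 0.5 * config$seat_off
  u_star <- uniroot(function(u) mj_s(u) - (1 - 10 / W0), c(1e-9, 1 - 1e-9),
                    tol = 1e-12)$root
  t_b <- t_a + (config$seat_off - t_a) / u_star
  t_f <- seq(0, config$duration + config$padding, by = 1 / config$force_rate)
  uu <- pmin(pmax((t_f - t_a) / (t_b - t_a), 0), 1)
  hip_v <- W0 * (1 - mj_s(uu))
  feet_v <- config$mass * GRAV - hip_v
  forces <- data.frame(hip_v = hip_v, foot_l_v = feet_v / 2, foot_r_v = feet_v / 2)

  structure(
    list(
      recording = list(
        emg = emg, emg_rate = config$emg_rate,
        angles = as.data.frame(kin$theta), angle_rate = config$angle_rate,
        forces = forces, force_rate = config$force_rate,
        subject_id = "synthetic", session_day = 1L
      ),
      truth = list(
        kin = kin, activations = m_all, envelopes = env_true,
        alpha = alpha, W = act$W, C = act$C,
        torques = torques_true, seat_off_time = config$seat_off
      ),
      config = config
    ),
    class = "synth_trial"
  )
}

#' Generate a longitudinal series of synthetic trial sets
#'
#' Emulates serial sit-to-stand measurements across rehabilitation days:
#' per-day growth factors scale each synergy's temporal amplitude
#' (geometrically interpolated from 1 on the first day to `growth` on the
#' last), with per-trial lognormal amplitude jitter and the configured EMG
#' noise.
#'
#' @param config A [synth_config()].
#' @param days Number of measurement days (>= 2).
#' @param trials_per_day Trials per day (>= 5).
#' @param growth Length-4 multiplicative change of each synergy's amplitude
#'   from first to last day (1 = no change).
#' @param jitter_sd Standard deviation of the per-trial lognormal amplitude
#'   jitter applied to each synergy.
#' @param full_recordings If `TRUE`, attach a complete [gen_trial()]
#'   recording per trial; otherwise only the activation matrix (fast path
#'   for synergy/statistics studies).
#' @return List of days; each day is a list of trials, each with `M`
#'   (muscles x 101 activation matrix), `day`, `trial`, and optionally
#'   `recording`.
#' @export
gen_longitudinal_series <- function(config = synth_config(), days = 2L,
                                    trials_per_day = 10L,
                                    growth = c(1, 1, 1, 1),
                                    jitter_sd = 0.10,
                                    full_recordings = FALSE) {
  if (days < 2L) sts_error("need at least two days", "sts_validation_error")
  if (trials_per_day < 5L) sts_error("need at least five trials per day", "sts_validation_error")
  lapply(seq_len(days), function(d) {
    day_factor <- growth^((d - 1) / (days - 1))
    lapply(seq_len(trials_per_day), function(tr) {
      seed_dt <- config$seed + 7919L * d + 104729L * tr
      jit <- exp(local_rnorm(4L, seed = seed_dt, sd = jitter_sd))
      cfg_t <- config
      cfg_t$synergy_levels <- config$synergy_levels * day_factor * jit
      out <- list(M = gen_activation_matrix(cfg_t, seed = seed_dt + 1L),
                  day = d, trial = tr)
      if (full_recordings) {
        cfg_t$seed <- seed_dt + 2L
        out$recording <- gen_trial(cfg_t)
      }
      out
    })
  })
}
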