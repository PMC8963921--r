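#' EMG envelope extraction
#'
#' Conditions one raw EMG channel into a non-negative activation envelope:
#' zero-lag 4th-order Butterworth band-pass at 40-400 Hz, full-wave
#' rectification, then a zero-lag 4th-order Butterworth low-pass at 4 Hz.
#' Zero-lag filtering is forward-backward ([signal::filtfilt()]) on a
#' half-order design, the usual reading of an "Nth-order zero-lag
#' Butterworth". Small negative undershoot from the final low-pass is
#' clipped at zero.
#'
#' @param raw_channel Numeric vector, raw EMG in V.
#' @param rate Sampling rate in Hz; must exceed 800 Hz so the 400 Hz band
#'   edge stays below Nyquist. At 1000 Hz the edge sits at 0.8 Nyquist,
#'   which is allowed with a warning.
#' @param band Band-pass edges in Hz (default `c(40, 400)`).
#' @param lowpass Envelope low-pass cut-off in Hz (default 4).
#' @return Non-negative numeric vector, same length as the input.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 2000)
#' x <- sin(2 * pi * 120 * t)
#' env <- emg_envelope(x, 2000)
# Forward-backward filtering with odd-reflection padding long enough for the
# slowest filter pole to settle, so edges carry no start-up transient.
zero_lag_filter <- function(filt, x) {
  n <- length(x)
  r <- tryCatch(max(Mod(polyroot(rev(filt$a)))), error = function(e) 0.95)
  r <- min(max(r, 0.5), 0.99995)
  pad <- min(n - 1L, max(12L, ceiling(log(1e-13) / log(r))))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1L):(pad + n)]
}

emg_envelope <- function(raw_channel, rate, band = c(40, 400), lowpass = 4) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 800) {
    sts_error("EMG sample rate must exceed 800 Hz", "sts_rate_error")
  }
  stopifnot_finite(raw_channel, "raw EMG")
  if (length(raw_channel) < 24L) {
    sts_error("EMG series too short to filter", "sts_validation_error")
  }
  nyq <- rate / 2
  if (band[2] / nyq >= 0.75) {
    warning(sprintf("band edge %g Hz is at %.2f of Nyquist (%g Hz)",
                    band[2], band[2] / nyq, nyq))
  }
  bp <- signal::butter(2, band / nyq, type = "pass")
  x <- zero_lag_filter(bp, raw_channel)
  lp <- signal::butter(2, lowpass / nyq, type = "low")
  env <- zero_lag_filter(lp, abs(x))
  pmax(env, 0)
}

#' Low-pass filter reaction-force series
#'
#' Zero-lag 4th-order Butterworth low-pass at 20 Hz (half-order design
#' applied forward-backward).
#'
#' @param force_series Numeric vector of forces in N.
#' @param rate Sampling rate in Hz (> 40 Hz).
#' @param cutoff Cut-off frequency in Hz (default 20).
#' @return Filtered series, same length.
#' @export
filter_forces <- function(force_series, rate, cutoff = 20) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 2 * cutoff) {
    sts_error("force sample rate must exceed twice the cut-off", "sts_rate_error")
  }
  if (length(force_series) == 0L) {
    sts_error("empty force series", "sts_validation_error")
  }
  stopifnot_finite(force_series, "force series")
  if (length(force_series) < 24L) {
    sts_error("force series too short to filter", "sts_validation_error")
  }
  lp <- signal::butter(2, cutoff / (rate / 2), type = "low")
  zero_lag_filter(lp, force_series)
}

#' Detect seat-off from the hip force plate
#'
#' Seat-off is the first instant the vertical force under the hip drops
#' strictly below `threshold` (10 N). The recording must start loaded: every
#' sample in the first 0.2 s must exceed the threshold, guarding against
#' trials that begin unloaded.
#'
#' @param hip_vertical_force Numeric vector of (filtered) hip vertical force, N.
#' @param rate Sampling rate in Hz.
#' @param threshold Unloading threshold in N (default 10).
#' @return Seat-off time in seconds (time of the first sub-threshold sample;
#'   sample 1 is time 0).
#' @export
detect_seat_off <- function(hip_vertical_force, rate, threshold = 10) {
  stopifnot_finite(hip_vertical_force, "hip vertical force")
  n_prefix <- max(1L, ceiling(0.2 * rate))
  if (length(hip_vertical_force) < n_prefix + 1L) {
    sts_error("hip force series shorter than the 0.2 s loading prefix",
              "sts_validation_error")
  }
  if (any(hip_vertical_force[seq_len(n_prefix)] < threshold)) {
    sts_error("hip plate not loaded above threshold at recording start",
              "sts_invalid_loading_error")
  }
  below <- which(hip_vertical_force < threshold)
  if (length(below) == 0L) {
    sts_error("hip vertical force never drops below threshold: no seat-off",
              "sts_no_seat_off_error")
  }
  (below[1] - 1L) / rate
}

#' Cut and resample a 3-second trial window around seat-off
#'
#' One sit-to-stand trial is the 3 s interval from 1 s before seat-off to
#' 2 s after it. All streams are cut to that window and resampled (linear
#' interpolation; every stream was low-pass filtered well below the target
#' Nyquist beforehand) onto a common grid at `common_rate`, 301 samples at
#' the default 100 Hz (inclusive endpoints). A fixed-length motion-progress
#' resampling (0-100%, `progress_n` samples) of every stream is attached.
#'
#' @param envelopes Named list or matrix-like data.frame of EMG envelope
#'   series (columns = muscles).
#' @param emg_rate EMG sampling rate, Hz.
#' @param joint_angles Data.frame/list of the four joint-angle series (rad).
#' @param angle_rate Kinematics sampling rate, Hz.
#' @param forces Data.frame/list of filtered force series (N).
#' @param force_rate Force sampling rate, Hz.
#' @param seat_off_time Seat-off time in seconds (on the shared clock; all
#'   streams are assumed to start at time 0).
#' @param common_rate Output sampling rate, Hz (default 100, the kinematics
#'   native rate that drives inverse dynamics).
#' @param progress_n Number of motion-progress samples (default 101,
#'   0-100% inclusive).
#' @param pre,post Seconds before/after seat-off (defaults 1 and 2).
#' @return An object of class `processed_trial`: list with `time` (window
#'   time axis, s), `envelopes`, `joint_angles`, `forces` (data.frames on the
#'   common grid), `seat_off_time`, `window` (`c(t_start, t_end)`),
#'   `progress` (percent grid) and `progress_grid` (list of data.frames
#'   resampled to the progress grid), `rate`.
#' @export
segment_trial <- function(envelopes, emg_rate, joint_angles, angle_rate,
                          forces, force_rate, seat_off_time,
                          common_rate = 100, progress_n = 101,
                          pre = 1, post = 2) {
  t0 <- seat_off_time - pre
  t1 <- seat_off_time + post
  dur <- function(x, rate) (nrow_or_len(x) - 1L) / rate
  if (t0 < -1e-9 || t1 > min(dur(envelopes, emg_rate),
                             dur(joint_angles, angle_rate),
                             dur(forces, force_rate)) + 1e-9) {
    sts_error("trial window exceeds recording bounds", "sts_truncation_error")
  }
  tt <- t0 + seq(0, by = 1 / common_rate, length.out = round((t1 - t0) * common_rate) + 1L)
  resample_set <- function(x, rate, grid) {
    x <- as.data.frame(x)
    src_t <- (seq_len(nrow(x)) - 1L) / rate
    out <- as.data.frame(lapply(x, function(col) {
      approx(src_t, col, xout = grid, rule = 2)$y
    }))
    names(out) <- names(x)
    out
  }
  env_w <- resample_set(envelopes, emg_rate, tt)
  ang_w <- resample_set(joint_angles, angle_rate, tt)
  frc_w <- resample_set(forces, force_rate, tt)

  pgrid <- seq(0, 100, length.out = progress_n)
  tp <- t0 + (t1 - t0) * pgrid / 100
  structure(
    list(
      time = tt - t0,
      envelopes = env_w, joint_angles = ang_w, forces = frc_w,
      seat_off_time = seat_off_time, window = c(t0, t1),
      rate = common_rate,
      progress = pgrid,
      progress_grid = list(
        envelopes = resample_set(envelopes, emg_rate, tp),
        joint_angles = resample_set(joint_angles, angle_rate, tp),
        forces = resample_set(forces, force_rate, tp)
      )
    ),
    class = "processed_trial"
  )
}

nrow_or_len <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) nrow(x) else length(x[[1]])
}

#' Normalize an envelope to an MVC reference value
#'
#' Reference-mode normalization for healthy-subject validation: element-wise
#' division by the muscle's maximum-voluntary-contraction activation value.
#' Values above 1 are permitted (task activation can exceed the recorded
#' MVC) and flagged with a warning.
#'
#' @param envelope Non-negative envelope series.
#' @param mvc_value Positive scalar MVC activation for this muscle.
#' @return The normalized series.
#' @export
mvc_normalize <- function(envelope, mvc_value) {
  if (!is.numeric(mvc_value) || length(mvc_value) != 1L || mvc_value <= 0) {
    sts_error("MVC value must be a positive scalar", "sts_validation_error")
  }
  out <- envelope / mvc_value
  if (any(out > 1)) {
    warning(sprintf("normalized activation exceeds 1 (max %.3f)", max(out)))
  }
  out
}

#' Full preprocessing of one raw trial recording
#'
#' Applies [emg_envelope()] to every EMG channel, [filter_forces()] to every
#' force series, [detect_seat_off()] on the filtered hip vertical force, and
#' [segment_trial()] to produce the 3 s windowed trial. In reference mode
#' (`mvc` given), envelopes are MVC-normalized before segmentation; the peak
#' used in MVC mode can come from the segmented window or the full recording
#' (`mvc_scope`), defaulting to the trial window.
#'
#' @param recording A list with `emg` (data.frame of raw channels), `emg_rate`,
#'   `angles` (data.frame of 4 joint-angle series), `angle_rate`, `forces`
#'   (data.frame with a `hip_v` column among the force series), `force_rate`.
#'   [gen_trial()] and [read_trial_recording()] produce this shape.
#' @param mvc Optional named per-muscle MVC values (reference mode).
#' @param mvc_scope `"trial"` or `"recording"`: window used when reporting the
#'   per-muscle peak in MVC mode.
#' @param ... Passed to [segment_trial()].
#' @return A `processed_trial` (see [segment_trial()]).
#' @export
preprocess_trial <- function(recording, mvc = NULL, mvc_scope = c("trial", "recording"),
                             ...) {
  mvc_scope <- match.arg(mvc_scope)
  env <- as.data.frame(lapply(recording$emg, emg_envelope, rate = recording$emg_rate))
  frc <- as.data.frame(lapply(recording$forces, filter_forces, rate = recording$force_rate))
  if (!"hip_v" %in% names(frc)) {
    sts_error("forces must include a 'hip_v' (hip vertical) series", "sts_validation_error")
  }
  so <- detect_seat_off(frc$hip_v, recording$force_rate)
  if (!is.null(mvc)) {
    for (nm in names(env)) {
      if (!nm %in% names(mvc)) {
        sts_error(sprintf("no MVC value for channel %s", nm), "sts_validation_error")
      }
      env[[nm]] <- mvc_normalize(env[[nm]], mvc[[nm]])
    }
  }
  out <- segment_trial(env, recording$emg_rate, recording$angles, recording$angle_rate,
                       frc, recording$force_rate, so, ...)
  out$mvc_scope <- if (is.null(mvc)) NULL else mvc_scope
  out
}
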