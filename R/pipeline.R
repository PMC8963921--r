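#' External forces of a processed trial
#'
#' Builds the [external_forces()] container from a windowed trial's filtered
#' force columns: hip reaction from `hip_v` (and `hip_h` when present),
#' zeroed from seat-off onward (the plate is unloaded and residual filtered
#' noise must not act on the chain); foot columns (`foot*`) summed.
#'
#' @param pt A `processed_trial`.
#' @return An [external_forces()] object on the trial's common grid.
#' @export
trial_external_forces <- function(pt) {
  n <- length(pt$time)
  hip_h <- if ("hip_h" %in% names(pt$forces)) pt$forces$hip_h else numeric(n)
  hip_v <- pt$forces$hip_v
  so_local <- pt$seat_off_time - pt$window[1]
  off <- pt$time >= so_local
  hip_h[off] <- 0; hip_v[off] <- 0
  foot_cols <- grep("^foot", names(pt$forces), value = TRUE)
  feet_v <- if (length(foot_cols)) rowSums(pt$forces[foot_cols]) else numeric(n)
  external_forces(hip = cbind(hip_h, hip_v), feet = cbind(numeric(n), feet_v))
}

#' Analyze one processed trial end to end
#'
#' Inverse dynamics, torque-matching normalization, muscle tensions and
#' synergy extraction for a single windowed trial.
#'
#' @param pt A `processed_trial`.
#' @param body A [body_model()].
#' @param muscles A [muscle_set()].
#' @param solver Solver config for [optimize_scales()].
#' @param n_synergies Synergy count (default 4).
#' @param synergy_restarts NNMF restarts (default 20).
#' @param seed Seed for solver starts and NNMF restarts.
#' @param smoothing_window Angle-smoothing window for differentiation.
#' @return List with `kin`, `torques_id` (inverse dynamics), `norm`
#'   (`normalization_result`), `tensions`, `max_tension` (named per
#'   measured muscle), `synergies` (matched `synergy_set`), `features`
#'   (from [synergy_features()]).
#' @export
analyze_trial <- function(pt, body, muscles = muscle_set(), solver = list(),
                          n_synergies = 4L, synergy_restarts = 20L, seed = 1L,
                          smoothing_window = 5L) {
  kin <- differentiate_kinematics(pt$joint_angles, pt$rate, smoothing_window)
  torques_id <- inverse_dynamics(kin, trial_external_forces(pt), body)
  solver <- modifyList(list(seed = seed), solver)
  norm <- optimize_scales(as.matrix(pt$envelopes), torques_id, kin, muscles, solver)
  tens <- muscle_tensions(norm$m_hat, kin$theta, kin$dtheta, muscles)
  measured <- intersect(colnames(norm$m_hat), measured_muscle_names())
  max_tension <- apply(tens$tension[, measured, drop = FALSE], 2, max)

  # synergies from normalized activation resampled to the progress grid
  pn <- length(pt$progress)
  tp <- seq(min(pt$time), max(pt$time), length.out = pn)
  Mp <- t(vapply(measured, function(nm) {
    approx(pt$time, norm$m_hat[, nm], xout = tp)$y
  }, numeric(pn)))
  syn <- extract_synergies(Mp, N = n_synergies, seed = seed,
                           restarts = synergy_restarts)
  syn <- reorder_synergies(syn, match_synergies(syn))
  list(kin = kin, torques_id = torques_id, norm = norm, tensions = tens,
       max_tension = max_tension, synergies = syn,
       features = synergy_features(syn))
}

#' Longitudinal feature table from per-trial analyses
#'
#' Collects per-trial features (max tension per muscle, synergy peak levels)
#' into a long data frame suitable for [longitudinal_stats()].
#'
#' @param analyses List of [analyze_trial()] results.
#' @param days Session day per analysis.
#' @return Data frame with `day`, `trial`, `feature`, `name`, `value`.
#' @export
feature_table <- function(analyses, days) {
  do.call(rbind, lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    rbind(
      data.frame(day = days[i], trial = i, feature = "max_tension",
                 name = names(a$max_tension), value = unname(a$max_tension)),
      data.frame(day = days[i], trial = i, feature = "synergy_peak",
                 name = paste0("synergy_", a$features$synergy),
                 value = a$features$peak_level)
    )
  }))
}

#' Longitudinal statistics report
#'
#' For every feature (each muscle's maximum tension; each synergy's temporal
#' peak level) runs the appropriate nonparametric between-day test and the
#' first-to-last percent change of per-day means. Significance thresholds
#' follow the study conventions: p < 0.001 for tension changes, p < 0.05
#' for synergy peak changes.
#'
#' @param feats Long feature table from [feature_table()].
#' @return Data frame (one row per feature/name) with columns `feature`,
#'   `name`, `first_day_mean`, `last_day_mean`, `percent_change`, `test`,
#'   `statistic`, `p_value`, `significant`.
#' @export
stats_report <- function(feats) {
  keys <- unique(feats[c("feature", "name")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- feats[feats$feature == keys$feature[i] & feats$name == keys$name[i], ]
    dl <- sort(unique(sub$day))
    mu_first <- mean(sub$value[sub$day == dl[1]])
    mu_last <- mean(sub$value[sub$day == dl[length(dl)]])
    st <- longitudinal_stats(sub$value, sub$day)
    thr <- if (keys$feature[i] == "max_tension") 0.001 else 0.05
    data.frame(feature = keys$feature[i], name = keys$name[i],
               first_day_mean = mu_first, last_day_mean = mu_last,
               percent_change = percent_change(mu_first, mu_last),
               test = st$test, statistic = st$statistic, p_value = st$p_value,
               significant = st$p_value < thr)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline over a set of trial manifests
#'
#' Per trial: read, preprocess, inverse dynamics, normalization, tensions,
#' synergies. Per subject: longitudinal feature statistics and a
#' `summary.tsv` (muscle and synergy rows with percent change, test,
#' p-value and significance flag). A trial whose stage fails is dropped
#' with a logged reason; the summary records completed-trial counts.
#'
#' @param manifests Character vector of `trial.yaml` paths.
#' @param body A [body_model()].
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param muscles,solver,seed,... Passed to [analyze_trial()].
#' @param verbose Print per-stage progress.
#' @return List with `analyses`, `days`, `report` (the summary data frame),
#'   `failed` (named reasons), `n_completed`.
#' @export
run_pipeline <- function(manifests, body, out_dir = NULL, muscles = muscle_set(),
                         solver = list(), seed = 1L, verbose = FALSE, ...) {
  if (length(manifests) == 0L) {
    sts_error("no trial manifests given", "sts_validation_error")
  }
  analyses <- list(); days <- integer(); failed <- character()
  for (mp in manifests) {
    res <- tryCatch({
      rec <- read_trial_recording(mp)
      pt <- preprocess_trial(rec)
      a <- analyze_trial(pt, body, muscles = muscles, solver = solver,
                         seed = seed, ...)
      list(a = a, day = rec$session_day)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[mp] <- conditionMessage(res)
      if (verbose) message(sprintf("trial %s failed: %s", mp, failed[mp]))
    } else {
      analyses[[length(analyses) + 1L]] <- res$a
      days <- c(days, res$day)
      if (verbose) message(sprintf("trial %s done (day %s)", mp, res$day))
    }
  }
  if (length(analyses) == 0L) {
    sts_error("no trial completed successfully", "sts_runtime_error")
  }
  report <- stats_report(feature_table(analyses, days))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report, file.path(out_dir, "summary.tsv"))
    jsonlite::write_json(
      list(n_completed = length(analyses), failed = as.list(failed),
           provenance = provenance(seed)),
      file.path(out_dir, "pipeline.json"), auto_unbox = TRUE, digits = NA)
  }
  list(analyses = analyses, days = days, report = report,
       failed = failed, n_completed = length(analyses))
}
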