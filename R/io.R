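#' Tabular and manifest IO
#'
#' All tables are written as TSV with a `time_s` (or `progress_pct`) first
#' column and floats at 12 significant digits, so write-read round trips are
#' lossless at working precision. Every metadata file carries provenance:
#' package version, seed and a configuration hash.
#'
#' @param x Data frame to write.
#' @param path Output file.
#' @return `write_tsv()` invisibly returns `path`.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(lapply(x, function(col) {
    if (is.double(col)) signif(col, 12) else col
  }), check.names = FALSE)
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @param required Column names that must be present.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) sts_error(sprintf("file not found: %s", path), "sts_io_error")
  x <- tryCatch(read.delim(path, check.names = FALSE),
                error = function(e) sts_error(
                  sprintf("malformed table %s: %s", path, conditionMessage(e)),
                  "sts_parse_error"))
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      sts_error(sprintf("%s: missing column(s) %s", path,
                        paste(missing, collapse = ", ")), "sts_parse_error")
    }
  }
  x
}

# Small stable content hash (modular rolling hash over the serialized object)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance <- function(seed = NA, config = NULL) {
  list(package = "stsnorm",
       version = as.character(packageVersion("stsnorm")),
       seed = seed,
       config_hash = config_hash(if (is.null(config)) list(seed = seed) else config))
}

#' Write or read a raw trial recording
#'
#' A recording is stored as one CSV per stream (first column `time_s`,
#' remaining columns labeled channels) plus a YAML manifest naming the
#' files, rates, subject and session day.
#'
#' @param recording Recording list (see [preprocess_trial()]).
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest provenance.
#' @return `write_trial_recording()` returns the manifest path;
#'   `read_trial_recording()` returns the recording list.
#' @export
write_trial_recording <- function(recording, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(df, rate, name) {
    df <- cbind(time_s = (seq_len(nrow(df)) - 1L) / rate, df)
    p <- file.path(dir, paste0(name, ".csv"))
    write.table(as.data.frame(lapply(df, signif, digits = 12)), p,
                sep = ",", row.names = FALSE, quote = FALSE)
    basename(p)
  }
  manifest <- list(
    emg = list(file = put(recording$emg, recording$emg_rate, "emg"),
               rate = recording$emg_rate),
    angles = list(file = put(recording$angles, recording$angle_rate, "angles"),
                  rate = recording$angle_rate),
    forces = list(file = put(recording$forces, recording$force_rate, "forces"),
                  rate = recording$force_rate),
    subject_id = recording$subject_id,
    session_day = recording$session_day,
    provenance = provenance(seed)
  )
  mp <- file.path(dir, "trial.yaml")
  yaml::write_yaml(manifest, mp)
  mp
}

#' @rdname write_trial_recording
#' @param manifest_path Path to a `trial.yaml` manifest.
#' @export
read_trial_recording <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    sts_error(sprintf("manifest not found: %s", manifest_path), "sts_io_error")
  }
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  get <- function(entry) {
    df <- read_tsv_any(file.path(base, entry$file))
    df$time_s <- NULL
    df
  }
  list(emg = get(man$emg), emg_rate = man$emg$rate,
       angles = get(man$angles), angle_rate = man$angles$rate,
       forces = get(man$forces), force_rate = man$forces$rate,
       subject_id = man$subject_id, session_day = man$session_day)
}

read_tsv_any <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  x <- tryCatch(read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           dec = "."),
                error = function(e) sts_error(
                  sprintf("malformed table %s: %s", path, conditionMessage(e)),
                  "sts_parse_error"))
  x
}

#' Write or read a processed trial directory
#'
#' Serializes a `processed_trial` as `envelopes.tsv`, `angles.tsv`,
#' `forces.tsv` (common-grid window) plus `meta.json` with seat-off time,
#' window and provenance.
#'
#' @param pt A `processed_trial` from [segment_trial()].
#' @param dir Output directory.
#' @param seed Seed recorded in provenance.
#' @return `write_processed_trial()` invisibly returns `dir`.
#' @export
write_processed_trial <- function(pt, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- function(df) cbind(time_s = signif(pt$time, 12), df)
  write_tsv(tag(pt$envelopes), file.path(dir, "envelopes.tsv"))
  write_tsv(tag(pt$joint_angles), file.path(dir, "angles.tsv"))
  write_tsv(tag(pt$forces), file.path(dir, "forces.tsv"))
  jsonlite::write_json(
    list(seat_off_time = pt$seat_off_time, window = pt$window, rate = pt$rate,
         progress_n = length(pt$progress), provenance = provenance(seed)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_processed_trial
#' @export
read_processed_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  grab <- function(name) {
    df <- read_tsv(file.path(dir, name), required = "time_s")
    df$time_s <- NULL
    df
  }
  env <- grab("envelopes.tsv"); ang <- grab("angles.tsv"); frc <- grab("forces.tsv")
  so_local <- meta$seat_off_time - meta$window[1]
  pt <- segment_trial(env, meta$rate, ang, meta$rate, frc, meta$rate,
                      seat_off_time = so_local,
                      common_rate = meta$rate, progress_n = meta$progress_n,
                      pre = so_local,
                      post = meta$window[2] - meta$seat_off_time)
  pt$window <- meta$window
  pt$seat_off_time <- meta$seat_off_time
  pt
}
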