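#' Hill-type muscle parameter set
#'
#' Parameters for the 11 modeled sit-to-stand muscles: tibialis anterior (TA),
#' soleus (SOL), gastrocnemius (GAS), rectus femoris (RF), vastus lateralis
#' (VAS), biceps femoris long/short head (BFL/BFS), gluteus maximus (GMAX),
#' rectus abdominis (RA), erector spinae (ES) and iliopsoas (IL). IL is a deep
#' hip flexor with no surface-EMG channel; the normalizer treats its
#' activation as a free bounded variable and it is excluded from accuracy
#' metrics.
#'
#' Each muscle carries: isometric maximum force `fmax` (N), optimal fiber
#' length `l_opt` (m), maximum contraction velocity `v_max` (m/s), a signed
#' moment arm per joint `r` (m; 0 where unattached), and a reference length
#' `l_ref` (m) attained at the reference posture `theta_ref` (rad; defaults
#' to upright stance, all zeros). Moment-arm signs follow the convention in
#' [joint_names()]: positive moment arm means the muscle shortens as that
#' joint angle increases and contributes positive torque there.
#'
#' Default values are literature-order magnitudes (cadaver/MRI-derived tables
#' round to figures of this size); every value can be overridden per muscle or
#' loaded from YAML ([read_muscle_set()]).
#'
#' @param overrides Named list: per-muscle lists of fields to override, e.g.
#'   `list(TA = list(fmax = 900))`.
#' @return An object of class `muscle_set`: named list of muscles, each a list
#'   with `name`, `fmax`, `l_opt`, `v_max`, `r` (length-4 named), `l_ref`,
#'   `theta_ref`.
#' @export
#' @examples
#' ms <- muscle_set()
#' ms$VAS$r
muscle_set <- function(overrides = NULL) {
  r0 <- setNames(numeric(4), joint_names())
  arm <- function(...) {
    v <- r0
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  # l_opt / v_max are effective muscle-tendon-unit values: with no series
  # elastic element in the model, the normalized length must absorb the whole
  # joint excursion, so l_opt is MTU-scale (keeps l_hat within ~0.7-1.3 over
  # the sit-to-stand range instead of saturating the passive element)
  defs <- list(
    TA   = list(fmax = 1000, l_opt = 0.31, v_max = 1.9, r = arm(ankle = -0.040)),
    SOL  = list(fmax = 3500, l_opt = 0.26, v_max = 1.6, r = arm(ankle = 0.048)),
    GAS  = list(fmax = 1500, l_opt = 0.39, v_max = 2.3, r = arm(ankle = 0.048, knee = 0.020)),
    RF   = list(fmax = 1200, l_opt = 0.36, v_max = 2.2, r = arm(knee = -0.048, hip = -0.040)),
    VAS  = list(fmax = 4000, l_opt = 0.33, v_max = 2.0, r = arm(knee = -0.045)),
    BFL  = list(fmax = 1300, l_opt = 0.44, v_max = 2.6, r = arm(knee = 0.025, hip = 0.055)),
    BFS  = list(fmax = 800,  l_opt = 0.27, v_max = 1.6, r = arm(knee = 0.025)),
    GMAX = list(fmax = 2500, l_opt = 0.33, v_max = 2.0, r = arm(hip = 0.060)),
    RA   = list(fmax = 900,  l_opt = 0.30, v_max = 1.8, r = arm(lumbar = -0.080)),
    ES   = list(fmax = 2000, l_opt = 0.25, v_max = 1.5, r = arm(lumbar = 0.058)),
    IL   = list(fmax = 1500, l_opt = 0.30, v_max = 1.8, r = arm(hip = -0.035))
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(defs)) {
        sts_error(sprintf("unknown muscle '%s'", nm), "sts_validation_error")
      }
      defs[[nm]] <- modifyList(defs[[nm]], overrides[[nm]])
    }
  }
  ms <- lapply(names(defs), function(nm) {
    m <- defs[[nm]]
    m$name <- nm
    if (is.null(m$l_ref)) m$l_ref <- m$l_opt
    if (is.null(m$theta_ref)) m$theta_ref <- setNames(numeric(4), joint_names())
    r <- r0
    r[names(m$r)] <- m$r
    m$r <- r
    validate_muscle(m)
    m
  })
  structure(setNames(ms, names(defs)), class = "muscle_set")
}

validate_muscle <- function(m) {
  if (m$fmax <= 0 || m$l_opt <= 0 || m$v_max <= 0) {
    sts_error(sprintf("muscle %s: fmax, l_opt, v_max must be positive", m$name),
              "sts_validation_error")
  }
  nz <- sum(m$r != 0)
  if (nz == 0) {
    sts_error(sprintf("muscle %s: needs at least one nonzero moment arm", m$name),
              "sts_validation_error")
  }
  if (m$name %in% c("GAS", "RF", "BFL") && nz != 2L) {
    sts_error(sprintf("muscle %s is biarticular and must span exactly two joints", m$name),
              "sts_validation_error")
  }
  invisible(m)
}

#' Moment-arm matrix of a muscle set
#'
#' @param muscles A [muscle_set()].
#' @return 4 x n_muscle matrix of signed moment arms (m), rows named by joint.
#' @export
moment_arm_matrix <- function(muscles) {
  R <- vapply(muscles, function(m) m$r, numeric(4))
  rownames(R) <- joint_names()
  R
}

#' Read or write a muscle set as YAML
#'
#' @param path YAML file with one block per muscle (fields of [muscle_set()]).
#' @return `read_muscle_set()` returns a `muscle_set`.
#' @export
read_muscle_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- lapply(cfg, function(m) {
    if (!is.null(m$r)) m$r <- unlist(m$r)
    if (!is.null(m$theta_ref)) m$theta_ref <- unlist(m$theta_ref)
    m
  })
  muscle_set(overrides = cfg)
}

#' @rdname read_muscle_set
#' @param muscles A [muscle_set()].
#' @export
write_muscle_set <- function(muscles, path) {
  yaml::write_yaml(lapply(unclass(muscles), function(m) {
    list(fmax = m$fmax, l_opt = m$l_opt, v_max = m$v_max,
         r = as.list(m$r), l_ref = m$l_ref, theta_ref = as.list(m$theta_ref))
  }), path)
  invisible(path)
}

#' @export
print.muscle_set <- function(x, ...) {
  cat(sprintf("Hill-type muscle set: %d muscles\n", length(x)))
  df <- data.frame(
    fmax = vapply(x, `[[`, 0, "fmax"),
    l_opt = vapply(x, `[[`, 0, "l_opt"),
    v_max = vapply(x, `[[`, 0, "v_max"),
    t(moment_arm_matrix(x))
  )
  print(df)
  invisible(x)
}
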