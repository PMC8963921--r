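#' Four-link sagittal-plane body model
#'
#' Builds the rigid-body model used by inverse and forward dynamics: four
#' segments (shank, thigh, pelvis, HAT = head-arms-trunk) chained at four
#' joints (ankle, knee, hip, lumbar), with the ankle as the grounded root
#' (feet stay still during sit-to-stand, so the foot is not modeled).
#'
#' Segment lengths, masses, center-of-mass locations and moments of inertia
#' are scaled from subject height and mass with a table of anthropometric
#' fractions (editable; see `fractions`). Defaults are literature-order
#' values for an adult body; they are deliberately configurable because
#' published anthropometric tables differ and patient bodies deviate from
#' any generic table.
#'
#' Joint viscous resistance uses coefficients `d` (N m s/rad) at ankle,
#' knee and hip, and angle-proportional coefficients `d4_ext`, `d4_flex`
#' (N m/rad) at the lumbar joint (see [viscous_resistance()]).
#'
#' @param height Subject height in m.
#' @param mass Subject mass in kg.
#' @param fractions Optional list overriding the anthropometric fraction
#'   table; see [default_body_fractions()].
#' @param d Numeric length-3 viscous coefficients for ankle, knee, hip
#'   (N m s/rad). Zero disables viscous resistance (useful for testing).
#' @param d4_ext,d4_flex Lumbar elastic-resistance coefficients (N m/rad)
#'   applied outside the +/-0.0314 rad dead zone.
#' @param seat_offset Distance (m) along the pelvis segment from the hip
#'   joint to the seat-contact point where the hip reaction force applies.
#'
#' @return An object of class `body_model`: a list with `segments`
#'   (data.frame with length, mass, com, inertia per segment), `d`,
#'   `d4_ext`, `d4_flex`, `seat_offset`, `height`, `mass`.
#' @export
#' @examples
#' bm <- body_model(height = 1.7, mass = 65)
#' bm$segments
body_model <- function(height, mass, fractions = NULL,
                       d = c(1.0, 1.0, 1.0), d4_ext = 10, d4_flex = 10,
                       seat_offset = NULL) {
  if (!is.numeric(height) || length(height) != 1L || height <= 0) {
    sts_error("height must be a positive scalar", "sts_validation_error")
  }
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0) {
    sts_error("mass must be a positive scalar", "sts_validation_error")
  }
  fr <- default_body_fractions()
  if (!is.null(fractions)) fr <- modifyList(fr, fractions)
  if (length(d) != 3L || any(d < 0)) {
    sts_error("d must be three non-negative coefficients", "sts_validation_error")
  }
  if (d4_ext < 0 || d4_flex < 0) {
    sts_error("lumbar coefficients must be non-negative", "sts_validation_error")
  }

  seg_names <- c("shank", "thigh", "pelvis", "hat")
  len <- height * unlist(fr$length)[seg_names]
  m <- mass * unlist(fr$mass)[seg_names]
  if (sum(m) > mass + 1e-9) {
    sts_error("segment masses exceed subject mass", "sts_validation_error")
  }
  com <- len * unlist(fr$com)[seg_names]
  # inertia about the COM from radius of gyration as a fraction of segment length
  rog <- len * unlist(fr$gyration)[seg_names]
  inertia <- m * rog^2

  segments <- data.frame(
    segment = seg_names, length = as.numeric(len), mass = as.numeric(m),
    com = as.numeric(com), inertia = as.numeric(inertia),
    row.names = seg_names
  )
  if (is.null(seat_offset)) seat_offset <- segments["pelvis", "com"]

  structure(
    list(segments = segments, d = as.numeric(d),
         d4_ext = as.numeric(d4_ext), d4_flex = as.numeric(d4_flex),
         seat_offset = as.numeric(seat_offset),
         height = height, mass = mass),
    class = "body_model"
  )
}

#' Default anthropometric fraction table
#'
#' Fractions of subject height (segment length), subject mass (segment mass),
#' segment length (COM distance from the proximal joint; radius of gyration
#' about the COM) for the four modeled segments. Values are rounded
#' literature-order figures for adult bodies; the HAT segment aggregates
#' head, arms and trunk above the lumbar joint. Override any entry through
#' the `fractions` argument of [body_model()] or by editing the shipped
#' `body.yaml` configuration.
#'
#' @return A named list with elements `length`, `mass`, `com`, `gyration`,
#'   each a named list over `shank`, `thigh`, `pelvis`, `hat`.
#' @export
default_body_fractions <- function() {
  list(
    length   = list(shank = 0.246, thigh = 0.245, pelvis = 0.078, hat = 0.400),
    mass     = list(shank = 0.093, thigh = 0.200, pelvis = 0.142, hat = 0.497),
    com      = list(shank = 0.567, thigh = 0.567, pelvis = 0.500, hat = 0.626),
    gyration = list(shank = 0.303, thigh = 0.323, pelvis = 0.310, hat = 0.496)
  )
}

#' Read or write a body model as YAML
#'
#' @param path File path of the YAML configuration.
#' @return `read_body_model()` returns a [body_model()]; `write_body_model()`
#'   invisibly returns `path`.
#' @export
read_body_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  body_model(
    height = cfg$height, mass = cfg$mass,
    fractions = cfg$fractions,
    d = if (is.null(cfg$d)) c(1, 1, 1) else as.numeric(cfg$d),
    d4_ext = if (is.null(cfg$d4_ext)) 10 else cfg$d4_ext,
    d4_flex = if (is.null(cfg$d4_flex)) 10 else cfg$d4_flex,
    seat_offset = cfg$seat_offset
  )
}

#' @rdname read_body_model
#' @param body A [body_model()] object.
#' @export
write_body_model <- function(body, path) {
  fr <- default_body_fractions()
  yaml::write_yaml(list(
    height = body$height, mass = body$mass,
    d = body$d, d4_ext = body$d4_ext, d4_flex = body$d4_flex,
    seat_offset = body$seat_offset, fractions = fr
  ), path)
  invisible(path)
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("Four-link sagittal body model: height %.2f m, mass %.1f kg\n",
              x$height, x$mass))
  print(x$segments[, c("length", "mass", "com", "inertia")])
  cat(sprintf("viscous d = (%s) N m s/rad; lumbar d4 ext/flex = %.1f/%.1f N m/rad\n",
              paste(format(x$d), collapse = ", "), x$d4_ext, x$d4_flex))
  invisible(x)
}
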