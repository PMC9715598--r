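#' Trial metadata
#'
#' Bundles the subject and laboratory conventions needed to interpret one
#' gait trial: body mass and height (used for moment normalisation to
#' \%Bw*Ht), limb side, and the lab-frame walking direction and vertical
#' axis that define the mediolateral sign convention.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param mass Body mass in kg (> 0).
#' @param height Body height in m (> 0).
#' @param side `"left"` or `"right"`.
#' @param walking_direction Unit 3-vector, lab frame; normalised internally.
#' @param up_axis Unit 3-vector, lab frame, orthogonal to
#'   `walking_direction` within 1e-6; normalised internally.
#' @param fs_kinematics Kinematic sampling rate, Hz.
#' @param fs_kinetics Kinetic (force-plate) sampling rate, Hz; must be
#'   `>= fs_kinematics`.
#' @param gravity Gravitational acceleration, m/s^2.
#'
#' @return A `trial_meta` object (a named list).
#' @examples
#' trial_meta("S01", mass = 77.3, height = 1.775, side = "right")
#' @export
trial_meta <- function(subject_id = "anon",
                       mass,
                       height,
                       side = c("right", "left"),
                       walking_direction = c(1, 0, 0),
                       up_axis = c(0, 0, 1),
                       fs_kinematics = 100,
                       fs_kinetics = 1000,
                       gravity = 9.81) {
  side <- match.arg(side)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0) {
    abort("`mass` must be a positive finite scalar (kg).", class = "kamdecomp_meta_error")
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0) {
    abort("`height` must be a positive finite scalar (m).", class = "kamdecomp_meta_error")
  }
  walking_direction <- as_unit3(walking_direction, "walking_direction")
  up_axis <- as_unit3(up_axis, "up_axis")
  if (abs(sum(walking_direction * up_axis)) > 1e-6) {
    abort("`walking_direction` and `up_axis` must be orthogonal within 1e-6.",
          class = "kamdecomp_meta_error")
  }
  if (!is.numeric(fs_kinematics) || fs_kinematics <= 0 ||
      !is.numeric(fs_kinetics) || fs_kinetics < fs_kinematics) {
    abort("Require fs_kinetics >= fs_kinematics > 0.", class = "kamdecomp_meta_error")
  }
  structure(
    list(
      subject_id = as.character(subject_id)[1],
      mass = as.numeric(mass),
      height = as.numeric(height),
      side = side,
      walking_direction = walking_direction,
      up_axis = up_axis,
      fs_kinematics = as.numeric(fs_kinematics),
      fs_kinetics = as.numeric(fs_kinetics),
      gravity = as.numeric(gravity)
    ),
    class = "trial_meta"
  )
}

as_unit3 <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v))) {
    abort(sprintf("`%s` must be a finite 3-vector.", what), class = "kamdecomp_meta_error")
  }
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    abort(sprintf("`%s` must be non-zero.", what), class = "kamdecomp_meta_error")
  }
  v / n
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf(
    "<trial_meta> subject %s, %s limb, %.1f kg, %.3f m, %g/%g Hz (kin/kinetics)\n",
    x$subject_id, x$side, x$mass, x$height, x$fs_kinematics, x$fs_kinetics
  ))
  invisible(x)
}

# column layout of the native trial table
trial_signal_cols <- function() {
  roles <- c("grf", "cop", "kjc", "ajc", "heel", "toe")
  c("time", as.vector(t(outer(roles, c("x", "y", "z"), paste, sep = "_"))))
}

#' Assemble a gait trial
#'
#' A `gait_trial` is one stance-inclusive recording: synchronised lab-frame
#' time series of ground reaction force (N), centre of pressure (m), knee
#' and ankle joint centres (m) and heel/toe foot-axis landmarks (m), plus a
#' [trial_meta()]. All series must share the same uniform time base.
#'
#' @param meta A [trial_meta()].
#' @param data A data frame with columns `time`, `grf_x/y/z`, `cop_x/y/z`,
#'   `kjc_x/y/z`, `ajc_x/y/z`, `heel_x/y/z`, `toe_x/y/z` (SI units).
#' @param validate Run invariant checks (default `TRUE`).
#'
#' @return A `gait_trial` object.
#' @export
gait_trial <- function(meta, data, validate = TRUE) {
  if (!inherits(meta, "trial_meta")) {
    abort("`meta` must be a trial_meta object.", class = "kamdecomp_meta_error")
  }
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(trial_signal_cols(), names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Trial table is missing required column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      class = "kamdecomp_schema_error"
    )
  }
  data <- data[trial_signal_cols()]
  trial <- structure(list(meta = meta, data = data), class = "gait_trial")
  if (validate) validate_gait_trial(trial)
  trial
}

validate_gait_trial <- function(trial, contact_threshold = 20, cop_tol = 0.02) {
  d <- trial$data
  if (nrow(d) < 2L) {
    abort("A gait trial needs at least 2 samples.", class = "kamdecomp_data_error")
  }
  if (any(!is.finite(as.matrix(d)))) {
    abort("Trial table contains non-finite values.", class = "kamdecomp_data_error")
  }
  dt <- diff(d$time)
  if (any(dt <= 0)) {
    abort("`time` must be strictly increasing.", class = "kamdecomp_data_error")
  }
  if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-9 * max(dt)) {
    abort("`time` must be uniformly spaced (relative tolerance 1e-9).",
          class = "kamdecomp_data_error")
  }
  # COP must sit on the ground plane whenever the foot is loaded
  up <- trial$meta$up_axis
  grf_v <- as.matrix(d[c("grf_x", "grf_y", "grf_z")]) %*% up
  cop_v <- as.matrix(d[c("cop_x", "cop_y", "cop_z")]) %*% up
  loaded <- grf_v > contact_threshold
  if (any(loaded) && max(abs(cop_v[loaded])) > cop_tol) {
    abort("COP is off the ground plane while the foot is loaded.",
          class = "kamdecomp_data_error")
  }
  invisible(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %d samples @ %g Hz, %s limb, subject %s\n",
              nrow(x$data), 1 / stats::median(diff(x$data$time)),
              x$meta$side, x$meta$subject_id))
  invisible(x)
}

#' Read / write a gait trial in the native CSV + JSON format
#'
#' The native format is a flat CSV of lab-frame signals (`time`, `grf_*`,
#' `cop_*`, `kjc_*`, `ajc_*`, `heel_*`, `toe_*`; SI units) plus a JSON
#' metadata file matching the [trial_meta()] schema.
#'
#' @param trial_path Path to the trial CSV.
#' @param meta_path Path to the metadata JSON.
#' @return `read_trial()` returns a [gait_trial()]; `write_trial()` returns
#'   `trial_path` invisibly.
#' @export
read_trial <- function(trial_path, meta_path) {
  for (p in c(trial_path, meta_path)) {
    if (!file.exists(p)) {
      abort(sprintf("File not found: %s", p), class = "kamdecomp_io_error")
    }
  }
  meta_json <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("mass", "height", "side")
  missing_meta <- setdiff(required, names(meta_json))
  if (length(missing_meta) > 0) {
    abort(sprintf("Metadata JSON is missing field(s): %s.",
                  paste(missing_meta, collapse = ", ")),
          class = "kamdecomp_meta_error")
  }
  meta <- trial_meta(
    subject_id = meta_json$subject_id %||% "anon",
    mass = meta_json$mass,
    height = meta_json$height,
    side = meta_json$side,
    walking_direction = meta_json$walking_direction %||% c(1, 0, 0),
    up_axis = meta_json$up_axis %||% c(0, 0, 1),
    fs_kinematics = meta_json$fs_kinematics %||% 100,
    fs_kinetics = meta_json$fs_kinetics %||% 1000,
    gravity = meta_json$gravity %||% 9.81
  )
  data <- readr::read_csv(trial_path, show_col_types = FALSE, progress = FALSE)
  gait_trial(meta, data)
}

#' @rdname read_trial
#' @param trial A [gait_trial()].
#' @export
write_trial <- function(trial, trial_path, meta_path) {
  stopifnot(inherits(trial, "gait_trial"))
  m <- trial$meta
  readr::write_csv(trial$data, trial_path)
  jsonlite::write_json(
    list(
      subject_id = m$subject_id, mass = m$mass, height = m$height,
      side = m$side, walking_direction = m$walking_direction,
      up_axis = m$up_axis, fs_kinematics = m$fs_kinematics,
      fs_kinetics = m$fs_kinetics, gravity = m$gravity
    ),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(trial_path)
}

#' Write / read a KAM decomposition table
#'
#' Serialises the stance-normalised component profiles (`stance_pct`, `m1`,
#' `m2`, `m3`, `m4`, `dgrv_total` and optionally `id_reference`, all in
#' \%Bw*Ht) to CSV. Writing refuses a decomposition whose components do not
#' sum to the total within 1e-9 \%Bw*Ht.
#'
#' @param dec A `kam_decomposition` (see [decompose_trial()]).
#' @param path Output CSV path.
#' @return `write_decomposition()` returns `path` invisibly;
#'   `read_decomposition()` returns a tibble of the profile columns.
#' @export
write_decomposition <- function(dec, path) {
  stopifnot(inherits(dec, "kam_decomposition"))
  prof <- dec$profiles
  resid <- max(abs(prof$m1 + prof$m2 + prof$m3 + prof$m4 - prof$dgrv_total))
  if (resid > 1e-9) {
    abort(sprintf(
      "Component sum differs from dgrv_total by %.3g %%Bw*Ht (> 1e-9); refusing to write.",
      resid), class = "kamdecomp_invariant_error")
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) {
    abort(sprintf("Directory does not exist: %s", dirname(path)),
          class = "kamdecomp_io_error")
  }
  cols <- c("stance_pct", "m1", "m2", "m3", "m4", "dgrv_total")
  if ("id_reference" %in% names(prof)) cols <- c(cols, "id_reference")
  readr::write_csv(prof[cols], path)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "kamdecomp_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a C3D motion-capture file (not supported)
#'
#' Ingestion of binary C3D containers is not implemented in this package;
#' convert recordings to the native CSV + JSON trial format (see
#' [read_trial()]) with any motion-capture toolchain and load those instead.
#'
#' @param path Path to a C3D file.
#' @param mapping Named list mapping C3D point labels to trial roles.
#' @export
read_c3d <- function(path, mapping = list()) {
  abort(paste(
    "C3D ingestion is not supported by this build.",
    "Export the recording to the native trial CSV + metadata JSON",
    "(see ?read_trial) and use read_trial() instead."
  ), class = "kamdecomp_not_supported_error")
}
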