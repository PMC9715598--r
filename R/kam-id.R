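#' Anthropometric segment parameters for foot and shank
#'
#' Scales segment mass, centre-of-mass position and frontal-plane radius of
#' gyration from body mass using a published anthropometric table:
#' `"deLeva"` (adjusted Zatsiorsky-Seluyanov, male values) or `"dempster"`
#' (classic cadaver data as tabulated by Winter). COM offsets are fractions
#' of segment length from the proximal end (knee for the shank, heel for
#' the foot); radii of gyration are about the segment COM. Nominal segment
#' lengths are scaled from stature; the inverse-dynamics routine replaces
#' them with measured landmark distances when available.
#'
#' @param meta A [trial_meta()].
#' @param table `"deLeva"` (default) or `"dempster"`.
#' @return A list with elements `foot` and `shank`, each a list with
#'   `mass` (kg), `com_offset`, `radius_of_gyration` (fractions of segment
#'   length) and `length` (m, nominal).
#' @export
anthropometrics <- function(meta, table = c("deLeva", "dempster")) {
  table <- match.arg(table)
  tab <- switch(table,
    deLeva = list(
      shank = c(mass_frac = 0.0433, com = 0.4459, rg = 0.251, len = 0.2460),
      foot = c(mass_frac = 0.0137, com = 0.4415, rg = 0.257, len = 0.1520)
    ),
    dempster = list(
      shank = c(mass_frac = 0.0465, com = 0.4330, rg = 0.302, len = 0.2460),
      foot = c(mass_frac = 0.0145, com = 0.5000, rg = 0.475, len = 0.1520)
    )
  )
  mk <- function(row) {
    list(
      mass = meta$mass * row[["mass_frac"]],
      com_offset = row[["com"]],
      radius_of_gyration = row[["rg"]],
      length = meta$height * row[["len"]]
    )
  }
  list(foot = mk(tab$foot), shank = mk(tab$shank))
}

second_derivative <- function(x, fs) {
  n <- length(x)
  if (n < 3) {
    abort("Need at least 3 samples to differentiate twice.",
          class = "kamdecomp_data_error")
  }
  a <- numeric(n)
  a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  a[1] <- a[2]
  a[n] <- a[n - 1]
  a
}

cross2 <- function(r_ml, r_v, f_ml, f_v) r_ml * f_v - r_v * f_ml

#' Newton-Euler inverse-dynamics knee adduction moment
#'
#' Reference KAM over stance computed by a bottom-up two-segment (foot,
#' shank) Newton-Euler recursion in the frontal plane: the ankle moment
#' balances the ground reaction force at the COP plus foot gravity and
#' translational inertia, and the knee moment adds the shank's
#' gravitational, translational and rotational inertial terms. The moment
#' is taken about the global anteroposterior axis at the knee joint centre,
#' reported as the external moment with adduction positive, so with
#' massless segments it reduces exactly to [grv_kam()]. Segment COM
#' accelerations and the shank frontal-plane angular acceleration use
#' central finite differences (one-sided at the boundaries) on optionally
#' pre-filtered kinematics. The foot's own rotational inertia about the
#' anteroposterior axis is neglected (flat-foot frontal rotation is
#' negligible at gait speeds).
#'
#' @param trial A [gait_trial()].
#' @param params Segment parameters from [anthropometrics()]; measured
#'   heel-toe and knee-ankle distances override the nominal lengths for
#'   the radii of gyration.
#' @param frame Optional [limb_frame()] (defaults to trial metadata).
#' @param segment Optional stance segment (defaults to [detect_stance()]
#'   at 20 N on vertical GRF).
#' @param filter Low-pass filter signals first (default `TRUE`; set
#'   `FALSE` if the trial is already filtered).
#' @param cutoff,filter_order Butterworth settings.
#' @param fs Sampling rate; inferred from the time column when `NULL`.
#' @return External KAM in N·m over the stance samples, adduction positive.
#' @export
newton_euler_kam <- function(trial, params = NULL, frame = NULL, segment = NULL,
                             filter = TRUE, cutoff = 8, filter_order = 4,
                             fs = NULL) {
  stopifnot(inherits(trial, "gait_trial"))
  meta <- trial$meta
  frame <- frame %||% limb_frame_from_meta(meta)
  params <- params %||% anthropometrics(meta)
  fs <- fs %||% (1 / stats::median(diff(trial$data$time)))
  if (nrow(trial$data) < 3) {
    abort("Inverse dynamics needs at least 3 samples for differentiation.",
          class = "kamdecomp_data_error")
  }

  d <- trial$data
  if (filter) {
    sig_cols <- setdiff(trial_signal_cols(), "time")
    d[sig_cols] <- lapply(d[sig_cols], lowpass_filter,
                          fs = fs, cutoff = cutoff, order = filter_order)
  }
  pick <- function(role) as.matrix(d[paste(role, c("x", "y", "z"), sep = "_")])
  grf <- to_limb_scalars(pick("grf"), frame)
  cop <- to_limb_scalars(pick("cop"), frame)
  kjc <- to_limb_scalars(pick("kjc"), frame)
  ajc <- to_limb_scalars(pick("ajc"), frame)
  heel <- to_limb_scalars(pick("heel"), frame)
  toe <- to_limb_scalars(pick("toe"), frame)

  if (is.null(segment)) {
    # contact events from the raw (pre-filter) plate force
    grf_v_raw <- as.numeric(
      as.matrix(trial$data[c("grf_x", "grf_y", "grf_z")]) %*%
        frame$vertical_axis)
    segment <- detect_stance(grf_v_raw, fs, threshold = 20)
  }
  g <- meta$gravity

  # segment COMs along the measured joint-to-joint / heel-to-toe axes
  cf <- params$foot$com_offset
  cs <- params$shank$com_offset
  foot_com_ml <- heel$ml + cf * (toe$ml - heel$ml)
  foot_com_v <- heel$v + cf * (toe$v - heel$v)
  shank_com_ml <- kjc$ml + cs * (ajc$ml - kjc$ml)
  shank_com_v <- kjc$v + cs * (ajc$v - kjc$v)

  shank_len <- sqrt((kjc$ap - ajc$ap)^2 + (kjc$ml - ajc$ml)^2 + (kjc$v - ajc$v)^2)
  l_shank <- stats::median(shank_len)
  i_shank <- params$shank$mass * (params$shank$radius_of_gyration * l_shank)^2

  # COM translational accelerations and shank frontal-plane angular accel.
  af_ml <- second_derivative(foot_com_ml, fs)
  af_v <- second_derivative(foot_com_v, fs)
  as_ml <- second_derivative(shank_com_ml, fs)
  as_v <- second_derivative(shank_com_v, fs)
  theta_s <- atan2(ajc$ml - kjc$ml, kjc$v - ajc$v)
  alpha_s <- second_derivative(theta_s, fs)

  m_f <- params$foot$mass
  m_s <- params$shank$mass

  # foot: GRF + gravity + ankle reaction
  fa_ml <- m_f * af_ml - grf$ml
  fa_v <- m_f * af_v - grf$v + m_f * g
  ma <- -cross2(ajc$ml - foot_com_ml, ajc$v - foot_com_v, fa_ml, fa_v) -
    cross2(cop$ml - foot_com_ml, cop$v - foot_com_v, grf$ml, grf$v)

  # shank: ankle reaction (negated), gravity, knee reaction
  fk_ml <- m_s * as_ml + fa_ml
  fk_v <- m_s * as_v + fa_v + m_s * g
  mk <- i_shank * alpha_s + ma +
    cross2(ajc$ml - shank_com_ml, ajc$v - shank_com_v, fa_ml, fa_v) -
    cross2(kjc$ml - shank_com_ml, kjc$v - shank_com_v, fk_ml, fk_v)

  # external moment (adduction positive) over the stance window
  idx <- seq(segment$start, segment$end - 1L)
  -mk[idx]
}

#' Pair a dGRV decomposition with an inverse-dynamics reference profile
#'
#' @param dgrv A `kam_decomposition` (or a numeric profile in \%Bw*Ht).
#' @param id_ref Numeric ID reference profile on the same stance axis and
#'   normalisation.
#' @return A tibble with columns `stance_pct`, `dgrv`, `id`, `diff`
#'   (`dgrv - id`).
#' @export
compare_profiles <- function(dgrv, id_ref) {
  prof <- if (inherits(dgrv, "kam_decomposition")) {
    dgrv$profiles$dgrv_total
  } else {
    as.numeric(dgrv)
  }
  id_ref <- as.numeric(id_ref)
  if (length(prof) != length(id_ref)) {
    abort(sprintf("Profile lengths differ (%d vs %d).",
                  length(prof), length(id_ref)),
          class = "kamdecomp_alignment_error")
  }
  tibble::tibble(
    stance_pct = stance_axis(length(prof)),
    dgrv = prof,
    id = id_ref,
    diff = prof - id_ref
  )
}
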