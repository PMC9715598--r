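#' Ground-reaction-vector estimate of the knee adduction moment
#'
#' The GRV model estimates the external KAM about the anteroposterior axis
#' at the knee joint centre from the ground reaction force alone, ignoring
#' segment inertial and gravitational terms:
#' `KAM = grf_ml * kjc_v + grf_v * (cop_ml - kjc_ml)`, with all
#' mediolateral quantities medial-positive so that knee adduction is
#' positive for either limb.
#'
#' @param g A frame-geometry tibble (or one row of it) from
#'   [build_frame_geometry()].
#' @return KAM in N·m (vectorised over rows), adduction positive.
#' @export
grv_kam <- function(g) {
  g$grf_ml * g$kjc_v + g$grf_v * (g$cop_ml - g$kjc_ml)
}

#' Decompose the GRV knee adduction moment into four components
#'
#' Splits the GRV KAM into moments with interpretable lever arms:
#' \describe{
#'   \item{M1}{mediolateral GRF over knee height: `grf_ml * kjc_v`.}
#'   \item{M2}{vertical GRF over the frontal-plane knee-ankle offset
#'     (tibia varus): `grf_v * (ajc_ml - kjc_ml)`.}
#'   \item{M3}{vertical GRF over the medial COP offset from the foot axis:
#'     `grf_v * cop_ml_ff * cos(fpa)`; negative only when the COP is
#'     lateral to the foot axis.}
#'   \item{M4}{vertical GRF over the anterior COP position combined with
#'     the foot progression angle: `grf_v * cop_ap_ff * sin(-fpa)`;
#'     negative with toe-out and anterior COP.}
#' }
#' In `"coordinate"` mode (default) the lever arms are the measured joint
#' coordinates and the four components sum to [grv_kam()] exactly. In
#' `"angle"` mode M1 and M2 use the tibia-angle lever arms
#' `l_shank*cos(spta) + ankle_height` and `l_shank*sin(fpta)`, which are
#' planar approximations of the same quantities and sum only approximately.
#'
#' @param g Frame-geometry tibble rows ([build_frame_geometry()]).
#' @param mode `"coordinate"` or `"angle"`.
#' @return A tibble with columns `m1`, `m2`, `m3`, `m4`, `total` in N·m.
#' @export
decompose_sample <- function(g, mode = c("coordinate", "angle")) {
  mode <- match.arg(mode)
  if (mode == "coordinate") {
    m1 <- g$grf_ml * g$kjc_v
    m2 <- g$grf_v * (g$ajc_ml - g$kjc_ml)
  } else {
    m1 <- g$grf_ml * (g$l_shank * cosd(g$spta) + g$ankle_height)
    m2 <- g$grf_v * g$l_shank * sind(g$fpta)
  }
  m3 <- g$grf_v * g$cop_ml_ff * cosd(g$fpa)
  m4 <- g$grf_v * g$cop_ap_ff * sind(-g$fpa)
  tibble::tibble(m1 = m1, m2 = m2, m3 = m3, m4 = m4,
                 total = m1 + m2 + m3 + m4)
}

#' Normalise a moment to percent bodyweight times height
#'
#' @param moment Moment(s) in N·m.
#' @param meta A [trial_meta()] supplying mass, height and gravity.
#' @return Moment in \%Bw*Ht: `moment / (mass * gravity * height) * 100`.
#' @examples
#' m <- trial_meta("S01", mass = 77.3, height = 1.775, side = "right")
#' normalize_moment(28, m)
#' @export
normalize_moment <- function(moment, meta) {
  moment / (meta$mass * meta$gravity * meta$height) * 100
}

#' Full KAM decomposition pipeline for one trial
#'
#' Runs the stance-phase pipeline: optional zero-phase low-pass filtering
#' of forces and positions, stance detection on vertical GRF, per-sample
#' limb-frame geometry, the four-component GRV decomposition, normalisation
#' to \%Bw*Ht and time-normalisation to a fixed stance-percent axis.
#' Optionally appends the Newton-Euler inverse-dynamics reference KAM.
#'
#' @param trial A [gait_trial()].
#' @param filter Low-pass filter forces and positions first (default
#'   `TRUE`).
#' @param cutoff,filter_order Butterworth settings (default 8 Hz, order 4,
#'   zero phase).
#' @param stance_threshold Contact threshold in N (default 20).
#' @param n_points Stance stations (default 101).
#' @param mode Lever-arm mode, see [decompose_sample()].
#' @param convention Tibia-angle convention, see [tibia_angles()]. Defaults
#'   to `"projection"` in coordinate mode (the angles are then purely
#'   descriptive) and to `"consistent"` in angle mode, where the angle
#'   lever arms reproduce the coordinate lever arms; pass
#'   `convention = "projection"` explicitly to evaluate the angle forms
#'   with planar projection angles (an approximation whose error grows
#'   with combined sagittal/frontal shank inclination).
#' @param include_id Also compute the inverse-dynamics reference profile
#'   (default `FALSE`).
#' @param id_table Anthropometric table for the ID reference, see
#'   [anthropometrics()].
#' @return A `kam_decomposition` object: list with `profiles` (tibble of
#'   `stance_pct`, `m1`..`m4`, `dgrv_total`, optional `id_reference`, all
#'   \%Bw*Ht), `side`, `mode`, `stance_duration` (s), `meta` and
#'   `residual_max` (max |m1+m2+m3+m4 - total| in N·m before
#'   normalisation).
#' @export
decompose_trial <- function(trial,
                            filter = TRUE,
                            cutoff = 8,
                            filter_order = 4,
                            stance_threshold = 20,
                            n_points = 101,
                            mode = c("coordinate", "angle"),
                            convention = c("projection", "consistent"),
                            include_id = FALSE,
                            id_table = c("deLeva", "dempster")) {
  mode <- match.arg(mode)
  if (missing(convention)) {
    convention <- if (mode == "angle") "consistent" else "projection"
  } else {
    convention <- match.arg(convention)
  }
  stopifnot(inherits(trial, "gait_trial"))
  meta <- trial$meta
  fs <- 1 / stats::median(diff(trial$data$time))

  # contact events are detected on the raw plate force: smoothing the force
  # first would smear the contact instant by several samples
  frame <- limb_frame_from_meta(meta)
  grf_v_raw <- as.numeric(as.matrix(trial$data[c("grf_x", "grf_y", "grf_z")]) %*%
                            frame$vertical_axis)
  segment <- detect_stance(grf_v_raw, fs, threshold = stance_threshold)

  work <- trial
  if (filter) {
    d <- work$data
    sig_cols <- setdiff(trial_signal_cols(), "time")
    d[sig_cols] <- lapply(d[sig_cols], lowpass_filter,
                          fs = fs, cutoff = cutoff, order = filter_order)
    work <- gait_trial(meta, d, validate = FALSE)
  }

  geom <- build_frame_geometry(work, segment, frame, convention = convention)
  comp <- decompose_sample(geom, mode = mode)
  residual_max <- max(abs(comp$m1 + comp$m2 + comp$m3 + comp$m4 - comp$total))

  local_seg <- list(start = 1L, end = nrow(comp) + 1L)
  norm_profile <- function(x) {
    time_normalize(normalize_moment(x, meta), local_seg, n_points)
  }
  profiles <- tibble::tibble(
    stance_pct = stance_axis(n_points),
    m1 = norm_profile(comp$m1),
    m2 = norm_profile(comp$m2),
    m3 = norm_profile(comp$m3),
    m4 = norm_profile(comp$m4)
  )
  profiles$dgrv_total <- profiles$m1 + profiles$m2 + profiles$m3 + profiles$m4

  if (include_id) {
    id_table <- match.arg(id_table)
    params <- anthropometrics(meta, table = id_table)
    id_nm <- newton_euler_kam(work, params, frame, segment,
                              filter = FALSE, fs = fs)
    profiles$id_reference <- time_normalize(
      normalize_moment(id_nm, meta), local_seg, n_points)
  }

  structure(
    list(
      profiles = profiles,
      side = meta$side,
      mode = mode,
      stance_duration = segment$duration,
      segment = segment,
      meta = meta,
      residual_max = residual_max
    ),
    class = "kam_decomposition"
  )
}

#' @export
print.kam_decomposition <- function(x, ...) {
  p <- x$profiles
  cat(sprintf(
    "<kam_decomposition> %s limb, %s lever arms, %d stance stations (%.3f s stance)\n",
    x$side, x$mode, nrow(p), x$stance_duration))
  cat(sprintf("  KAM peaks: %.3f / %.3f %%Bw*Ht; component-sum residual %.2e N*m\n",
              max(p$dgrv_total[p$stance_pct <= 50]),
              max(p$dgrv_total[p$stance_pct > 50]),
              x$residual_max))
  invisible(x)
}

#' @describeIn decompose_trial Long-format component profiles
#'   (`stance_pct`, `component`, `value`).
#' @param x A `kam_decomposition`.
#' @param ... Unused.
#' @method tidy kam_decomposition
#' @export
tidy.kam_decomposition <- function(x, ...) {
  tidyr::pivot_longer(x$profiles, -"stance_pct",
                      names_to = "component", values_to = "value")
}

#' @describeIn decompose_trial One-row summary: KAM peaks, impulse, stance
#'   duration and the exact-sum residual.
#' @method glance kam_decomposition
#' @export
glance.kam_decomposition <- function(x, ...) {
  feats <- extract_features(x$profiles$dgrv_total, x$stance_duration)
  tibble::tibble(
    first_peak = feats$first_peak,
    second_peak = feats$second_peak,
    impulse = feats$impulse,
    stance_duration = x$stance_duration,
    residual_max = x$residual_max,
    mode = x$mode,
    side = x$side
  )
}

#' @describeIn decompose_trial Component profiles versus stance percent.
#' @param object A `kam_decomposition`.
#' @method autoplot kam_decomposition
#' @export
autoplot.kam_decomposition <- function(object, ...) {
  long <- tidy(object)
  labels <- c(m1 = "M1 (ML force x knee height)", m2 = "M2 (tibia varus)",
              m3 = "M3 (medial COP)", m4 = "M4 (FPA x anterior COP)",
              dgrv_total = "dGRV total", id_reference = "ID reference")
  present <- intersect(names(labels), unique(long$component))
  long$component <- factor(long$component, levels = present,
                           labels = labels[present])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stance_pct, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Stance (%)", y = "Moment (%Bw*Ht)", colour = NULL) +
    ggplot2::theme_minimal()
}
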