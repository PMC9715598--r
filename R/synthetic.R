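#' Configuration for the stance-phase gait simulator
#'
#' Defines a parametric single-stance gait trial with analytically known
#' component ground truth. The vertical GRF is a double-bump curve (two
#' Gaussian bumps at 25\% and 75\% of stance under a smooth
#' zero-at-endpoints window), the COP travels monotonically heel-to-toe
#' along a foot axis toed out by `fpa`, the shank is inclined by `fpta` in
#' the frontal plane and follows `spta_profile` sagittally, and the knee
#' joint centre carries a speed-scaled oscillation so that inverse dynamics
#' and the GRV estimate separate at faster regimes.
#'
#' @param meta A [trial_meta()]; defaults to a healthy-adult subject
#'   (77.3 kg, 1.775 m, right limb).
#' @param speed_regime `"slow"`, `"self_selected"` or `"fast"`; sets the
#'   default stance duration (0.75 / 0.60 / 0.50 s) and scales segment
#'   accelerations (0.5 / 1 / 2).
#' @param stance_duration Stance time in s (default from `speed_regime`).
#' @param n_samples Stance samples (default `stance_duration *
#'   fs_kinematics + 1`).
#' @param fpa Foot progression angle, deg, toe-out positive (default 5).
#' @param fpta Frontal-plane tibia angle, deg, varus positive (default 4,
#'   a mid-range varus inclination of the shank at the load peaks).
#' @param spta_profile Function of stance fraction giving the sagittal
#'   tibia angle in deg (default a -15 to +20 deg sweep).
#' @param l_shank Shank length, m (default 0.246 * height).
#' @param ankle_height Ankle joint-centre height, m (default 0.08).
#' @param cop_ap_start,cop_ap_end COP travel along the foot axis relative
#'   to the ankle, m (default -0.05 at heel strike to 0.10 under the
#'   metatarsal heads at toe-off).
#' @param cop_ml_ff_profile Function of stance fraction giving the medial
#'   COP offset from the foot axis, m (default an early-stance medial bump
#'   decaying toward toe-off).
#' @param grf_v_params List `a1`, `a2` (bump amplitudes, xBw), `w1`, `w2`
#'   (bump widths, stance fraction), `edge` (fraction of stance over which
#'   a C2 smootherstep window takes the force smoothly toward zero at
#'   contact and toe-off) and `floor` (small fraction of the envelope kept
#'   at the stance endpoints, emulating the fast heel-strike/lift-off
#'   transient so that contact detection at a 20 N threshold is decisive).
#' @param grf_ml_params List `amp` (xBw, medial positive), `center`,
#'   `width` (stance fraction).
#' @param osc_amp Base amplitude of the knee-centre oscillation, m; scaled
#'   by the speed regime (default 0.008).
#' @param osc_freq Oscillation cycles per stance (default 2).
#' @param noise_sd_pos Marker/COP noise SD, m (default 0).
#' @param noise_sd_force GRF noise SD, N (default 0).
#' @param pad_samples Unloaded samples prepended/appended (default 10).
#' @param seed Integer seed for the noise stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(meta = NULL,
                       speed_regime = c("self_selected", "slow", "fast"),
                       stance_duration = NULL,
                       n_samples = NULL,
                       fpa = 5,
                       fpta = 4,
                       spta_profile = function(tau) -15 + 35 * tau,
                       l_shank = NULL,
                       ankle_height = 0.08,
                       cop_ap_start = -0.05,
                       cop_ap_end = 0.10,
                       cop_ml_ff_profile = function(tau) 0.02 * sin(pi * tau) * (1 - tau),
                       grf_v_params = list(a1 = 1.20, a2 = 1.13, w1 = 0.18, w2 = 0.18, edge = 0.28, floor = 0.14),
                       grf_ml_params = list(amp = 0.04, center = 0.3, width = 0.25),
                       osc_amp = 0.008,
                       osc_freq = 2,
                       noise_sd_pos = 0,
                       noise_sd_force = 0,
                       pad_samples = 10,
                       seed = 1L) {
  speed_regime <- match.arg(speed_regime)
  meta <- meta %||% trial_meta("sim", mass = 77.3, height = 1.775, side = "right")
  stance_duration <- stance_duration %||%
    switch(speed_regime, slow = 0.75, self_selected = 0.60, fast = 0.50)
  if (stance_duration <= 0) {
    abort("`stance_duration` must be positive.", class = "kamdecomp_config_error")
  }
  n_samples <- n_samples %||% (round(stance_duration * meta$fs_kinematics) + 1L)
  if (n_samples < 20) {
    abort("`n_samples` must be at least 20.", class = "kamdecomp_config_error")
  }
  if (noise_sd_pos < 0 || noise_sd_force < 0) {
    abort("Noise SDs must be non-negative.", class = "kamdecomp_config_error")
  }
  l_shank <- l_shank %||% (0.246 * meta$height)
  structure(
    list(
      meta = meta, speed_regime = speed_regime,
      stance_duration = stance_duration, n_samples = as.integer(n_samples),
      fpa = fpa, fpta = fpta, spta_profile = spta_profile,
      l_shank = l_shank, ankle_height = ankle_height,
      cop_ap_start = cop_ap_start, cop_ap_end = cop_ap_end,
      cop_ml_ff_profile = cop_ml_ff_profile,
      grf_v_params = grf_v_params, grf_ml_params = grf_ml_params,
      osc_amp = osc_amp, osc_freq = osc_freq,
      noise_sd_pos = noise_sd_pos, noise_sd_force = noise_sd_force,
      pad_samples = as.integer(pad_samples), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

acc_scale_for <- function(speed_regime) {
  switch(speed_regime, slow = 0.5, self_selected = 1, fast = 2)
}

#' Simulate one stance-phase gait trial with known component ground truth
#'
#' Builds the lab-frame trial signals from the configuration and, in
#' parallel, evaluates the four component moments analytically from the
#' noise-free limb-frame coordinates (coordinate lever arms, normalised to
#' \%Bw*Ht and time-normalised to `n_points` stations over the detected
#' stance). The trial itself then carries optional additive Gaussian noise
#' on positions and forces, drawn from a stream seeded by `cfg$seed`, so a
#' given configuration is bit-reproducible.
#'
#' @param cfg A [sim_config()].
#' @param n_points Stations of the ground-truth profiles (default 101).
#' @return A `sim_result` list: `trial` (a [gait_trial()]),
#'   `ground_truth` (tibble `stance_pct`, `m1`..`m4`, `dgrv_total` in
#'   \%Bw*Ht), `stance_duration` (s) and `config`.
#' @export
simulate_trial <- function(cfg, n_points = 101) {
  stopifnot(inherits(cfg, "sim_config"))
  meta <- cfg$meta
  fs <- meta$fs_kinematics
  n <- cfg$n_samples
  tau <- seq(0, 1, length.out = n)
  bw <- meta$mass * meta$gravity
  scale <- acc_scale_for(cfg$speed_regime)

  # forces (limb scalars, medial-positive ML); the smootherstep edge window
  # keeps the signal effectively band-limited below the 8 Hz pipeline filter
  gv <- cfg$grf_v_params
  sstep <- function(u) {
    u <- pmin(1, pmax(0, u))
    u^3 * (6 * u^2 - 15 * u + 10)
  }
  # contact floor: the force steps to a small decisive level at touch-down /
  # lift-off (heel-strike transient) and is otherwise a smooth C2 envelope
  floor_frac <- gv$floor %||% 0.14
  win_smooth <- sstep(tau / gv$edge) * sstep((1 - tau) / gv$edge)
  win_v <- floor_frac + (1 - floor_frac) * win_smooth
  grf_v <- bw * win_v * (gv$a1 * exp(-(tau - 0.25)^2 / (2 * gv$w1^2)) +
                           gv$a2 * exp(-(tau - 0.75)^2 / (2 * gv$w2^2)))
  gm <- cfg$grf_ml_params
  grf_ml <- bw * gm$amp * win_smooth * exp(-(tau - gm$center)^2 / (2 * gm$width^2))
  grf_ap <- -0.15 * bw * win_smooth * sin(2 * pi * tau)

  # geometry (limb scalars); ankle fixed, foot flat on the ground
  ajc_ap <- rep(0, n)
  ajc_ml <- rep(0, n)
  ajc_v <- rep(cfg$ankle_height, n)
  spta <- cfg$spta_profile(tau)
  d_ap <- cfg$l_shank * sind(spta)
  d_ml <- -cfg$l_shank * sind(cfg$fpta)
  d_v <- sqrt(pmax(0, cfg$l_shank^2 - d_ap^2 - d_ml^2))
  # zero-velocity endpoints so filtering does not ring at the stance edges
  osc <- cfg$osc_amp * scale
  osc_env <- sin(pi * tau)^2
  kjc_ap <- ajc_ap + d_ap
  kjc_ml <- ajc_ml + d_ml + osc * osc_env * sin(2 * pi * cfg$osc_freq * tau)
  kjc_v <- ajc_v + d_v + 0.5 * osc * (1 - cos(2 * pi * cfg$osc_freq * tau))

  # monotone heel-to-toe progression, eased so velocity is zero at contact
  cop_ap_ff <- cfg$cop_ap_start +
    (cfg$cop_ap_end - cfg$cop_ap_start) * tau^2 * (3 - 2 * tau)
  cop_ml_ff <- cfg$cop_ml_ff_profile(tau)
  c_f <- cosd(cfg$fpa)
  s_f <- sind(cfg$fpa)
  cop_ap <- ajc_ap + c_f * cop_ap_ff + s_f * cop_ml_ff
  cop_ml <- ajc_ml - s_f * cop_ap_ff + c_f * cop_ml_ff
  cop_v <- rep(0, n)

  heel_ap <- ajc_ap - 0.06 * c_f
  heel_ml <- ajc_ml + 0.06 * s_f
  toe_ap <- heel_ap + 0.22 * c_f
  toe_ml <- heel_ml - 0.22 * s_f

  # analytic component ground truth from the noise-free coordinates
  m1 <- grf_ml * kjc_v
  m2 <- grf_v * (ajc_ml - kjc_ml)
  m3 <- grf_v * cop_ml_ff * c_f
  m4 <- grf_v * cop_ap_ff * sind(-cfg$fpa)

  # assemble lab-frame table with unloaded padding at both ends
  frame <- limb_frame_from_meta(meta)
  to_lab <- function(ap, ml, v) {
    outer(ap, frame$ap_axis) + outer(ml, frame$ml_axis) +
      outer(v, frame$vertical_axis)
  }
  pad <- cfg$pad_samples
  pad_scalar <- function(x) c(rep(x[1], pad), x, rep(x[n], pad))
  pad_zero <- function(x) c(rep(0, pad), x, rep(0, pad))
  signals <- list(
    grf = to_lab(pad_zero(grf_ap), pad_zero(grf_ml), pad_zero(grf_v)),
    cop = to_lab(pad_scalar(cop_ap), pad_scalar(cop_ml), pad_scalar(cop_v)),
    kjc = to_lab(pad_scalar(kjc_ap), pad_scalar(kjc_ml), pad_scalar(kjc_v)),
    ajc = to_lab(pad_scalar(ajc_ap), pad_scalar(ajc_ml), pad_scalar(ajc_v)),
    heel = to_lab(pad_scalar(heel_ap), pad_scalar(heel_ml), rep(0, n + 2 * pad)),
    toe = to_lab(pad_scalar(toe_ap), pad_scalar(toe_ml), rep(0, n + 2 * pad))
  )

  if (cfg$noise_sd_pos > 0 || cfg$noise_sd_force > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(cfg$seed)
    nt <- n + 2L * pad
    if (cfg$noise_sd_force > 0) {
      signals$grf <- signals$grf + matrix(rnorm(3 * nt, sd = cfg$noise_sd_force), nt, 3)
    }
    if (cfg$noise_sd_pos > 0) {
      for (role in c("cop", "kjc", "ajc", "heel", "toe")) {
        noise <- matrix(rnorm(3 * nt, sd = cfg$noise_sd_pos), nt, 3)
        if (role == "cop") noise[, ] <- noise - outer(
          as.numeric(noise %*% frame$vertical_axis), frame$vertical_axis)
        signals[[role]] <- signals[[role]] + noise
      }
    }
  }

  nt <- n + 2L * pad
  data <- tibble::tibble(time = (seq_len(nt) - 1) / fs)
  for (role in names(signals)) {
    colnames(signals[[role]]) <- paste(role, c("x", "y", "z"), sep = "_")
    data <- dplyr::bind_cols(data, tibble::as_tibble(signals[[role]]))
  }
  trial <- gait_trial(meta, data)

  # ground truth over the stance the pipeline will detect (noise-free GRF)
  seg <- detect_stance(pad_zero(grf_v), fs, threshold = 20)
  local <- list(start = seg$start - pad, end = seg$end - pad)
  gt_profile <- function(x) {
    time_normalize(normalize_moment(x, meta), local, n_points)
  }
  ground_truth <- tibble::tibble(
    stance_pct = stance_axis(n_points),
    m1 = gt_profile(m1), m2 = gt_profile(m2),
    m3 = gt_profile(m3), m4 = gt_profile(m4)
  )
  ground_truth$dgrv_total <- with(ground_truth, m1 + m2 + m3 + m4)

  structure(
    list(trial = trial, ground_truth = ground_truth,
         stance_duration = seg$duration, config = cfg),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %s regime, fpa %.1f deg, fpta %.1f deg, %d stance samples\n",
    x$config$speed_regime, x$config$fpa, x$config$fpta, x$config$n_samples))
  invisible(x)
}

#' Scenario presets for the simulator
#'
#' Three study-like conditions sharing one base geometry:
#' \describe{
#'   \item{healthy}{natural gait: 5 deg toe-out, 2 deg tibia varus,
#'     medially offset COP in early stance.}
#'   \item{varus_oa}{medial knee osteoarthritis with varus deformity:
#'     FPA +6.5 deg and frontal tibia angle +4.1 deg relative to healthy,
#'     heavier subject, laterally shifted COP (scaled to a quarter of the
#'     healthy medial offset).}
#'   \item{braced_healthy}{healthy gait wearing a valgus-pushing
#'     ankle-foot orthosis: FPA -3.9 deg and frontal tibia angle -1.1 deg
#'     relative to healthy.}
#' }
#'
#' @param name Preset name.
#' @param speed Speed regime passed to [sim_config()].
#' @param ... Further overrides forwarded to [sim_config()].
#' @return A [sim_config()].
#' @export
scenario_preset <- function(name = c("healthy", "varus_oa", "braced_healthy"),
                            speed = c("self_selected", "slow", "fast"), ...) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("healthy", "varus_oa", "braced_healthy")) {
    abort(sprintf("Unknown scenario preset: %s",
                  paste(as.character(name), collapse = ", ")),
          class = "kamdecomp_parameter_error")
  }
  speed <- match.arg(speed)
  base_fpa <- 5
  base_fpta <- 4
  args <- switch(name,
    healthy = list(fpa = base_fpa, fpta = base_fpta),
    varus_oa = list(
      fpa = base_fpa + 6.5, fpta = base_fpta + 4.1,
      meta = trial_meta("sim-oa", mass = 91.5, height = 1.747, side = "right"),
      cop_ml_ff_profile = function(tau) 0.005 * sin(pi * tau) * (1 - tau)
    ),
    braced_healthy = list(fpa = base_fpa - 3.9, fpta = base_fpta - 1.1)
  )
  do.call(sim_config, modifyList(c(args, list(speed_regime = speed)), list(...)))
}

#' Simulate a batch of gait cycles
#'
#' Draws `cycles` independent noise realisations of one configuration (or
#' of each configuration in a list), with per-cycle seeds derived
#' deterministically from `seed` so the whole collection is reproducible.
#'
#' @param cfg A [sim_config()] or a list of them.
#' @param cycles Cycles per configuration (>= 1).
#' @param seed Integer master seed.
#' @param n_points Ground-truth stations per cycle.
#' @return A list of `sim_result` (flattened over configurations).
#' @export
simulate_batch <- function(cfg, cycles = 10, seed = 1L, n_points = 101) {
  if (cycles < 1) {
    abort("`cycles` must be at least 1.", class = "kamdecomp_config_error")
  }
  cfgs <- if (inherits(cfg, "sim_config")) list(cfg) else cfg
  stopifnot(all(vapply(cfgs, inherits, logical(1), "sim_config")))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  cycle_seeds <- sample.int(.Machine$integer.max - 1L, cycles * length(cfgs))
  out <- vector("list", cycles * length(cfgs))
  k <- 0L
  for (ci in seq_along(cfgs)) {
    for (cy in seq_len(cycles)) {
      k <- k + 1L
      cfg_k <- cfgs[[ci]]
      cfg_k$seed <- cycle_seeds[k]
      out[[k]] <- simulate_trial(cfg_k, n_points = n_points)
      attr(out[[k]], "condition") <- ci
      attr(out[[k]], "cycle") <- cy
    }
  }
  out
}
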