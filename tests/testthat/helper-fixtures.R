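# Shared fixture builders. Everything is generated in code; no data files.

# A self-consistent random frame-geometry table: the foot-frame COP offsets
# and the global medial COP offset are linked by the exact rotation, as they
# are for geometry assembled from a real trial.
random_geometry <- function(n, seed = 1) {
  set.seed(seed)
  fpa <- runif(n, -30, 30)
  ajc_ml <- runif(n, -0.1, 0.1)
  ajc_v <- runif(n, 0.05, 0.12)
  cop_ap_ff <- runif(n, -0.08, 0.20)
  cop_ml_ff <- runif(n, -0.03, 0.04)
  l_shank <- runif(n, 0.35, 0.50)
  fpta <- runif(n, -8, 12)
  spta <- runif(n, -25, 25)
  d_ml <- -l_shank * sin(fpta * pi / 180)
  d_ap <- l_shank * sin(spta * pi / 180)
  kjc_ml <- ajc_ml + d_ml
  kjc_v <- ajc_v + sqrt(pmax(0, l_shank^2 - d_ml^2 - d_ap^2))
  tibble::tibble(
    grf_ml = runif(n, -80, 80),
    grf_v = runif(n, 50, 900),
    kjc_ml = kjc_ml, kjc_v = kjc_v,
    ajc_ml = ajc_ml, ajc_v = ajc_v,
    cop_ml = ajc_ml - sin(fpa * pi / 180) * cop_ap_ff +
      cos(fpa * pi / 180) * cop_ml_ff,
    cop_ap_ff = cop_ap_ff, cop_ml_ff = cop_ml_ff,
    fpa = fpa, l_shank = l_shank, spta = spta, fpta = fpta,
    ankle_height = ajc_v
  )
}

# Constant-in-time trial from explicit limb-frame scalars (lab = canonical
# frame: x walking, z up; y is medial for the right side).
static_trial <- function(n = 120, fs = 100,
                         grf = c(0, 0, 700),        # ap, ml, v
                         cop = c(0.05, 0.01, 0),    # ap, ml, v
                         kjc = c(0, -0.02, 0.52),
                         ajc = c(0, 0, 0.08),
                         heel = c(-0.06, 0, 0),
                         toe = c(0.16, 0, 0),
                         mass = 77.3, height = 1.775, side = "right") {
  meta <- trial_meta("static", mass = mass, height = height, side = side)
  sgn <- if (side == "right") 1 else -1   # medial scalar -> lab y
  lab <- function(v) c(v[1], sgn * v[2], v[3])
  rep3 <- function(v) {
    v <- lab(v)
    stats::setNames(as.data.frame(matrix(rep(v, each = n), n, 3)), NULL)
  }
  d <- tibble::tibble(time = (seq_len(n) - 1) / fs)
  roles <- list(grf = grf, cop = cop, kjc = kjc, ajc = ajc,
                heel = heel, toe = toe)
  for (nm in names(roles)) {
    m <- rep3(roles[[nm]])
    names(m) <- paste(nm, c("x", "y", "z"), sep = "_")
    d <- dplyr::bind_cols(d, m)
  }
  gait_trial(meta, d)
}

# Prescribed frontal-plane pendulum: shank swings about a fixed knee with
# zero ground contact; used against the closed-form torque oracle.
pendulum_trial <- function(fs = 100, duration = 4, theta0 = 0.3, f_hz = 0.8,
                           l = 0.4, knee_height = 1) {
  t <- seq(0, duration, by = 1 / fs)
  theta <- theta0 * sin(2 * pi * f_hz * t)
  meta <- trial_meta("pendulum", mass = 70, height = 1.75, side = "right")
  ajc <- cbind(0, l * sin(theta), knee_height - l * cos(theta))
  d <- tibble::tibble(
    time = t,
    grf_x = 0, grf_y = 0, grf_z = 0,
    cop_x = 0, cop_y = 0, cop_z = 0,
    kjc_x = 0, kjc_y = 0, kjc_z = knee_height,
    ajc_x = ajc[, 1], ajc_y = ajc[, 2], ajc_z = ajc[, 3],
    heel_x = ajc[, 1] - 0.05, heel_y = ajc[, 2], heel_z = ajc[, 3],
    toe_x = ajc[, 1] + 0.20, toe_y = ajc[, 2], toe_z = ajc[, 3]
  )
  list(trial = gait_trial(meta, d, validate = FALSE), theta = theta, t = t,
       l = l, meta = meta)
}

# Mirror a trial through the sagittal plane (flip lab y) and flip side.
mirror_trial <- function(trial) {
  m <- trial$meta
  meta_m <- trial_meta(m$subject_id, mass = m$mass, height = m$height,
                       side = if (m$side == "right") "left" else "right",
                       walking_direction = m$walking_direction,
                       up_axis = m$up_axis,
                       fs_kinematics = m$fs_kinematics,
                       fs_kinetics = m$fs_kinetics, gravity = m$gravity)
  d <- trial$data
  for (col in grep("_y$", names(d), value = TRUE)) d[[col]] <- -d[[col]]
  gait_trial(meta_m, d)
}

# Independent 3D moment oracle: KAM about the walking-direction axis at the
# knee, adduction positive, via an explicit cross product.
kam_cross_oracle <- function(cop, kjc, grf, walking_direction, side) {
  r <- cop - kjc
  m3d <- c(r[2] * grf[3] - r[3] * grf[2],
           r[3] * grf[1] - r[1] * grf[3],
           r[1] * grf[2] - r[2] * grf[1])
  s <- if (side == "right") 1 else -1
  s * sum(m3d * walking_direction)
}
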