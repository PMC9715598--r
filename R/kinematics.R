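#' Per-limb coordinate frame with medial-positive mediolateral axis
#'
#' The frontal-plane moment equations become side-agnostic (knee adduction
#' positive for both limbs) when every mediolateral quantity is expressed
#' medial-positive, i.e. toward the body midline for the limb under study.
#' `limb_frame()` builds that frame from the lab-frame walking direction and
#' vertical axis: for a right limb the medial axis is `up x walking`
#' (subject's left), for a left limb its negation.
#'
#' @param side `"left"` or `"right"`.
#' @param walking_direction,up_axis Lab-frame unit 3-vectors (orthogonal).
#' @return A `limb_frame` list with `ap_axis`, `ml_axis` (medial-positive),
#'   `vertical_axis` and `side`.
#' @examples
#' limb_frame("right")$ml_axis  # +y: medial for the right limb
#' @export
limb_frame <- function(side = c("right", "left"),
                       walking_direction = c(1, 0, 0),
                       up_axis = c(0, 0, 1)) {
  side <- match.arg(side)
  ap <- as_unit3(walking_direction, "walking_direction")
  v <- as_unit3(up_axis, "up_axis")
  if (abs(sum(ap * v)) > 1e-6) {
    abort("walking_direction and up_axis must be orthogonal.",
          class = "kamdecomp_geometry_error")
  }
  left_of_subject <- cross3(v, ap)
  ml <- if (side == "right") left_of_subject else -left_of_subject
  structure(list(ap_axis = ap, ml_axis = ml, vertical_axis = v, side = side),
            class = "limb_frame")
}

#' @rdname limb_frame
#' @param meta A [trial_meta()]; convenience constructor using its axes and side.
#' @export
limb_frame_from_meta <- function(meta) {
  limb_frame(meta$side, meta$walking_direction, meta$up_axis)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project lab-frame vectors onto limb-frame scalars
#'
#' @param vec A 3-vector or an n x 3 matrix / data frame of lab-frame
#'   coordinates (positions in m or forces in N).
#' @param frame A [limb_frame()].
#' @return A tibble with columns `ap` (along walking direction), `ml`
#'   (medial-positive) and `v` (up), one row per input row.
#' @export
to_limb_scalars <- function(vec, frame) {
  m <- vec3_matrix(vec)
  tibble::tibble(
    ap = as.numeric(m %*% frame$ap_axis),
    ml = as.numeric(m %*% frame$ml_axis),
    v = as.numeric(m %*% frame$vertical_axis)
  )
}

vec3_matrix <- function(vec) {
  if (is.null(dim(vec))) {
    matrix(as.numeric(vec), nrow = 1, ncol = 3)
  } else {
    m <- as.matrix(vec)
    stopifnot(ncol(m) == 3)
    m
  }
}

#' Foot progression angle
#'
#' Signed angle between the walking direction and the ground-plane
#' projection of the heel-to-toe foot axis, toe-out positive for either
#' limb (the toe deviating laterally, away from the midline). Range
#' (-90, 90] degrees.
#'
#' @param heel,toe Lab-frame 3-vectors (or n x 3 matrices) of the heel and
#'   toe landmarks, m.
#' @param frame A [limb_frame()].
#' @return FPA in degrees (vector if matrix input).
#' @export
foot_progression_angle <- function(heel, toe, frame) {
  h <- to_limb_scalars(heel, frame)
  t <- to_limb_scalars(toe, frame)
  d_ap <- t$ap - h$ap
  d_ml <- t$ml - h$ml
  if (any(sqrt(d_ap^2 + d_ml^2) < 1e-6)) {
    abort("Degenerate foot axis: heel and toe coincide in the ground plane.",
          class = "kamdecomp_geometry_error")
  }
  # lateral deviation of the toe = negative medial component
  fpa <- rad2deg(atan2(-d_ml, d_ap))
  fpa[fpa <= -90] <- fpa[fpa <= -90] + 180
  fpa[fpa > 90] <- fpa[fpa > 90] - 180
  fpa
}

#' Tibia (shank) inclination angles and shank length
#'
#' Frontal-plane tibia angle (FPTA) is the inclination of the shank's
#' frontal-plane projection from vertical, positive when the knee lies
#' lateral to the ankle (varus). Sagittal-plane tibia angle (SPTA) is the
#' corresponding sagittal projection, positive with the knee anterior to
#' the ankle. Two conventions are offered: `"projection"` (planar
#' projection angles, the default reported to users) and `"consistent"`
#' (angles solved so that the lever arms `l_shank*sin(fpta)` and
#' `l_shank*cos(spta) + ankle_height` reproduce the frontal/vertical joint
#' coordinates exactly); no pair of independent planar angles does both at
#' once in 3D.
#'
#' @param kjc,ajc Knee / ankle joint centres: 3-vectors or n x 3 matrices, m.
#' @param frame A [limb_frame()].
#' @param convention `"projection"` or `"consistent"`.
#' @return A tibble with columns `spta`, `fpta` (deg) and `l_shank` (m).
#' @export
tibia_angles <- function(kjc, ajc, frame, convention = c("projection", "consistent")) {
  convention <- match.arg(convention)
  k <- to_limb_scalars(kjc, frame)
  a <- to_limb_scalars(ajc, frame)
  d_ap <- k$ap - a$ap
  d_ml_lat <- a$ml - k$ml   # positive = knee lateral to ankle (varus)
  d_v <- k$v - a$v
  l_shank <- sqrt(d_ap^2 + (a$ml - k$ml)^2 + d_v^2)
  if (any(l_shank < 0.05)) {
    abort("Near-zero shank length (< 5 cm): knee and ankle centres coincide.",
          class = "kamdecomp_geometry_error")
  }
  if (convention == "projection") {
    spta <- rad2deg(atan2(d_ap, d_v))
    fpta <- rad2deg(atan2(d_ml_lat, d_v))
  } else {
    fpta <- rad2deg(asin(pmin(1, pmax(-1, d_ml_lat / l_shank))))
    spta <- sign(d_ap) * rad2deg(acos(pmin(1, pmax(-1, d_v / l_shank))))
  }
  tibble::tibble(spta = spta, fpta = fpta, l_shank = l_shank)
}

#' Centre of pressure in the foot frame
#'
#' Expresses the ground-projected COP position relative to the ankle joint
#' centre in a foot-fixed frame whose anteroposterior axis is the foot axis
#' (rotated from the walking direction by the foot progression angle about
#' vertical) and whose mediolateral axis is medial-positive. The rotation
#' is exact: `cop_ml_gf = cop_ml_ff*cos(fpa) + cop_ap_ff*sin(-fpa)`, where
#' `cop_ml_gf` is the medial COP offset from the ankle in the limb frame.
#'
#' @param cop,ajc Lab-frame 3-vectors or n x 3 matrices, m.
#' @param fpa Foot progression angle, degrees (toe-out positive).
#' @param frame A [limb_frame()].
#' @return A tibble with columns `cop_ap_ff` (anterior along foot axis, m)
#'   and `cop_ml_ff` (medial of the foot axis, m).
#' @export
cop_in_foot_frame <- function(cop, ajc, fpa, frame) {
  cp <- to_limb_scalars(cop, frame)
  an <- to_limb_scalars(ajc, frame)
  d_ap <- cp$ap - an$ap
  d_ml <- cp$ml - an$ml
  # foot-frame axes in limb coordinates: toe-out rotates the foot axis laterally
  tibble::tibble(
    cop_ap_ff = d_ap * cosd(fpa) - d_ml * sind(fpa),
    cop_ml_ff = d_ap * sind(fpa) + d_ml * cosd(fpa)
  )
}

#' Per-sample limb-frame geometry over stance
#'
#' Assembles, for every stance sample, the scalar quantities the moment
#' decomposition consumes: limb-frame GRF components, joint-centre
#' coordinates, COP offsets in the global and foot frames, shank length and
#' tibia angles, and the foot progression angle. The FPA is evaluated once,
#' at the midstance sample (50\% of stance), and applied to the whole
#' stance, matching its definition as a per-step foot placement angle.
#'
#' The limb-frame vertical coordinate is treated as height above the ground
#' plane, so the lab origin must lie on the ground (the COP invariant of
#' [gait_trial()] enforces this for loaded samples).
#'
#' @param trial A [gait_trial()] (already at a common sampling rate).
#' @param segment A [detect_stance()] stance segment.
#' @param frame Optional [limb_frame()]; defaults to the trial metadata.
#' @param convention Tibia-angle convention, see [tibia_angles()].
#' @return A tibble, one row per stance sample, with columns `time`,
#'   `grf_ap`, `grf_ml`, `grf_v`, `kjc_ml`, `kjc_v`, `ajc_ml`, `ajc_v`,
#'   `cop_ml`, `cop_ap_ff`, `cop_ml_ff`, `fpa`, `l_shank`, `spta`, `fpta`,
#'   `ankle_height`.
#' @export
build_frame_geometry <- function(trial, segment, frame = NULL,
                                 convention = c("projection", "consistent")) {
  convention <- match.arg(convention)
  frame <- frame %||% limb_frame_from_meta(trial$meta)
  d <- trial$data
  n <- nrow(d)
  if (segment$start < 1 || segment$end > n + 1L || segment$end - segment$start < 2L) {
    abort("Stance segment must contain at least 2 samples inside the trial.",
          class = "kamdecomp_parameter_error")
  }
  idx <- seq(segment$start, segment$end - 1L)
  pick <- function(role) as.matrix(d[idx, paste(role, c("x", "y", "z"), sep = "_")])

  grf <- to_limb_scalars(pick("grf"), frame)
  kjc <- to_limb_scalars(pick("kjc"), frame)
  ajc <- to_limb_scalars(pick("ajc"), frame)
  cop <- to_limb_scalars(pick("cop"), frame)

  mid <- idx[1L + floor(0.5 * (length(idx) - 1L))]
  fpa <- foot_progression_angle(
    as.numeric(d[mid, paste("heel", c("x", "y", "z"), sep = "_")]),
    as.numeric(d[mid, paste("toe", c("x", "y", "z"), sep = "_")]),
    frame
  )

  ang <- tibia_angles(pick("kjc"), pick("ajc"), frame, convention = convention)
  ff <- cop_in_foot_frame(pick("cop"), pick("ajc"), fpa, frame)

  geom <- tibble::tibble(
    time = d$time[idx],
    grf_ap = grf$ap, grf_ml = grf$ml, grf_v = grf$v,
    kjc_ml = kjc$ml, kjc_v = kjc$v,
    ajc_ml = ajc$ml, ajc_v = ajc$v,
    cop_ml = cop$ml,
    cop_ap_ff = ff$cop_ap_ff, cop_ml_ff = ff$cop_ml_ff,
    fpa = fpa,
    l_shank = ang$l_shank, spta = ang$spta, fpta = ang$fpta,
    ankle_height = ajc$v
  )
  if (any(geom$ankle_height < -1e-6)) {
    abort("Ankle joint centre below the ground plane.",
          class = "kamdecomp_geometry_error")
  }
  geom
}
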