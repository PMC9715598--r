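geom_row <- function(grf_ml = 0, grf_v = 700, kjc_ml = 0, kjc_v = 0.5,
                     ajc_ml = 0, ajc_v = 0.08, cop_ml = 0, cop_ap_ff = 0,
                     cop_ml_ff = 0, fpa = 0, l_shank = 0.42, spta = 0,
                     fpta = 0, ankle_height = 0.08) {
  tibble::tibble(grf_ml = grf_ml, grf_v = grf_v, kjc_ml = kjc_ml,
                 kjc_v = kjc_v, ajc_ml = ajc_ml, ajc_v = ajc_v,
                 cop_ml = cop_ml, cop_ap_ff = cop_ap_ff,
                 cop_ml_ff = cop_ml_ff, fpa = fpa, l_shank = l_shank,
                 spta = spta, fpta = fpta, ankle_height = ankle_height)
}

test_that("the GRV moment matches the 3D cross-product oracle", {
  expect_equal(grv_kam(geom_row(grf_v = 700, cop_ml = 0.03)), 21.0)
  expect_equal(grv_kam(geom_row(grf_v = 700, cop_ml = 0)), 0)
  expect_equal(grv_kam(geom_row(grf_ml = 30, grf_v = 0, kjc_v = 0.5)), 15.0)

  set.seed(12)
  for (i in 1:50) {
    side <- sample(c("left", "right"), 1)
    yaw <- runif(1, 0, 2 * pi)
    wd <- c(cos(yaw), sin(yaw), 0)
    fr <- limb_frame(side, walking_direction = wd)
    meta <- trial_meta("x", mass = 70, height = 1.7, side = side,
                       walking_direction = wd)
    cop <- c(rnorm(2, sd = 0.3), 0)
    kjc <- c(rnorm(2, sd = 0.3), runif(1, 0.3, 0.7))
    grf <- c(rnorm(2, sd = 60), runif(1, 100, 900))
    g <- tibble::tibble(
      grf_ml = to_limb_scalars(grf, fr)$ml,
      grf_v = to_limb_scalars(grf, fr)$v,
      kjc_ml = to_limb_scalars(kjc, fr)$ml,
      kjc_v = to_limb_scalars(kjc, fr)$v,
      cop_ml = to_limb_scalars(cop, fr)$ml
    )
    expect_equal(grv_kam(g), kam_cross_oracle(cop, kjc, grf, wd, side),
                 tolerance = 1e-10)
  }
})

test_that("the four components evaluate the stated lever arms and sum to the GRV moment", {
  # worked example: all lever arms active except M1/M4
  g <- geom_row(grf_v = 700, kjc_ml = -0.03, ajc_ml = 0, cop_ap_ff = 0.10,
                cop_ml_ff = 0.01, cop_ml = 0.01)
  d <- decompose_sample(g)
  expect_equal(d$m1, 0)
  expect_equal(d$m2, 21.0)
  expect_equal(d$m3, 7.0)
  expect_equal(d$m4, 0)
  expect_equal(d$total, 28.0)
  expect_equal(d$total, grv_kam(g), tolerance = 1e-9)

  # fpa = 0 kills M4 regardless of COP
  expect_equal(decompose_sample(geom_row(cop_ap_ff = 0.2, cop_ml_ff = 0.05,
                                         cop_ml = 0.05))$m4, 0)
  # vertical shank and COP on the foot axis kill M2 and M3
  z <- decompose_sample(geom_row(cop_ap_ff = 0.1, fpa = 10,
                                 cop_ml = 0.1 * sin(-10 * pi / 180)))
  expect_equal(z$m2, 0)
  expect_equal(z$m3, 0)

  # angle mode reproduces the trigonometric lever arm
  ga <- geom_row(grf_v = 700, l_shank = 0.4, fpta = 5)
  expect_equal(decompose_sample(ga, mode = "angle")$m2,
               700 * 0.4 * sin(5 * pi / 180), tolerance = 1e-12)
  expect_equal(round(decompose_sample(ga, mode = "angle")$m2, 1), 24.4)
})

test_that("moment normalisation applies the %Bw*Ht scaling law", {
  meta <- trial_meta("S01", mass = 77.3, height = 1.775, side = "right")
  expect_equal(normalize_moment(0, meta), 0)
  expect_equal(normalize_moment(28, meta),
               28 / (77.3 * 9.81 * 1.775) * 100, tolerance = 1e-12)
  expect_equal(round(normalize_moment(28, meta), 2), 2.08)
  heavy <- trial_meta("S01", mass = 2 * 77.3, height = 1.775, side = "right")
  expect_equal(normalize_moment(28, heavy), normalize_moment(28, meta) / 2)
})

test_that("component sum equals the GRV moment on randomized geometry", {
  g <- random_geometry(1000, seed = 42)
  d <- decompose_sample(g)
  expect_lt(max(abs(d$m1 + d$m2 + d$m3 + d$m4 - grv_kam(g))), 1e-9)
})

test_that("component signs follow their biomechanical semantics", {
  # toe-out with anterior COP -> abducting M4
  grid1 <- tidyr::expand_grid(fpa = seq(2, 30, length.out = 10),
                              cop_ap_ff = seq(0.01, 0.2, length.out = 10))
  m4 <- decompose_sample(geom_row(fpa = grid1$fpa, cop_ap_ff = grid1$cop_ap_ff,
                                  cop_ml = -sin(grid1$fpa * pi / 180) *
                                    grid1$cop_ap_ff))$m4
  expect_true(all(m4 < 0))

  # COP lateral to the foot axis -> abducting M3
  grid2 <- tidyr::expand_grid(fpa = seq(-20, 20, length.out = 10),
                              cop_ml_ff = seq(-0.05, -0.002, length.out = 10))
  m3 <- decompose_sample(geom_row(fpa = grid2$fpa, cop_ml_ff = grid2$cop_ml_ff,
                                  cop_ml = grid2$cop_ml_ff *
                                    cos(grid2$fpa * pi / 180)))$m3
  expect_true(all(m3 < 0))

  # knee lateral to the ankle -> adducting M2
  off <- seq(0.002, 0.08, length.out = 100)
  m2 <- decompose_sample(geom_row(kjc_ml = -off, ajc_ml = 0))$m2
  expect_true(all(m2 > 0))

  # medially directed GRF -> adducting M1
  m1 <- decompose_sample(geom_row(grf_ml = seq(1, 80, length.out = 100)))$m1
  expect_true(all(m1 > 0))
})

test_that("the total is invariant to where the foot frame splits M3 and M4", {
  set.seed(21)
  ajc <- c(0, 0, 0.08)
  fr <- limb_frame("right")
  for (i in 1:25) {
    cop <- c(runif(1, -0.05, 0.2), runif(1, -0.05, 0.05), 0)
    fpa <- runif(1, -25, 25)
    delta <- runif(1, -20, 20)
    part <- function(angle) {
      ff <- cop_in_foot_frame(cop, ajc, angle, fr)
      700 * ff$cop_ml_ff * cos(angle * pi / 180) +
        700 * ff$cop_ap_ff * sin(-angle * pi / 180)
    }
    expect_equal(part(fpa), part(fpa + delta), tolerance = 1e-9)
  }
})

test_that("the pipeline recovers generator ground truth and mirrors sides", {
  sim <- simulate_trial(sim_config(fpa = 9, fpta = 3.5))
  dec <- decompose_trial(sim$trial, filter = FALSE)
  err <- as.matrix(dec$profiles[c("m1", "m2", "m3", "m4", "dgrv_total")]) -
    as.matrix(sim$ground_truth[c("m1", "m2", "m3", "m4", "dgrv_total")])
  peak <- max(abs(sim$ground_truth$dgrv_total))
  expect_lt(sqrt(mean((err / peak)^2)), 0.01)

  # fpa = 0 throughout -> M4 identically zero
  sim0 <- simulate_trial(sim_config(fpa = 0))
  dec0 <- decompose_trial(sim0$trial, filter = FALSE)
  expect_equal(max(abs(dec0$profiles$m4)), 0, tolerance = 1e-12)

  # left/right mirror-image trials give identical decompositions
  dec_m <- decompose_trial(mirror_trial(sim$trial), filter = FALSE)
  expect_equal(as.matrix(dec$profiles), as.matrix(dec_m$profiles),
               tolerance = 1e-12)
  expect_lt(dec$residual_max, 1e-9)
})

test_that("angle mode tracks coordinate mode closely on gait-like geometry", {
  worst <- 0
  for (fpta in c(-5, 2, 10)) {
    for (fpa in c(-15, 5, 30)) {
      sim <- simulate_trial(sim_config(fpa = fpa, fpta = fpta, osc_amp = 0))
      dc <- decompose_trial(sim$trial, filter = FALSE, mode = "coordinate")
      da <- decompose_trial(sim$trial, filter = FALSE, mode = "angle")
      disc <- max(abs(da$profiles$dgrv_total - dc$profiles$dgrv_total)) /
        max(abs(dc$profiles$dgrv_total))
      worst <- max(worst, disc)
    }
  }
  expect_lt(worst, 0.02)
})

test_that("tidy and glance expose profiles and features", {
  sim <- simulate_trial(sim_config())
  dec <- decompose_trial(sim$trial, filter = FALSE)
  long <- generics::tidy(dec)
  expect_setequal(unique(long$component),
                  c("m1", "m2", "m3", "m4", "dgrv_total"))
  expect_equal(nrow(long), 101 * 5)
  g <- generics::glance(dec)
  expect_equal(g$first_peak, max(dec$profiles$dgrv_total[dec$profiles$stance_pct <= 50]))
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
})
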