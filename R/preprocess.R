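#' Zero-phase Butterworth low-pass filter
#'
#' Gait kinetics and kinematics are conventionally smoothed with a 4th-order
#' Butterworth low-pass at 8 Hz applied forward and backward (zero phase),
#' so peak timing is not shifted. The double pass squares the magnitude
#' response; the cutoff is left at its nominal value rather than corrected
#' for the second pass.
#'
#' @param series Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (default 8).
#' @param order Filter order of a single pass (default 4).
#' @param zero_phase Apply forward-backward (default `TRUE`); `FALSE` gives
#'   a single causal pass.
#' @return Filtered series, same length; DC gain 1.
#' @export
lowpass_filter <- function(series, fs, cutoff = 8, order = 4, zero_phase = TRUE) {
  if (!is.numeric(fs) || fs <= 0) {
    abort("`fs` must be positive.", class = "kamdecomp_parameter_error")
  }
  if (cutoff >= fs / 2) {
    abort("`cutoff` must be below the Nyquist frequency fs/2.",
          class = "kamdecomp_parameter_error")
  }
  if (length(series) <= 3 * order) {
    abort("Series too short for the requested filter order.",
          class = "kamdecomp_parameter_error")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # single pass started in steady state at the first sample (no step transient)
  one_pass <- function(x) {
    k <- length(bf$a) - 1L
    as.numeric(signal::filter(bf$b, bf$a, x,
                              init.x = rep(x[1], k), init.y = rep(x[1], k)))
  }
  if (zero_phase) {
    # reflect-pad so the backward pass also settles before the data start
    n <- length(series)
    pad <- min(n - 1L, max(3L * order, 50L))
    ext <- c(2 * series[1] - series[(pad + 1):2],
             series,
             2 * series[n] - series[(n - 1):(n - pad)])
    out <- rev(one_pass(rev(one_pass(ext))))
    out[(pad + 1):(pad + n)]
  } else {
    one_pass(series)
  }
}

#' Resample a series to a lower rate
#'
#' Aligns kinetics (e.g. 1000 Hz force plate) with kinematics (e.g. 100 Hz
#' cameras). The default path requires an integer rate ratio and low-pass
#' filters below the output Nyquist before subsampling to prevent aliasing;
#' non-integer ratios must explicitly request linear interpolation.
#'
#' @param series Numeric vector sampled at `fs_in`.
#' @param fs_in,fs_out Input / output rates, Hz, with `fs_in >= fs_out`.
#' @param method `"decimate"` (default, integer ratios only) or `"interp"`.
#' @return Series at `fs_out`.
#' @export
resample_to <- function(series, fs_in, fs_out, method = c("decimate", "interp")) {
  method <- match.arg(method)
  if (fs_in < fs_out) {
    abort("`fs_in` must be >= `fs_out`.", class = "kamdecomp_parameter_error")
  }
  if (fs_in == fs_out) return(series)
  ratio <- fs_in / fs_out
  if (method == "decimate") {
    if (abs(ratio - round(ratio)) > 1e-9) {
      abort("fs_in / fs_out is not an integer; request method = \"interp\" explicitly.",
            class = "kamdecomp_parameter_error")
    }
    q <- as.integer(round(ratio))
    filtered <- lowpass_filter(series, fs_in, cutoff = 0.8 * fs_out / 2, order = 8)
    filtered[seq(1L, length(series), by = q)]
  } else {
    t_in <- (seq_along(series) - 1) / fs_in
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
    approx(t_in, series, xout = t_out)$y
  }
}

#' Detect the stance phase from vertical ground reaction force
#'
#' Stance is taken as the longest contiguous run of samples with vertical
#' GRF at or above a contact threshold (default 20 N, a conventional
#' force-plate contact level). Indices are 1-based and half-open:
#' `[start, end)`, so the last stance sample is `end - 1`.
#'
#' @param grf_vertical Vertical GRF, N.
#' @param fs Sampling rate, Hz.
#' @param threshold Contact threshold, N (default 20).
#' @return A `stance_segment` list with `start`, `end` (half-open), `fs`
#'   and `duration` (s).
#' @export
detect_stance <- function(grf_vertical, fs, threshold = 20) {
  above <- is.finite(grf_vertical) & grf_vertical >= threshold
  if (!any(above)) {
    abort("No samples reach the contact threshold; no stance detected.",
          class = "kamdecomp_detection_error")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= 3L)
  if (length(cand) == 0) {
    abort("No contact run of at least 3 samples; no stance detected.",
          class = "kamdecomp_detection_error")
  }
  best <- cand[which.max(r$lengths[cand])]
  structure(
    list(start = starts[best], end = ends[best] + 1L, fs = fs,
         duration = (ends[best] + 1L - starts[best] - 1L) / fs),
    class = "stance_segment"
  )
}

#' @export
print.stance_segment <- function(x, ...) {
  cat(sprintf("<stance_segment> samples [%d, %d) @ %g Hz (%.3f s)\n",
              x$start, x$end, x$fs, x$duration))
  invisible(x)
}

#' Time-normalise a profile over stance
#'
#' Linearly interpolates the samples of a stance segment onto `n_points`
#' equally spaced stations spanning 0-100\% of stance. Endpoints are
#' preserved and affine profiles are reproduced exactly.
#'
#' @param profile Numeric vector covering at least the stance segment.
#' @param segment A [detect_stance()] result (or a list with `start`,
#'   `end`).
#' @param n_points Number of output stations (default 101, i.e. every 1\%).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(profile, segment, n_points = 101) {
  if (n_points < 2) {
    abort("`n_points` must be at least 2.", class = "kamdecomp_parameter_error")
  }
  s <- segment$start
  e <- segment$end
  if (is.null(s) || is.null(e) || s < 1 || e > length(profile) + 1L || e - s < 2L) {
    abort("Stance segment does not fit inside the profile.",
          class = "kamdecomp_index_error")
  }
  idx <- seq(s, e - 1L, length.out = n_points)
  approx(seq_along(profile), profile, xout = idx)$y
}

#' Stance-percent axis matching [time_normalize()]
#' @param n_points Number of stations.
#' @return Numeric vector from 0 to 100.
#' @export
stance_axis <- function(n_points = 101) seq(0, 100, length.out = n_points)
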