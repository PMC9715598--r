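#' Extract KAM stance features
#'
#' The three standard KAM descriptors: the first peak (maximum over the
#' first half of stance, the station at exactly 50\% belonging to the first
#' half), the second peak (maximum over the remainder), and the angular
#' impulse (trapezoidal time integral of the full signed profile over
#' stance, so abduction excursions subtract; set `positive_only = TRUE` to
#' integrate only the adduction part).
#'
#' @param profile Stance-normalised KAM profile (\%Bw*Ht), length >= 4.
#' @param stance_duration Stance time in s.
#' @param positive_only Integrate only positive values (default `FALSE`).
#' @return A one-row tibble: `first_peak`, `second_peak` (\%Bw*Ht),
#'   `impulse` (\%Bw*Ht·s), `stance_duration` (s).
#' @examples
#' extract_features(sin(pi * seq(0, 1, length.out = 101)), 1)
#' @export
extract_features <- function(profile, stance_duration, positive_only = FALSE) {
  if (length(profile) < 4) {
    abort("Profile must have at least 4 stations.", class = "kamdecomp_data_error")
  }
  if (any(!is.finite(profile))) {
    abort("Profile contains non-finite values.", class = "kamdecomp_data_error")
  }
  if (!is.numeric(stance_duration) || stance_duration <= 0) {
    abort("`stance_duration` must be positive.", class = "kamdecomp_data_error")
  }
  pct <- stance_axis(length(profile))
  first_half <- pct <= 50
  y <- if (positive_only) pmax(profile, 0) else profile
  t_real <- pct / 100 * stance_duration
  impulse <- sum(diff(t_real) * (head(y, -1) + tail(y, -1)) / 2)
  tibble::tibble(
    first_peak = max(profile[first_half]),
    second_peak = max(profile[!first_half]),
    impulse = impulse,
    stance_duration = stance_duration
  )
}

#' Inter-protocol coefficient of multiple correlation
#'
#' Waveform-similarity statistic between P protocols (e.g. two KAM
#' estimation methods) measured over G gait cycles of F stance stations,
#' formulated so that between-cycle variability does not inflate the
#' agreement. With `Y[g,p,f]` the profile value of cycle g, protocol p,
#' station f, `Ybar[g,f]` the across-protocol mean and `Ybar[g]` the grand
#' mean of cycle g:
#' \deqn{CMC = \sqrt{1 - \frac{\sum (Y_{gpf}-\bar Y_{gf})^2 / (G F (P-1))}
#'                        {\sum (Y_{gpf}-\bar Y_{g})^2 / (G (P F - 1))}}}
#' When the within-cycle mean square exceeds the total (ratio > 1) or the
#' denominator is zero (flat profiles) the statistic is undefined and
#' `NA` is returned (never clamped to 0).
#'
#' @param profiles Either a 3-D array `[cycle, protocol, station]` or a
#'   long data frame with columns `cycle`, `protocol`, `station`, `value`.
#' @return The CMC in `[0, 1]`, or `NA` when undefined.
#' @export
cmc_inter_protocol <- function(profiles) {
  y <- if (is.array(profiles) && length(dim(profiles)) == 3) {
    profiles
  } else if (is.data.frame(profiles)) {
    needed <- c("cycle", "protocol", "station", "value")
    if (!all(needed %in% names(profiles))) {
      abort("Long input needs columns cycle, protocol, station, value.",
            class = "kamdecomp_data_error")
    }
    df <- profiles
    cyc <- sort(unique(df$cycle))
    pro <- sort(unique(df$protocol))
    sta <- sort(unique(df$station))
    arr <- array(NA_real_, dim = c(length(cyc), length(pro), length(sta)))
    arr[cbind(match(df$cycle, cyc), match(df$protocol, pro),
              match(df$station, sta))] <- df$value
    arr
  } else {
    abort("`profiles` must be a [cycle, protocol, station] array or long data frame.",
          class = "kamdecomp_data_error")
  }
  if (any(!is.finite(y))) {
    abort("Profiles contain missing or non-finite values.",
          class = "kamdecomp_data_error")
  }
  G <- dim(y)[1]; P <- dim(y)[2]; F_ <- dim(y)[3]
  if (P < 2 || F_ < 2 || G < 1) {
    abort("Need at least 2 protocols, 2 stations and 1 cycle.",
          class = "kamdecomp_data_error")
  }
  ybar_gf <- apply(y, c(1, 3), mean)             # across-protocol mean
  ybar_g <- apply(y, 1, mean)                    # grand mean per cycle
  ybar_gf_full <- aperm(array(ybar_gf, dim = c(G, F_, P)), c(1, 3, 2))
  num <- sum((y - ybar_gf_full)^2) / (G * F_ * (P - 1))
  den <- sum((y - array(ybar_g, dim = c(G, P, F_)))^2) / (G * (P * F_ - 1))
  if (den <= 0) return(NA_real_)
  ratio <- num / den
  if (ratio > 1) return(NA_real_)
  sqrt(1 - ratio)
}

#' Bland-Altman agreement between two feature sets
#'
#' Computes the mean difference (bias), standard deviation of differences
#' (precision, n-1 denominator), 95\% limits of agreement
#' `bias +/- 1.96 * precision` (normal quantile), and t-based confidence
#' intervals: `t * precision / sqrt(n)` for the bias and
#' `t * precision * sqrt(3/n)` for each limit.
#'
#' @param a,b Paired feature vectors of equal length `n >= 3`; differences
#'   are `a - b`.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return A `kam_agreement` object with fields `bias`, `precision`,
#'   `loa_low`, `loa_high`, `ci_bias`, `ci_loa_low`, `ci_loa_high`, `n`,
#'   plus the per-pair `differences` and `means`.
#' @examples
#' bland_altman(c(1.1, 1.2, 1.3), c(1.0, 1.0, 1.0))
#' @export
bland_altman <- function(a, b, conf = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length.", class = "kamdecomp_data_error")
  }
  n <- length(a)
  if (n < 3) {
    abort("Bland-Altman needs at least 3 pairs.",
          class = "kamdecomp_sample_size_error")
  }
  d <- a - b
  bias <- mean(d)
  precision <- sd(d)
  loa_low <- bias - 1.96 * precision
  loa_high <- bias + 1.96 * precision
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  half_bias <- tq * precision / sqrt(n)
  half_loa <- tq * precision * sqrt(3 / n)
  structure(
    list(
      bias = bias, precision = precision,
      loa_low = loa_low, loa_high = loa_high,
      ci_bias = c(bias - half_bias, bias + half_bias),
      ci_loa_low = c(loa_low - half_loa, loa_low + half_loa),
      ci_loa_high = c(loa_high - half_loa, loa_high + half_loa),
      n = n,
      differences = d,
      means = (a + b) / 2,
      conf = conf
    ),
    class = "kam_agreement"
  )
}

#' @export
print.kam_agreement <- function(x, ...) {
  cat(sprintf(
    "<kam_agreement> n = %d: bias %.4f [%.4f, %.4f], precision %.4f, LOA [%.4f, %.4f]\n",
    x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$precision, x$loa_low, x$loa_high))
  invisible(x)
}

#' @describeIn bland_altman Per-pair means and differences (for plotting).
#' @param x A `kam_agreement`.
#' @param ... Unused.
#' @method tidy kam_agreement
#' @export
tidy.kam_agreement <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$differences)
}

#' @describeIn bland_altman One-row summary of bias, precision, limits and
#'   their confidence intervals.
#' @method glance kam_agreement
#' @export
glance.kam_agreement <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, precision = x$precision,
    loa_low = x$loa_low, loa_high = x$loa_high,
    ci_bias_low = x$ci_bias[1], ci_bias_high = x$ci_bias[2],
    ci_loa_low_low = x$ci_loa_low[1], ci_loa_low_high = x$ci_loa_low[2],
    ci_loa_high_low = x$ci_loa_high[1], ci_loa_high_high = x$ci_loa_high[2],
    n = x$n
  )
}

#' @describeIn bland_altman Bland-Altman plot: pair means vs differences,
#'   bias and limits of agreement with confidence bands.
#' @param object A `kam_agreement`.
#' @method autoplot kam_agreement
#' @export
autoplot.kam_agreement <- function(object, ...) {
  pts <- tidy(object)
  lines <- tibble::tibble(
    level = c("bias", "LOA low", "LOA high"),
    y = c(object$bias, object$loa_low, object$loa_high),
    lo = c(object$ci_bias[1], object$ci_loa_low[1], object$ci_loa_high[1]),
    hi = c(object$ci_bias[2], object$ci_loa_low[2], object$ci_loa_high[2])
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_rect(
      data = lines,
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      xmin = -Inf, xmax = Inf, fill = "grey80", alpha = 0.5,
      inherit.aes = FALSE) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$level),
                        colour = c("black", "red", "red")) +
    ggplot2::geom_point() +
    ggplot2::scale_linetype_manual(
      values = c(bias = "solid", `LOA low` = "dotted", `LOA high` = "dotted")) +
    ggplot2::labs(x = "Mean of methods", y = "Difference", linetype = NULL) +
    ggplot2::theme_minimal()
}
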