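#' Linear least-squares fit of the signal channel on the control channel
#'
#' Ordinary least squares of the excitation signal on the isosbestic control
#' over a fitting window; the fitted control \code{slope * control +
#' intercept} is evaluated over the whole recording and is what the
#' preprocessing variants subtract from (or divide into) the signal.
#'
#' @param control control-channel values.
#' @param signal signal-channel values.
#' @param window length-2 vector in the units of \code{t} (seconds when
#'   \code{t} is given, sample indices otherwise); NULL fits the whole
#'   recording.
#' @param t optional time vector.
#' @return list of class \code{lls_fit}: \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{window} (NULL means whole session),
#'   \code{fitted} (full-length fitted control).
#' @export
fit_lls <- function(control, signal, window = NULL, t = NULL) {
  stopifnot(length(control) == length(signal))
  if (is.null(t)) t <- seq_along(control)
  idx <- if (is.null(window)) seq_along(control) else window_idx(t, window)
  if (length(idx) < 2) stop("fitting window must hold at least 2 samples")
  if (stats::sd(control[idx]) == 0)
    stop("control channel is constant over the fitting window (singular design)")
  fit <- stats::lm(signal[idx] ~ control[idx])
  cf <- stats::coef(fit)
  tss <- sum((signal[idx] - mean(signal[idx]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, window = window,
                 fitted = unname(cf[1]) + unname(cf[2]) * control),
            class = "lls_fit")
}

#' @export
print.lls_fit <- function(x, ...) {
  cat(sprintf("LLS fit (%s): slope = %.4g, intercept = %.4g, R^2 = %.4f\n",
              if (is.null(x$window)) "whole session" else
                sprintf("window %.0f-%.0f", x$window[1], x$window[2]),
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Power-like photobleaching baseline fit
#'
#' Fits the slowly decaying baseline \eqn{F_0(t) = a (t + t_0)^{-b} + c}
#' (a, b, t0 > 0) to a 1 Hz trace over the baseline window by nonlinear
#' least squares and extrapolates it over the full trace. The fit is
#' declared unsuccessful — so the caller should substitute the median of the
#' baseline window — when the optimizer fails, the fitted exponent collapses
#' to zero, or the fitted curve shows no appreciable decay (relative decline
#' below 0.1\% across the window), which covers flat and monotone-increasing
#' traces.
#'
#' @param trace fluorescence series (typically 1 Hz).
#' @param baseline_window length-2 vector in the units of \code{t}.
#' @param t optional time vector (defaults to sample index).
#' @return list of class \code{powerlike_fit}: \code{baseline} (full-length
#'   curve, or the baseline-window median replicated when unsuccessful),
#'   \code{coefficients}, \code{success}.
#' @export
fit_powerlike_baseline <- function(trace, baseline_window, t = NULL) {
  if (is.null(t)) t <- seq_along(trace)
  idx <- window_idx(t, baseline_window)
  if (length(idx) < 30)
    stop("baseline window must hold at least 30 samples")
  med <- stats::median(trace[idx])
  fallback <- structure(list(baseline = rep(med, length(trace)),
                             coefficients = NULL, success = FALSE),
                        class = "powerlike_fit")
  df <- data.frame(tt = t[idx] - t[idx[1]] + 1, y = trace[idx])
  amp <- max(df$y) - min(df$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (tt + t0)^(-b) + c0, data = df,
                      start = list(a = max(amp, 1e-6), b = 0.3, t0 = 10,
                                   c0 = min(df$y)),
                      lower = c(1e-12, 1e-9, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  cf <- stats::coef(fit)
  curve_win <- cf[["a"]] * (df$tt + cf[["t0"]])^(-cf[["b"]]) + cf[["c0"]]
  # "no decay": fitted decline must stand clear of the residual noise and
  # be a non-trivial fraction of the baseline level
  decline <- curve_win[1] - curve_win[length(curve_win)]
  resid_sd <- stats::sd(df$y - curve_win)
  if (cf[["b"]] <= 1e-6 ||
      decline < max(3 * resid_sd,
                    1e-3 * max(abs(curve_win[1]), .Machine$double.eps)))
    return(fallback)
  full <- cf[["a"]] * (t - t[idx[1]] + 1 + cf[["t0"]])^(-cf[["b"]]) +
    cf[["c0"]]
  structure(list(baseline = full, coefficients = cf, success = TRUE),
            class = "powerlike_fit")
}

# Block-average samples sharing the same integer second; robust to
# non-integer acquisition rates (e.g. 1017.25 Hz).
downsample_to_1hz <- function(t, x) {
  sec <- floor(t)
  list(t = as.numeric(sort(unique(sec))),
       x = as.numeric(tapply(x, sec, mean)))
}

#' Power-like baseline dF/F photometry preprocessing
#'
#' Slice/pharmacology-style pipeline: each channel is block-averaged to
#' 1 Hz, the first and last \code{trim_s} seconds are removed, a power-like
#' photobleaching baseline \eqn{F_0(t)} is fitted on the pre-event baseline
#' period (median of the baseline period substituted when no decay can be
#' fitted), the channel is converted to \eqn{\Delta F_t / F_0(t)}, and the
#' control-channel dF/F0 is subtracted from the signal-channel dF/F0.
#'
#' @param rec a \code{\link{two_channel_recording}} whose events mark the
#'   baseline (pre-injection) period, or \code{baseline_s} given explicitly.
#' @param trim_s seconds trimmed from each end after downsampling.
#' @param baseline_s end of the baseline period (s); defaults to the onset
#'   of the first event in \code{rec$events}.
#' @return a \code{\link{processed_trace}} (variant \code{"arc"}, unit
#'   \code{"dff"}) at 1 Hz.
#' @export
preprocess_arc <- function(rec, trim_s = 1, baseline_s = NULL) {
  stopifnot(inherits(rec, "two_channel_recording"))
  if (is.null(baseline_s)) {
    if (is.null(rec$events) || nrow(rec$events$events) == 0)
      stop("no baseline marker: supply baseline_s or a recording with events")
    baseline_s <- rec$events$events$time_s[1]
  }
  if (length(rec$t) / rec$rate <= 2 * trim_s)
    stop("recording shorter than 2 * trim_s")
  ds_s <- downsample_to_1hz(rec$t, rec$signal)
  ds_c <- downsample_to_1hz(rec$t, rec$control)
  keep <- ds_s$t >= (min(ds_s$t) + trim_s) & ds_s$t <= (max(ds_s$t) - trim_s)
  t1 <- ds_s$t[keep]
  bw <- c(t1[1], baseline_s)
  chan <- lapply(list(signal = ds_s$x[keep], control = ds_c$x[keep]),
                 function(y) {
    pf <- fit_powerlike_baseline(y, bw, t = t1)
    list(dff = (y - pf$baseline) / pf$baseline, success = pf$success)
  })
  value <- chan$signal$dff - chan$control$dff
  processed_trace(
    t1, value, variant = "arc", unit = "dff", baseline_window = bw,
    provenance = list(
      list(step = "preprocess_arc",
           params = list(trim_s = trim_s, baseline_s = baseline_s)),
      list(step = "downsample_1hz", params = list()),
      list(step = "trim", params = list(trim_s = trim_s)),
      list(step = "powerlike_baseline_dff",
           params = list(baseline_window = bw,
                         signal_fit = chan$signal$success,
                         control_fit = chan$control$success)),
      list(step = "subtract_control_dff", params = list())))
}

#' Baseline-window isosbestic regression with z-scoring
#'
#' Pharmacology/chemogenetics-style pipeline: the control channel is
#' regressed onto the signal over the pre-injection baseline period, the
#' fitted control is subtracted from the signal (removing bleaching and
#' movement artifacts), the corrected trace is block-mean downsampled by
#' \code{down} (default 300), smoothed with a centered rolling mean over
#' \code{smooth_s} (default 10 s) and z-scored against the mean and SD of
#' the processed trace over the baseline period.
#'
#' @param rec a \code{\link{two_channel_recording}}.
#' @param baseline_window length-2 vector (s); defaults to recording start
#'   up to the first event onset.
#' @param down integer downsampling factor.
#' @param smooth_s rolling-mean window (s).
#' @return a \code{\link{processed_trace}} (variant \code{"baseline_lls"},
#'   unit \code{"zscore"}).
#' @export
preprocess_baseline_lls <- function(rec, baseline_window = NULL, down = 300,
                                    smooth_s = 10) {
  stopifnot(inherits(rec, "two_channel_recording"))
  if (is.null(baseline_window)) {
    if (is.null(rec$events) || nrow(rec$events$events) == 0)
      stop("no baseline marker: supply baseline_window or events")
    baseline_window <- c(rec$t[1], rec$events$events$time_s[1])
  }
  if (diff(baseline_window) * rec$rate < 2)
    stop("baseline window too short for the LLS fit")
  lls <- fit_lls(rec$control, rec$signal, window = baseline_window,
                 t = rec$t)
  corr <- rec$signal - lls$fitted
  t_ds <- downsample_block(rec$t, down)
  v <- downsample_block(corr, down)
  new_rate <- rec$rate / down
  v <- rolling_mean(v, round(smooth_s * new_rate))
  bidx <- window_idx(t_ds, baseline_window)
  mu <- mean(v[bidx]); sdv <- stats::sd(v[bidx])
  if (!is.finite(sdv) || sdv == 0)
    stop("baseline SD is zero; cannot z-score")
  z <- (v - mu) / sdv
  processed_trace(
    t_ds, z, variant = "baseline_lls", unit = "zscore",
    baseline_window = baseline_window,
    provenance = list(
      list(step = "preprocess_baseline_lls",
           params = list(baseline_window = baseline_window, down = down,
                         smooth_s = smooth_s)),
      list(step = "lls_subtract",
           params = list(slope = lls$slope, intercept = lls$intercept)),
      list(step = "downsample", params = list(factor = down)),
      list(step = "rolling_smooth", params = list(smooth_s = smooth_s)),
      list(step = "zscore_baseline",
           params = list(mean = mu, sd = sdv))))
}

#' Whole-session polynomial detrend and isosbestic division
#'
#' Behavioral-session pipeline: each channel is detrended by fitting a
#' fourth-degree polynomial to the raw trace and dividing it out, the
#' control is regressed onto the signal over the entire session, the signal
#' is divided by the fitted control, and the normalized ratio is block-mean
#' downsampled by \code{down} (default 100) and smoothed over
#' \code{smooth_s} (default 1 s). Event-aligned z-scoring happens downstream
#' (see \code{\link{extract_epochs}}).
#'
#' @param rec a \code{\link{two_channel_recording}}.
#' @param poly_degree polynomial degree for the bleaching detrend.
#' @param down integer downsampling factor.
#' @param smooth_s rolling-mean window (s).
#' @return a \code{\link{processed_trace}} (variant \code{"session_lls"},
#'   unit \code{"ratio"}), centered near 1.
#' @export
preprocess_session_lls <- function(rec, poly_degree = 4, down = 100,
                                   smooth_s = 1) {
  stopifnot(inherits(rec, "two_channel_recording"))
  n <- length(rec$t)
  if (n < 10 * (poly_degree + 1))
    stop("recording too short for a degree-", poly_degree, " detrend")
  detrend <- function(y) {
    fitted <- stats::fitted(stats::lm(y ~ stats::poly(rec$t, poly_degree,
                                                      raw = TRUE)))
    if (any(fitted <= 0))
      stop("polynomial detrend curve crosses zero; cannot divide")
    y / fitted
  }
  sig_d <- detrend(rec$signal)
  ctr_d <- detrend(rec$control)
  if (stats::sd(ctr_d) < 1e-12 * max(abs(ctr_d), 1)) {
    # degenerate artifact-free control: best LS constant predictor
    fitted_ctrl <- rep(mean(sig_d), n)
    slope <- 0; intercept <- mean(sig_d)
  } else {
    lls <- fit_lls(ctr_d, sig_d, window = NULL, t = rec$t)
    fitted_ctrl <- lls$fitted
    slope <- lls$slope; intercept <- lls$intercept
  }
  if (any(fitted_ctrl <= 0))
    stop("fitted control crosses zero; division undefined ",
         "(check channel scaling or the polynomial degree)")
  ratio <- sig_d / fitted_ctrl
  t_ds <- downsample_block(rec$t, down)
  v <- downsample_block(ratio, down)
  v <- rolling_mean(v, round(smooth_s * rec$rate / down))
  processed_trace(
    t_ds, v, variant = "session_lls", unit = "ratio",
    baseline_window = NULL,
    provenance = list(
      list(step = "preprocess_session_lls",
           params = list(poly_degree = poly_degree, down = down,
                         smooth_s = smooth_s)),
      list(step = "polynomial_detrend_divide",
           params = list(degree = poly_degree)),
      list(step = "lls_divide",
           params = list(slope = slope, intercept = intercept)),
      list(step = "downsample", params = list(factor = down)),
      list(step = "rolling_smooth", params = list(smooth_s = smooth_s))))
}

#' Replay the provenance of a processed trace
#'
#' Re-runs the preprocessing variant recorded in a trace's provenance on a
#' raw recording; with the original recording this reproduces the trace
#' bit-for-bit.
#'
#' @param rec the raw \code{\link{two_channel_recording}}.
#' @param trace a \code{\link{processed_trace}}.
#' @return a new \code{\link{processed_trace}}.
#' @export
replay_provenance <- function(rec, trace) {
  stopifnot(inherits(trace, "processed_trace"))
  head <- trace$provenance[[1]]
  fn <- switch(head$step,
               preprocess_arc = preprocess_arc,
               preprocess_baseline_lls = preprocess_baseline_lls,
               preprocess_session_lls = preprocess_session_lls,
               stop("unknown pipeline step: ", head$step))
  do.call(fn, c(list(rec), head$params))
}
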