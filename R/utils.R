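#' Non-overlapping block-mean downsampling
#'
#' Averages consecutive blocks of \code{factor} samples. A trailing partial
#' block is averaged over the samples it holds, so the overall mean of the
#' trace is preserved up to edge effects.
#'
#' @param x numeric vector.
#' @param factor integer downsampling factor, >= 1.
#' @return numeric vector of length \code{ceiling(length(x)/factor)}.
#' @export
downsample_block <- function(x, factor) {
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  idx <- (seq_along(x) - 1L) %/% factor
  as.numeric(tapply(x, idx, mean))
}

#' Centered rolling-mean smoothing
#'
#' Centered moving average whose window shrinks to the valid range near the
#' edges (no padding, no NA).
#'
#' @param x numeric vector.
#' @param width window width in samples (>= 1); even widths are extended to
#'   the next odd number so the window is symmetric.
#' @return smoothed numeric vector, same length as \code{x}.
#' @export
rolling_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  n <- length(x)
  if (h == 0L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Low-pass Gaussian noise: white noise smoothed with a moving average sized
# so the effective cutoff is near `bandwidth` Hz, then rescaled to unit SD.
lowpass_noise <- function(n, rate, bandwidth) {
  w <- stats::rnorm(n)
  width <- max(1L, as.integer(round(rate / (2 * bandwidth))))
  s <- rolling_mean(w, width)
  sdv <- stats::sd(s)
  if (sdv > 0) s <- s / sdv
  s
}

# Round half away from zero (round() in R rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Indices of samples with t inside [w[1], w[2]] (closed interval).
window_idx <- function(t, w) which(t >= w[1] & t <= w[2])

#' Photobleaching decay curve
#'
#' Evaluates a normalized bleaching multiplier b(t) with b(0) = 1 for one of
#' three parametric families commonly used to model photobleaching:
#' \itemize{
#'   \item \code{power_like}: \code{a*(t + t0)^(-b) + c} — slow power-law-like
#'     decay typical of fiber-photometry baselines;
#'   \item \code{biexponential}: \code{a1*exp(-t/tau1) + a2*exp(-t/tau2) + c};
#'   \item \code{polynomial}: \code{1 + sum(coef_k * t^k)}, degree up to 4.
#' }
#'
#' @param model \code{"none"}, \code{"power_like"}, \code{"biexponential"} or
#'   \code{"polynomial"}.
#' @param params named list overriding the family defaults.
#' @param t time vector (s).
#' @return numeric vector of multipliers, positive, with value 1 at t = 0.
#' @export
bleach_curve <- function(model, params = list(), t) {
  switch(model,
    none = rep(1, length(t)),
    power_like = {
      p <- utils::modifyList(list(a = 1, b = 0.25, t0 = 20, c = 0.3), params)
      raw <- p$a * (t + p$t0)^(-p$b) + p$c
      raw / (p$a * p$t0^(-p$b) + p$c)
    },
    biexponential = {
      p <- utils::modifyList(list(a1 = 0.3, tau1 = 60, a2 = 0.2, tau2 = 600,
                                  c = 0.5), params)
      raw <- p$a1 * exp(-t / p$tau1) + p$a2 * exp(-t / p$tau2) + p$c
      raw / (p$a1 + p$a2 + p$c)
    },
    polynomial = {
      p <- utils::modifyList(list(coef = c(-2e-4, 0, 0, 0)), params)
      k <- seq_along(p$coef)
      raw <- 1 + drop(outer(t, k, `^`) %*% p$coef)
      if (any(raw <= 0))
        stop("polynomial bleach curve crosses zero; choose milder coefficients")
      raw
    },
    stop("unknown bleach model: ", model)
  )
}
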