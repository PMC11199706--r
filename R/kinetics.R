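#' Onset latency of a reference-dye signal
#'
#' Determines how quickly the ligand reached the imaged cells by measuring
#' the time for a co-applied reference-dye signal to reach a set fraction
#' (default 85\%) of its plateau value. The plateau is estimated as the mean
#' of the final 10\% of samples and the baseline as the mean of samples
#' before \code{application_s}. Recordings whose latency is not below
#' \code{max_latency} (default 50 ms) fail the gate and should be excluded
#' from kinetic aggregates.
#'
#' @param reference reference-dye fluorescence series.
#' @param rate sampling rate (Hz).
#' @param fraction plateau fraction defining the crossing, in (0, 1).
#' @param max_latency gate threshold (s), default 0.050.
#' @param application_s ligand application time (s), default 0.
#' @return list of class \code{latency_gate}: \code{latency} (s, NA when the
#'   threshold is never crossed), \code{fraction}, \code{max_latency},
#'   \code{passed}, \code{reason}.
#' @export
onset_latency <- function(reference, rate, fraction = 0.85,
                          max_latency = 0.050, application_s = 0) {
  stopifnot(rate > 0, fraction > 0, fraction < 1)
  n <- length(reference)
  t <- (seq_len(n) - 1L) / rate
  pre <- reference[t < application_s]
  baseline <- if (length(pre) > 0) mean(pre) else reference[1]
  plateau <- mean(reference[t >= t[n] - 0.1 * (t[n] - t[1])])
  if (plateau <= baseline) {
    return(structure(list(latency = NA_real_, fraction = fraction,
                          max_latency = max_latency, passed = FALSE,
                          reason = "no positive excursion above baseline"),
                     class = "latency_gate"))
  }
  thr <- baseline + fraction * (plateau - baseline)
  cross <- which(reference > thr & t >= application_s)
  if (length(cross) == 0) {
    return(structure(list(latency = NA_real_, fraction = fraction,
                          max_latency = max_latency, passed = FALSE,
                          reason = "threshold never crossed"),
                     class = "latency_gate"))
  }
  latency <- t[cross[1]] - application_s
  structure(list(latency = latency, fraction = fraction,
                 max_latency = max_latency,
                 passed = latency < max_latency, reason = NULL),
            class = "latency_gate")
}

#' @export
print.latency_gate <- function(x, ...) {
  if (is.na(x$latency))
    cat(sprintf("Onset latency: undefined (%s); gate FAILED\n", x$reason))
  else
    cat(sprintf("Onset latency: %.1f ms (gate at %.0f ms): %s\n",
                1000 * x$latency, 1000 * x$max_latency,
                if (x$passed) "passed" else "FAILED"))
  invisible(x)
}

#' Mono-exponential kinetic fit
#'
#' Fits an association model \eqn{y(t) = c + A (1 - e^{-t/\tau})} or a decay
#' model \eqn{y(t) = c + A e^{-t/\tau}} by Levenberg-Marquardt nonlinear
#' least squares, initialized from a log-linear regression of the residual
#' amplitude. \eqn{\tau} is bounded in (0, 10 x trace duration]. A negative
#' fitted amplitude in association mode (or positive-going "decay") signals
#' an inverted trace and is flagged but not rejected.
#'
#' @param trace fluorescence (or dF/F0) series.
#' @param rate sampling rate (Hz); ignored when \code{t} is given.
#' @param mode \code{"association"} or \code{"decay"}.
#' @param t optional time vector (s).
#' @return list of class \code{exp_fit}: \code{tau} (s), \code{amplitude},
#'   \code{offset}, \code{mode}, \code{rss}, \code{converged},
#'   \code{inverted}.
#' @export
fit_mono_exponential <- function(trace, rate = NULL,
                                 mode = c("association", "decay"),
                                 t = NULL) {
  mode <- match.arg(mode)
  if (is.null(t)) {
    stopifnot(!is.null(rate), rate > 0)
    t <- (seq_along(trace) - 1) / rate
  }
  n <- length(trace)
  fail <- structure(list(tau = NA_real_, amplitude = NA_real_,
                         offset = NA_real_, mode = mode, rss = NA_real_,
                         converged = FALSE, inverted = FALSE),
                    class = "exp_fit")
  if (n < 10 || stats::sd(trace) == 0) return(fail)
  tt <- t - t[1]
  dur <- max(tt)
  # log-linear initialization on the decaying residual amplitude
  if (mode == "decay") {
    off0 <- mean(trace[tt >= 0.9 * dur])
    resid <- trace - off0
  } else {
    off0 <- mean(trace[seq_len(max(1L, floor(0.02 * n)))])
    plat <- mean(trace[tt >= 0.9 * dur])
    resid <- plat - trace
  }
  s <- sign(stats::median(resid[seq_len(max(1L, floor(n / 4)))]))
  if (s == 0) s <- 1
  pos <- which(s * resid > 0)
  tau0 <- if (length(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(s * resid[pos]) ~ tt[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else dur / 3
  } else dur / 3
  tau0 <- min(max(tau0, dur / 1e3), 10 * dur)
  amp0 <- if (mode == "decay") trace[1] - off0 else
    mean(trace[tt >= 0.9 * dur]) - off0
  df <- data.frame(tt = tt, y = trace)
  form <- if (mode == "decay") y ~ c0 + A * exp(-tt / tau)
          else y ~ c0 + A * (1 - exp(-tt / tau))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df,
                      start = list(c0 = off0, A = amp0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-12),
                      upper = c(Inf, Inf, 10 * dur),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  structure(list(tau = cf[["tau"]], amplitude = cf[["A"]],
                 offset = cf[["c0"]], mode = mode,
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 inverted = cf[["A"]] < 0),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Mono-exponential fit: did not converge\n")
  } else {
    cat(sprintf("Mono-exponential %s fit: tau = %.4g s, amplitude = %.3g, offset = %.3g%s\n",
                x$mode, x$tau, x$amplitude, x$offset,
                if (x$inverted) " [inverted trace]" else ""))
  }
  invisible(x)
}

#' Per-pixel activation time constants
#'
#' Fits a mono-exponential association model to every masked pixel of a
#' line-scan stack and summarizes the converged fits. Each pixel trace is
#' min-max normalized to [0, 1] first (when \code{normalize}), which makes
#' the estimated time constants invariant to per-pixel gain.
#'
#' @param stack a \code{\link{pixel_stack}}.
#' @param mask a \code{\link{select_membrane_rois}} result, or a logical
#'   vector per pixel.
#' @param normalize min-max normalize each pixel trace before fitting.
#' @param onset_s fit start time (s); frames before it are dropped so the
#'   fit covers the rising phase only. Default 0 (whole trace).
#' @return list of class \code{pixel_tau_summary}: data.frame \code{fits}
#'   (pixel, tau, converged), \code{mean}, \code{sd}, \code{n},
#'   \code{n_failed}.
#' @export
pixelwise_tau_on <- function(stack, mask, normalize = TRUE, onset_s = 0) {
  stopifnot(inherits(stack, "pixel_stack"))
  sel <- if (inherits(mask, "roi_mask")) mask$selected else as.logical(mask)
  stopifnot(length(sel) == nrow(stack$data))
  px <- which(sel)
  if (length(px) == 0) stop("mask selects no pixels")
  t <- (seq_len(ncol(stack$data)) - 1) / stack$rate
  keep <- t >= onset_s
  taus <- rep(NA_real_, length(px))
  conv <- logical(length(px))
  for (j in seq_along(px)) {
    y <- stack$data[px[j], keep]
    if (normalize) {
      rng <- range(y)
      if (diff(rng) > 0) y <- (y - rng[1]) / diff(rng)
    }
    f <- fit_mono_exponential(y, t = t[keep], mode = "association")
    conv[j] <- f$converged && !f$inverted
    if (conv[j]) taus[j] <- f$tau
  }
  if (!any(conv)) stop("no converged fits among the masked pixels")
  structure(list(fits = data.frame(pixel = px, tau = taus,
                                   converged = conv),
                 mean = mean(taus[conv]), sd = stats::sd(taus[conv]),
                 n = sum(conv), n_failed = sum(!conv)),
            class = "pixel_tau_summary")
}

#' @export
print.pixel_tau_summary <- function(x, ...) {
  cat(sprintf("Per-pixel tau_on: %.0f +/- %.0f ms (n = %d converged, %d failed)\n",
              1000 * x$mean, 1000 * ifelse(is.na(x$sd), 0, x$sd), x$n,
              x$n_failed))
  invisible(x)
}

#' Gate and aggregate kinetic experiments by onset latency
#'
#' Applies the onset-latency gate to a set of experiments and averages the
#' time constants of those that pass, reporting the exclusion count.
#'
#' @param taus time constants (s), one per experiment.
#' @param gates list of \code{\link{onset_latency}} results, parallel to
#'   \code{taus}.
#' @return list: \code{mean}, \code{sd}, \code{n}, \code{n_excluded}.
#' @export
aggregate_gated_taus <- function(taus, gates) {
  stopifnot(length(taus) == length(gates))
  ok <- vapply(gates, function(g) isTRUE(g$passed), logical(1))
  if (!any(ok)) stop("all experiments excluded by the latency gate")
  list(mean = mean(taus[ok]), sd = stats::sd(taus[ok]), n = sum(ok),
       n_excluded = sum(!ok))
}
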