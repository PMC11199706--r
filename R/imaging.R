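#' Fractional fluorescence change relative to a baseline period
#'
#' Computes \eqn{\Delta F/F_0 = (F_t - F_0)/F_0}, where \eqn{F_0} is the mean
#' fluorescence over the baseline window. Values below -1 are physically
#' impossible (fluorescence cannot be negative) and are clipped with a
#' warning, as they indicate a wrong baseline.
#'
#' @param trace raw fluorescence series.
#' @param baseline_window length-2 vector giving the baseline interval; in
#'   seconds when \code{t} is supplied, otherwise sample indices.
#' @param t optional time vector matching \code{trace}.
#' @return list of class \code{dff_trace}: \code{t}, \code{dff}, \code{f0},
#'   \code{baseline_window}.
#' @export
compute_dff <- function(trace, baseline_window, t = NULL) {
  if (is.null(t)) t <- seq_along(trace)
  stopifnot(length(t) == length(trace), length(baseline_window) == 2)
  idx <- window_idx(t, baseline_window)
  if (length(idx) == 0) stop("baseline window contains no samples")
  f0 <- mean(trace[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean must be positive; dF/F0 undefined")
  dff <- (trace - f0) / f0
  if (any(dff < -1)) {
    warning("dF/F0 values below -1 clipped; check the baseline window")
    dff <- pmax(dff, -1)
  }
  structure(list(t = t, dff = dff, f0 = f0,
                 baseline_window = baseline_window),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dF/F0 trace: %d samples, F0 = %.3g, peak dF/F0 = %.1f%%\n",
              length(x$dff), x$f0, 100 * max(x$dff)))
  invisible(x)
}

#' Select membrane regions of interest in a pixel stack
#'
#' Two selection methods:
#' \describe{
#'   \item{\code{dff_fraction}}{computes per-pixel peak dF/F0 (baseline =
#'     mean of the frames before \code{onset_frame}) and keeps pixels whose
#'     peak reaches at least \code{fraction} of the stack-wide maximum peak
#'     (default 0.65, the 65\% membrane-pixel criterion).}
#'   \item{\code{auto_threshold}}{Otsu's histogram threshold on the
#'     temporal-mean intensity image. A contrast-free (uniform) image yields
#'     an empty mask with a warning.}
#' }
#'
#' @param stack a \code{\link{pixel_stack}}.
#' @param method \code{"dff_fraction"} or \code{"auto_threshold"}.
#' @param fraction threshold fraction for \code{dff_fraction}.
#' @param onset_frame first frame of the response; frames before it define
#'   the per-pixel baseline (default: first 10\% of frames).
#' @return list of class \code{roi_mask}: logical \code{selected} per pixel,
#'   \code{method}, \code{threshold_used}.
#' @export
select_membrane_rois <- function(stack,
                                 method = c("dff_fraction",
                                            "auto_threshold"),
                                 fraction = 0.65, onset_frame = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "pixel_stack"))
  if (nrow(stack$data) == 0 || ncol(stack$data) == 0)
    stop("empty pixel stack")
  if (method == "dff_fraction") {
    stopifnot(fraction > 0, fraction < 1)
    nfr <- ncol(stack$data)
    if (is.null(onset_frame)) onset_frame <- max(2L, ceiling(0.1 * nfr))
    base <- rowMeans(stack$data[, seq_len(onset_frame - 1L), drop = FALSE])
    if (any(base <= 0)) base[base <= 0] <- .Machine$double.eps
    peak <- apply(stack$data / base - 1, 1, max)
    thr <- fraction * max(peak)
    sel <- peak >= thr
  } else {
    m <- rowMeans(stack$data)
    rng <- range(m)
    if (diff(rng) == 0) {
      warning("uniform image: no contrast for auto-thresholding; empty mask")
      return(structure(list(selected = rep(FALSE, nrow(stack$data)),
                            method = method, threshold_used = NA_real_),
                       class = "roi_mask"))
    }
    norm <- (m - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(matrix(norm, nrow = 1), range = c(0, 1))
    thr <- rng[1] + thr01 * diff(rng)
    sel <- m > thr
  }
  structure(list(selected = sel, method = method, threshold_used = thr),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask (%s): %d/%d pixels selected (threshold %.3g)\n",
              x$method, sum(x$selected), length(x$selected),
              x$threshold_used))
  invisible(x)
}

#' Biexponential photobleaching correction
#'
#' Fits \eqn{F(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + C} to the segment
#' preceding ligand application, extrapolates the fit across the whole trace
#' and removes it. Division (default) keeps subsequent dF/F0 quantification
#' scale-invariant; subtraction is available for completeness. The corrected
#' trace is rescaled so its mean over the pre-application window matches the
#' raw trace there, so a flat trace passes through unchanged.
#'
#' @param trace raw fluorescence series.
#' @param pre_window length-2 window (same units as \code{t}) preceding
#'   ligand application; must hold at least 20 samples.
#' @param t optional time vector (defaults to sample index).
#' @param method \code{"divide"} or \code{"subtract"}.
#' @return list of class \code{bleach_fit}: \code{corrected},
#'   \code{baseline} (fitted curve over the full trace), \code{coefficients},
#'   \code{converged}. On non-convergence the original trace is returned with
#'   \code{converged = FALSE}.
#' @export
correct_bleaching_biexp <- function(trace, pre_window, t = NULL,
                                    method = c("divide", "subtract")) {
  method <- match.arg(method)
  if (is.null(t)) t <- seq_along(trace)
  idx <- window_idx(t, pre_window)
  if (length(idx) < 20)
    stop("pre-application window must hold at least 20 samples for a 5-parameter fit")
  df <- data.frame(tt = t[idx] - t[idx[1]], y = trace[idx])
  t0 <- t[idx[1]]
  span <- max(df$tt)
  amp <- max(df$y) - min(df$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-tt / tau1) + a2 * exp(-tt / tau2) + c0, data = df,
      start = list(a1 = amp / 2, tau1 = span / 10, a2 = amp / 2,
                   tau2 = span, c0 = min(df$y)),
      lower = c(0, 1e-9, 0, 1e-9, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(corrected = trace, baseline = rep(NA_real_,
                                                            length(trace)),
                          coefficients = NULL, converged = FALSE),
                     class = "bleach_fit"))
  }
  cf <- stats::coef(fit)
  full <- cf[["a1"]] * exp(-(t - t0) / cf[["tau1"]]) +
          cf[["a2"]] * exp(-(t - t0) / cf[["tau2"]]) + cf[["c0"]]
  if (method == "divide") {
    if (any(full <= 0))
      return(structure(list(corrected = trace, baseline = full,
                            coefficients = cf, converged = FALSE),
                       class = "bleach_fit"))
    corrected <- trace / full * mean(full[idx])
  } else {
    corrected <- trace - full + mean(full[idx])
  }
  structure(list(corrected = corrected, baseline = full,
                 coefficients = cf, converged = TRUE),
            class = "bleach_fit")
}

#' Stepwise bath-application responses
#'
#' For a staircase protocol in which increasing ligand concentrations are
#' bath-applied sequentially, quantifies each step as the difference between
#' the mean dF/F0 over the last \code{avg_s} seconds of the application
#' window and the mean over the \code{avg_s} seconds immediately preceding
#' it (default 180 s, i.e. 3-min averaging intervals).
#'
#' @param dff a \code{\link{compute_dff}} result (or list with \code{t} and
#'   \code{dff}).
#' @param application_windows list of length-2 vectors (start, end) in
#'   seconds, ordered and non-overlapping, one per concentration.
#' @param avg_s averaging interval (s), default 180.
#' @return numeric vector of per-step responses (dF/F0 units).
#' @export
stepwise_response <- function(dff, application_windows, avg_s = 180) {
  t <- dff$t
  y <- dff$dff
  if (length(application_windows) == 0) return(numeric(0))
  starts <- vapply(application_windows, `[`, numeric(1), 1)
  ends <- vapply(application_windows, `[`, numeric(1), 2)
  if (any(ends - starts < avg_s))
    stop("each application window must be at least avg_s long")
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] < ends[-length(ends)]))
    stop("application windows must be ordered and non-overlapping")
  vapply(seq_along(application_windows), function(i) {
    late <- window_idx(t, c(ends[i] - avg_s, ends[i]))
    pre <- window_idx(t, c(starts[i] - avg_s, starts[i]))
    if (length(late) == 0 || length(pre) == 0)
      stop("averaging interval falls outside the trace for step ", i)
    mean(y[late]) - mean(y[pre])
  }, numeric(1))
}
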