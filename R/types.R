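#' Sensor simulation parameters
#'
#' Bundles the parameters of the two-state ligand-binding sensor model and of
#' the nuisance processes (photobleaching, shared motion artifacts, additive
#' noise) applied by the session simulators. The equilibrium dissociation
#' constant is \code{Kd = k_off / k_on}; at equilibrium the fractional
#' occupancy is \code{L / (L + Kd)}, so with a Hill coefficient of 1 the
#' simulated sensor reproduces a three-parameter Hill concentration-response
#' curve with \code{EC50 = Kd}.
#'
#' Defaults place Kd at 28.65 nM and the maximal fractional fluorescence
#' increase at 3.88 (a 388\% dF/F0 at saturation), matching the in vitro
#' characterization of the nociceptin sensor this package targets.
#'
#' @param k_on association rate constant (1/M/s), > 0.
#' @param k_off dissociation rate constant (1/s), > 0.
#' @param r_max maximal fractional fluorescence increase at full occupancy
#'   (dimensionless; 3.88 means +388\%).
#' @param f0 baseline fluorescence in arbitrary units, > 0.
#' @param bleach_model one of \code{"none"}, \code{"power_like"},
#'   \code{"biexponential"}, \code{"polynomial"}.
#' @param bleach_params named list of parameters for the chosen bleach model;
#'   see \code{\link{bleach_curve}} for the parameterizations and defaults.
#' @param motion_sd standard deviation of the shared multiplicative motion
#'   artifact, as a fraction of baseline fluorescence.
#' @param motion_bandwidth low-pass cutoff of the motion artifact (Hz).
#' @param noise_sd per-sample additive Gaussian noise SD, as a fraction of
#'   \code{f0}.
#' @param seed optional integer seed used by stochastic simulators.
#' @return An object of class \code{sensor_params}.
#' @export
sensor_params <- function(k_on = 1e6, k_off = 0.02865, r_max = 3.88,
                          f0 = 100, bleach_model = c("none", "power_like",
                                                     "biexponential",
                                                     "polynomial"),
                          bleach_params = list(), motion_sd = 0,
                          motion_bandwidth = 2, noise_sd = 0, seed = NULL) {
  bleach_model <- match.arg(bleach_model)
  stopifnot(k_on > 0, k_off > 0, f0 > 0, r_max >= 0,
            motion_sd >= 0, noise_sd >= 0, motion_bandwidth > 0)
  kd <- k_off / k_on
  if (!is.finite(kd) || kd <= 0)
    stop("equilibrium dissociation constant k_off/k_on must be finite and positive")
  structure(list(k_on = k_on, k_off = k_off, r_max = r_max, f0 = f0,
                 bleach_model = bleach_model, bleach_params = bleach_params,
                 motion_sd = motion_sd, motion_bandwidth = motion_bandwidth,
                 noise_sd = noise_sd, seed = seed, kd = kd),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat("Sensor simulation parameters\n")
  cat(sprintf("  k_on  = %.3g /M/s   k_off = %.3g /s   Kd = %.3g M\n",
              x$k_on, x$k_off, x$kd))
  cat(sprintf("  r_max = %.3g (max dF/F0 = %.0f%%)   f0 = %.3g\n",
              x$r_max, 100 * x$r_max, x$f0))
  cat(sprintf("  bleach = %s   motion_sd = %.3g   noise_sd = %.3g\n",
              x$bleach_model, x$motion_sd, x$noise_sd))
  invisible(x)
}

#' Behavioral event schedule
#'
#' @param events data.frame with columns \code{time_s}, \code{label},
#'   \code{duration_s}; onset times must be strictly increasing and every
#'   event must end inside the session.
#' @param session_length session length in seconds.
#' @param variant paradigm tag, one of \code{"injection"},
#'   \code{"cued_sucrose"}, \code{"tail_lift"}, \code{"operant_fr"},
#'   \code{"operant_pr"}.
#' @return An object of class \code{event_schedule}.
#' @export
event_schedule <- function(events, session_length,
                           variant = c("injection", "cued_sucrose",
                                       "tail_lift", "operant_fr",
                                       "operant_pr")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(events),
            all(c("time_s", "label", "duration_s") %in% names(events)),
            session_length > 0)
  if (nrow(events) > 1 && any(diff(events$time_s) <= 0))
    stop("event times must be strictly increasing")
  if (nrow(events) > 0 &&
      any(events$time_s < 0 | events$time_s + events$duration_s > session_length))
    stop("all events must fit inside the session")
  structure(list(events = events, session_length = session_length,
                 variant = variant),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("Event schedule (%s): %d events over %.0f s\n",
              x$variant, nrow(x$events), x$session_length))
  if (nrow(x$events) > 0) print(utils::head(x$events, 10))
  invisible(x)
}

#' Two-channel photometry recording
#'
#' Container for a signal (ligand-dependent excitation) and control
#' (isosbestic) fluorescence trace sampled on a common uniform grid, together
#' with the behavioral event schedule.
#'
#' @param t time vector (s), uniformly spaced.
#' @param signal signal-channel fluorescence.
#' @param control control-channel (isosbestic) fluorescence.
#' @param rate sampling rate (Hz).
#' @param events optional \code{\link{event_schedule}}.
#' @param meta named list of labels (e.g. channel wavelengths).
#' @param truth optional named list of simulator ground-truth values.
#' @return An object of class \code{two_channel_recording}.
#' @export
two_channel_recording <- function(t, signal, control, rate, events = NULL,
                                  meta = list(), truth = NULL) {
  stopifnot(length(t) == length(signal), length(t) == length(control),
            rate > 0)
  if (length(t) > 2) {
    dt <- diff(t)
    if (max(abs(dt - 1 / rate)) > 1e-6 / rate)
      stop("time vector must be uniformly spaced at 1/rate")
  }
  if (!is.null(events) && !inherits(events, "event_schedule"))
    stop("events must be an event_schedule")
  structure(list(t = t, signal = signal, control = control, rate = rate,
                 events = events, meta = meta, truth = truth),
            class = "two_channel_recording")
}

#' @export
print.two_channel_recording <- function(x, ...) {
  cat(sprintf("Two-channel recording: %d samples at %.2f Hz (%.1f s)\n",
              length(x$t), x$rate, length(x$t) / x$rate))
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%s)\n", nrow(x$events$events),
                x$events$variant))
  invisible(x)
}

#' Pixel stack (line-scan or movie reshaped to pixels x frames)
#'
#' @param data numeric matrix, pixels x frames, non-negative.
#' @param rate frame rate (Hz).
#' @param membrane_mask_truth optional logical vector (simulation ground
#'   truth), one entry per pixel.
#' @param reference optional matrix of identical shape holding a
#'   reference-dye channel.
#' @param truth optional named list of simulator ground-truth values.
#' @return An object of class \code{pixel_stack}.
#' @export
pixel_stack <- function(data, rate, membrane_mask_truth = NULL,
                        reference = NULL, truth = NULL) {
  stopifnot(is.matrix(data), rate > 0)
  if (any(data < 0)) stop("pixel data must be non-negative")
  if (!is.null(membrane_mask_truth))
    stopifnot(length(membrane_mask_truth) == nrow(data))
  if (!is.null(reference))
    stopifnot(is.matrix(reference), all(dim(reference) == dim(data)))
  structure(list(data = data, rate = rate,
                 membrane_mask_truth = membrane_mask_truth,
                 reference = reference, truth = truth),
            class = "pixel_stack")
}

#' @export
print.pixel_stack <- function(x, ...) {
  cat(sprintf("Pixel stack: %d pixels x %d frames at %.0f Hz%s\n",
              nrow(x$data), ncol(x$data), x$rate,
              if (is.null(x$reference)) "" else " (+ reference channel)"))
  invisible(x)
}

#' Dose-response table
#'
#' @param concentration concentrations in molar, > 0.
#' @param response replicate responses (dF/F0, dimensionless).
#' @param replicate_id replicate identifier per row.
#' @param normalized logical flag; set by \code{\link{normalize_responses}}.
#' @return A data.frame of class \code{dose_response_table} with columns
#'   \code{concentration}, \code{response}, \code{replicate_id}.
#' @export
dose_response_table <- function(concentration, response,
                                replicate_id = seq_along(concentration),
                                normalized = FALSE) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration <= 0)) stop("concentrations must be positive")
  out <- data.frame(concentration = concentration, response = response,
                    replicate_id = replicate_id)
  class(out) <- c("dose_response_table", "data.frame")
  attr(out, "normalized") <- normalized
  out
}

#' Processed photometry trace
#'
#' Output container of the preprocessing pipelines. \code{provenance} is an
#' ordered list of applied steps with their parameters; replaying it on the
#' raw recording reproduces the trace exactly (see
#' \code{\link{replay_provenance}}).
#'
#' @param t time vector (s) after downsampling.
#' @param value processed values (dF/F0 difference, z-score, or normalized
#'   ratio depending on the variant).
#' @param variant one of \code{"arc"}, \code{"baseline_lls"},
#'   \code{"session_lls"}.
#' @param unit unit tag: \code{"dff"}, \code{"zscore"} or \code{"ratio"}.
#' @param baseline_window numeric length-2 vector (s) or NULL.
#' @param provenance ordered list of steps, each a list with elements
#'   \code{step} and \code{params}.
#' @return An object of class \code{processed_trace}.
#' @export
processed_trace <- function(t, value, variant, unit, baseline_window = NULL,
                            provenance = list()) {
  stopifnot(length(t) == length(value))
  structure(list(t = t, value = value, variant = variant, unit = unit,
                 baseline_window = baseline_window, provenance = provenance),
            class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("Processed trace (%s, %s): %d samples, %.1f-%.1f s\n",
              x$variant, x$unit, length(x$t), min(x$t), max(x$t)))
  for (st in x$provenance) cat("  -", st$step, "\n")
  invisible(x)
}
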