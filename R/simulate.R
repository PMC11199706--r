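#' Simulate the two-state ligand-binding response of the sensor
#'
#' Integrates the mass-action occupancy model
#' \deqn{dB/dt = k_{on} L (1 - B) - k_{off} B}
#' for a sampled (piecewise-constant, held per sample) ligand concentration
#' series and converts occupancy to fluorescence as
#' \eqn{F = f_0 (1 + r_{max} B)}. The solution is computed analytically per
#' sampling step (exponential relaxation towards \eqn{L/(L + K_d)} at rate
#' \eqn{k_{on} L + k_{off}}), so it is exact for piecewise-constant ligand and
#' deterministic given the parameters.
#'
#' @param params a \code{\link{sensor_params}} object.
#' @param ligand ligand concentration series (M), non-negative; either a
#'   single value (held constant) or a vector matching \code{t}.
#' @param t uniform time grid (s).
#' @param b0 initial occupancy in [0, 1].
#' @return list with \code{t}, \code{occupancy} (in [0,1]),
#'   \code{fluorescence} (>= 0) and \code{ligand}.
#' @export
simulate_binding_response <- function(params, ligand, t, b0 = 0) {
  stopifnot(inherits(params, "sensor_params"), b0 >= 0, b0 <= 1)
  n <- length(t)
  if (length(ligand) == 1L) ligand <- rep(ligand, n)
  stopifnot(length(ligand) == n)
  if (any(ligand < 0)) stop("ligand concentrations must be non-negative")
  if (n > 1) {
    dt <- diff(t)
    if (max(dt) - min(dt) > 1e-9 * max(dt))
      stop("time grid must be uniform")
    dt <- dt[1]
  } else dt <- 0
  r <- params$k_on * ligand + params$k_off
  binf <- params$k_on * ligand / r
  a <- exp(-r * dt)
  b <- numeric(n)
  b[1] <- b0
  if (n > 1) {
    for (i in seq_len(n - 1L))
      b[i + 1L] <- binf[i] + (b[i] - binf[i]) * a[i]
  }
  b <- pmin(pmax(b, 0), 1)
  list(t = t, occupancy = b,
       fluorescence = params$f0 * (1 + params$r_max * b),
       ligand = ligand)
}

# Default mapping from event labels to ligand transients (amplitudes in M).
default_response_map <- function(kd) {
  list(
    injection = list(shape = "sustained", amplitude = 4 * kd, tau = 180),
    cno       = list(shape = "sustained", amplitude = 4 * kd, tau = 300),
    tail_lift = list(shape = "transient", amplitude = 4 * kd, tau = 5),
    tone      = list(shape = "transient", amplitude = 2 * kd, tau = 2),
    cue       = list(shape = "transient", amplitude = 2 * kd, tau = 2),
    sucrose   = list(shape = "transient", amplitude = -1 * kd, tau = 3),
    reward    = list(shape = "transient", amplitude = -1 * kd, tau = 3),
    poke      = list(shape = "transient", amplitude = 0.5 * kd, tau = 1)
  )
}

# Ligand concentration series implied by a schedule under a response map.
schedule_to_ligand <- function(schedule, t, map, tonic = 0) {
  lig <- rep(tonic, length(t))
  ev <- schedule$events
  for (k in seq_len(nrow(ev))) {
    m <- map[[ev$label[k]]]
    if (is.null(m) || m$amplitude == 0) next
    rel <- t - ev$time_s[k]
    on <- rel >= 0
    comp <- numeric(length(t))
    if (m$shape == "sustained") {
      comp[on] <- m$amplitude * (1 - exp(-rel[on] / m$tau))
    } else { # alpha-shaped transient peaking at tau after onset
      comp[on] <- m$amplitude * (rel[on] / m$tau) * exp(1 - rel[on] / m$tau)
    }
    lig <- lig + comp
  }
  pmax(lig, 0)
}

#' Simulate a two-channel fiber-photometry session
#'
#' Generates a signal (ligand-dependent) and control (isosbestic) channel at
#' the acquisition rate of the recording system (default 1017.25 Hz). Events
#' in the schedule drive ligand transients on the signal channel only (via
#' the binding model of \code{\link{simulate_binding_response}}); bleaching
#' and a shared low-pass motion artifact are applied multiplicatively to both
#' channels, followed by independent additive noise per channel.
#'
#' @param params a \code{\link{sensor_params}} object.
#' @param schedule an \code{\link{event_schedule}}.
#' @param rate sampling rate (Hz), default 1017.25.
#' @param control_gain baseline of the control channel as a fraction of
#'   \code{f0}.
#' @param response_map named list mapping event labels to ligand components
#'   (each a list with \code{shape} = "sustained" or "transient",
#'   \code{amplitude} in M — negative for consumption dips — and \code{tau}
#'   in s). Defaults scale amplitudes to the sensor Kd.
#' @param tonic tonic ligand level (M) the transients ride on.
#' @param seed integer seed (defaults to \code{params$seed}).
#' @return a \code{\link{two_channel_recording}} whose \code{truth} element
#'   records the ligand series, occupancy, bleach and motion waveforms.
#' @export
simulate_photometry_session <- function(params, schedule, rate = 1017.25,
                                        control_gain = 0.5,
                                        response_map = NULL, tonic = 0,
                                        seed = params$seed) {
  stopifnot(inherits(params, "sensor_params"),
            inherits(schedule, "event_schedule"), rate > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, floor(schedule$session_length * rate))
  t <- (seq_len(n) - 1L) / rate
  if (is.null(response_map)) response_map <- default_response_map(params$kd)
  lig <- schedule_to_ligand(schedule, t, response_map, tonic)
  b0 <- if (tonic > 0) tonic / (tonic + params$kd) else 0
  sim <- simulate_binding_response(params, lig, t, b0 = b0)
  bleach <- bleach_curve(params$bleach_model, params$bleach_params, t)
  motion <- if (params$motion_sd > 0)
    params$motion_sd * lowpass_noise(n, rate, params$motion_bandwidth)
  else rep(0, n)
  shared <- bleach * (1 + motion)
  signal <- sim$fluorescence * shared
  control <- params$f0 * control_gain * shared
  if (params$noise_sd > 0) {
    signal <- signal + stats::rnorm(n, 0, params$noise_sd * params$f0)
    control <- control + stats::rnorm(n, 0, params$noise_sd * params$f0)
  }
  two_channel_recording(
    t, signal, control, rate, events = schedule,
    meta = list(signal_nm = "470", control_nm = "405"),
    truth = list(ligand = lig, occupancy = sim$occupancy, bleach = bleach,
                 motion = motion, params = params))
}

#' Simulate a high-speed line-scan pixel stack
#'
#' Membrane pixels follow a mono-exponential association with time constant
#' \code{tau_true} after ligand arrival; background pixels carry a dim,
#' unresponsive baseline. A reference-dye channel is generated as a smoothed
#' step that reaches 85\% of its plateau \code{dye_latency} seconds after
#' ligand onset, for use with \code{\link{onset_latency}}.
#'
#' @param params a \code{\link{sensor_params}} object.
#' @param n_membrane,n_background pixel counts (>= 0).
#' @param rate frame rate (Hz), default 800.
#' @param tau_true association time constant (s), > 0; default 0.595.
#' @param dye_latency time for the reference dye to reach 85\% of plateau (s).
#' @param duration scan duration (s).
#' @param onset_s ligand arrival time (s).
#' @param noise_sd per-frame additive noise SD as a fraction of \code{f0}
#'   (defaults to \code{params$noise_sd}).
#' @param seed integer seed (defaults to \code{params$seed}).
#' @return a \code{\link{pixel_stack}} with \code{membrane_mask_truth} and a
#'   \code{truth} list holding \code{tau_true}, \code{onset_s} and
#'   \code{dye_latency}.
#' @export
simulate_linescan <- function(params, n_membrane = 50, n_background = 50,
                              rate = 800, tau_true = 0.595,
                              dye_latency = 0.02, duration = 5, onset_s = 1,
                              noise_sd = params$noise_sd,
                              seed = params$seed) {
  stopifnot(inherits(params, "sensor_params"), n_membrane >= 0,
            n_background >= 0, tau_true > 0, rate > 0, duration > onset_s)
  if (!is.null(seed)) set.seed(seed)
  nfr <- floor(duration * rate)
  t <- (seq_len(nfr) - 1L) / rate
  rel <- pmax(t - onset_s, 0)
  assoc <- 1 - exp(-rel / tau_true)
  npx <- n_membrane + n_background
  dat <- matrix(0, nrow = npx, ncol = nfr)
  if (n_membrane > 0) {
    gains <- stats::runif(n_membrane, 0.8, 1.2) * params$f0
    for (i in seq_len(n_membrane))
      dat[i, ] <- gains[i] * (1 + params$r_max * assoc)
  }
  if (n_background > 0) {
    gains <- stats::runif(n_background, 0.1, 0.2) * params$f0
    for (i in seq_len(n_background))
      dat[n_membrane + i, ] <- gains[i]
  }
  if (noise_sd > 0)
    dat <- dat + matrix(stats::rnorm(npx * nfr, 0, noise_sd * params$f0),
                        nrow = npx)
  dat <- pmax(dat, 0)
  # reference dye: exponential rise crossing 85% of plateau at dye_latency
  tau_d <- dye_latency / (-log(1 - 0.85))
  refprofile <- params$f0 * (0.1 + 0.9 * (1 - exp(-rel / tau_d)))
  reference <- matrix(rep(refprofile, each = npx), nrow = npx)
  if (noise_sd > 0)
    reference <- pmax(reference +
      matrix(stats::rnorm(npx * nfr, 0, 0.25 * noise_sd * params$f0),
             nrow = npx), 0)
  pixel_stack(dat, rate,
              membrane_mask_truth = c(rep(TRUE, n_membrane),
                                      rep(FALSE, n_background)),
              reference = reference,
              truth = list(tau_true = tau_true, onset_s = onset_s,
                           dye_latency = dye_latency))
}

#' Simulate a dose-response plate
#'
#' Replicate responses are drawn from a three-parameter Hill curve with
#' multiplicative Gaussian noise: \eqn{R_{ij} = H(c_i) (1 + \epsilon_{ij})}
#' with \eqn{\epsilon \sim N(0, cv)}.
#'
#' @param r_max maximal response (dimensionless dF/F0).
#' @param ec50 half-maximal effective concentration (M), > 0.
#' @param hill Hill coefficient, > 0.
#' @param concentrations tested concentrations (M); default is an 8-point
#'   ladder from 5 nM to 10 uM matching a typical bath-application series.
#' @param replicates replicates per concentration.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return a \code{\link{dose_response_table}} with attribute \code{truth}.
#' @export
simulate_dose_response <- function(r_max = 3.88, ec50 = 28.65e-9, hill = 1,
                                   concentrations = c(5e-9, 1e-8, 5e-8,
                                                      1e-7, 5e-7, 1e-6,
                                                      5e-6, 1e-5),
                                   replicates = 3, cv = 0.05, seed = NULL) {
  if (length(concentrations) == 0) stop("concentration list must be non-empty")
  stopifnot(ec50 > 0, hill > 0, cv >= 0, replicates >= 1,
            all(concentrations > 0))
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(concentrations, each = replicates)
  mu <- r_max * conc^hill / (ec50^hill + conc^hill)
  eps <- if (cv > 0) stats::rnorm(length(conc), 0, cv) else 0
  tab <- dose_response_table(conc, mu * (1 + eps),
                             replicate_id = rep(seq_len(replicates),
                                                times = length(concentrations)))
  attr(tab, "truth") <- list(r_max = r_max, ec50 = ec50, hill = hill, cv = cv)
  tab
}

#' Progressive-ratio nose-poke criteria
#'
#' Response requirement for the i-th reward on a progressive-ratio operant
#' schedule, following the geometric progression
#' \eqn{n_i = 5 e^{i/5} - 5} rounded half away from zero, which yields the
#' sequence 1, 2, 4, 6, 9, 12, ...
#'
#' @param n_rewards number of criteria to generate (>= 0).
#' @return integer vector of length \code{n_rewards}, non-decreasing.
#' @export
generate_pr_schedule <- function(n_rewards) {
  stopifnot(n_rewards >= 0)
  if (n_rewards == 0) return(integer(0))
  i <- seq_len(n_rewards)
  as.integer(round_half_away(5 * exp(i / 5) - 5))
}

#' Generate a behavioral event schedule
#'
#' Builds the trial structure of one of the supported paradigms with seeded
#' uniform inter-trial-interval draws:
#' \itemize{
#'   \item \code{injection}: a baseline period followed by a single
#'     injection event; session runs \code{post_s} after the injection.
#'   \item \code{cued_sucrose}: 5-min baseline, \code{n_trials} trials of a
#'     5-s tone immediately followed by 5-s sucrose access, ITI uniform on
#'     45-75 s, 5-min closing baseline.
#'   \item \code{tail_lift}: 5-min baseline, \code{n_trials} 10-s lifts with
#'     ITI uniform on 120-300 s, 5-min closing baseline.
#'   \item \code{operant_fr}: fixed-ratio session; every \code{fr}-th poke
#'     triggers a 5-s cue then reward.
#'   \item \code{operant_pr}: progressive-ratio session using
#'     \code{\link{generate_pr_schedule}} criteria.
#' }
#'
#' @param variant paradigm name (see above).
#' @param n_trials trial/reward count; defaults: 15 (cued_sucrose), 4
#'   (tail_lift), 30 (operant_fr), 10 (operant_pr), ignored for injection.
#' @param baseline_s opening baseline (s); default 300 (600 for injection).
#' @param post_s closing baseline (s); default 300 (1200 for injection).
#' @param iti_range ITI range (s) overriding the paradigm default.
#' @param fr fixed-ratio requirement (operant_fr only).
#' @param poke_interval mean interval between pokes (s, operant variants).
#' @param seed integer seed for the ITI draws.
#' @return an \code{\link{event_schedule}}.
#' @export
generate_event_schedule <- function(variant = c("injection", "cued_sucrose",
                                                "tail_lift", "operant_fr",
                                                "operant_pr"),
                                    n_trials = NULL, baseline_s = NULL,
                                    post_s = NULL, iti_range = NULL,
                                    fr = 1, poke_interval = 20,
                                    seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  bl <- baseline_s
  po <- post_s
  ev <- data.frame(time_s = numeric(0), label = character(0),
                   duration_s = numeric(0))
  if (variant == "injection") {
    if (is.null(bl)) bl <- 600
    if (is.null(po)) po <- 1200
    ev <- data.frame(time_s = bl, label = "injection", duration_s = 1)
    return(event_schedule(ev, session_length = bl + 1 + po, variant = variant))
  }
  if (is.null(bl)) bl <- 300
  if (is.null(po)) po <- 300
  if (variant == "cued_sucrose") {
    if (is.null(n_trials)) n_trials <- 15
    if (is.null(iti_range)) iti_range <- c(45, 75)
    t <- bl
    for (k in seq_len(n_trials)) {
      ev <- rbind(ev,
                  data.frame(time_s = t, label = "tone", duration_s = 5),
                  data.frame(time_s = t + 5, label = "sucrose",
                             duration_s = 5))
      t <- t + 10 + stats::runif(1, iti_range[1], iti_range[2])
    }
  } else if (variant == "tail_lift") {
    if (is.null(n_trials)) n_trials <- 4
    if (is.null(iti_range)) iti_range <- c(120, 300)
    t <- bl
    for (k in seq_len(n_trials)) {
      ev <- rbind(ev, data.frame(time_s = t, label = "tail_lift",
                                 duration_s = 10))
      t <- t + 10 + stats::runif(1, iti_range[1], iti_range[2])
    }
  } else { # operant variants
    if (is.null(n_trials)) n_trials <- if (variant == "operant_fr") 30 else 10
    criteria <- if (variant == "operant_pr") generate_pr_schedule(n_trials)
                else rep(fr, length.out = max(n_trials, 0))
    t <- bl
    for (k in seq_len(n_trials)) {
      for (p in seq_len(criteria[k])) {
        t <- t + stats::rexp(1, 1 / poke_interval)
        ev <- rbind(ev, data.frame(time_s = t, label = "poke",
                                   duration_s = 0.1))
      }
      t <- t + 0.5
      ev <- rbind(ev,
                  data.frame(time_s = t, label = "cue", duration_s = 5),
                  data.frame(time_s = t + 5, label = "reward",
                             duration_s = 1))
      t <- t + 7
    }
  }
  endt <- if (nrow(ev) > 0) max(ev$time_s + ev$duration_s) else bl
  event_schedule(ev, session_length = endt + po, variant = variant)
}
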