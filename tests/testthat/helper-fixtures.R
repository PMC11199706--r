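# Shared fixtures, built in code at test time.

# Quiet sensor with unit-friendly defaults for deterministic tests.
quiet_params <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, motion_sd = 0), list(...))
  do.call(sensor_params, args)
}

# Short two-channel recording with a single injection marker.
tiny_injection_session <- function(params, rate = 100, baseline_s = 60,
                                   post_s = 240, seed = 1, ...) {
  sch <- generate_event_schedule("injection", baseline_s = baseline_s,
                                 post_s = post_s, seed = seed)
  simulate_photometry_session(params, sch, rate = rate, seed = seed, ...)
}

# Noise-free mono-exponential traces in the fitted model class.
mono_decay <- function(tau, rate, dur, amp = 1, off = 0) {
  t <- seq(0, dur, by = 1 / rate)
  off + amp * exp(-t / tau)
}
mono_assoc <- function(tau, rate, dur, amp = 1, off = 0) {
  t <- seq(0, dur, by = 1 / rate)
  off + amp * (1 - exp(-t / tau))
}
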