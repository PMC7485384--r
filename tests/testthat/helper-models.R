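# shared fixtures built in code
sr_plant <- build_plant()
sr_mus <- default_muscles()

# short-episode configuration used where a full 110-s run is unnecessary
short_config <- function(t_total = 8, horizon = 5, ...) {
  episode_config(t_total = t_total, horizon = horizon, ...)
}

# a smooth synthetic trajectory table (evaluation dialect) built from sums of
# sinusoids; deterministic given the seed
toy_trajectory <- function(duration = 20, fs = 100, seed = 1, scale = 1) {
  set.seed(seed)
  tt <- seq(0, duration, by = 1 / fs)
  mk <- function(amp) {
    f <- runif(3, 0.1, 2); ph <- runif(3, 0, 2 * pi)
    amp * (sin(2 * pi * f[1] * tt + ph[1]) + 0.5 * sin(2 * pi * f[2] * tt + ph[2]) +
             0.25 * sin(2 * pi * f[3] * tt + ph[3]))
  }
  tibble::tibble(
    time_s = tt,
    hip_deg = mk(3 * scale), knee_deg = mk(4 * scale), ankle_deg = mk(2 * scale),
    hip_Nm = mk(10 * scale), knee_Nm = mk(12 * scale), ankle_Nm = mk(20 * scale)
  )
}
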