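#' Generate a random square-pulse platform perturbation signal
#'
#' The platform displacement is a sequence of square pulses with amplitudes
#' drawn i.i.d. uniformly from \{-5, -2.5, 0, 2.5, 5\} cm and durations drawn
#' i.i.d. uniformly from \{0.25, 0.5, 0.75, 1.0, 1.25, 1.5\} s, concatenated
#' until the requested total duration is covered.  In the default
#' `"absolute"` mode the platform position equals the pulse amplitude for the
#' pulse duration; in `"incremental"` mode amplitudes accumulate.  Pulse
#' edges are rate-limited (default 1 m/s) so the kinematically driven
#' platform has finite velocity.
#'
#' @param seed integer RNG seed; the signal is reproducible given the seed.
#' @param duration total signal duration (s), > 0.
#' @param mode `"absolute"` (default) or `"incremental"` amplitude semantics.
#' @param rate_limit maximum platform speed during pulse edges (m/s).
#' @return an `sr_signal` with a `pulses` tibble (`amplitude` m, `duration`
#'   s, `t_start` s, `position` m after the pulse edge).
#' @examples
#' sig <- generate_signal(seed = 1, duration = 20)
#' position_at(sig, c(0, 5, 10))
#' @export
generate_signal <- function(seed, duration = 110, mode = c("absolute", "incremental"),
                            rate_limit = 1) {
  mode <- match.arg(mode)
  if (duration <= 0) rlang::abort("duration must be > 0")
  amplitudes <- c(-0.05, -0.025, 0, 0.025, 0.05)
  durations <- c(0.25, 0.5, 0.75, 1.0, 1.25, 1.5)
  amp <- numeric(0); dur <- numeric(0)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  withr_seed(function() {
    total <- 0
    while (total < duration) {
      amp <<- c(amp, sample(amplitudes, 1))
      d <- sample(durations, 1)
      dur <<- c(dur, d)
      total <- total + d
    }
  })
  pos <- if (mode == "absolute") amp else cumsum(amp)
  sig <- list(
    pulses = tibble::tibble(amplitude = amp, duration = dur,
                            t_start = cumsum(c(0, dur[-length(dur)])),
                            position = pos),
    total_duration = duration, seed = seed, mode = mode,
    rate_limit = rate_limit, kind = "pulses"
  )
  class(sig) <- "sr_signal"
  sig
}

#' @export
print.sr_signal <- function(x, ...) {
  if (x$kind == "pulses")
    cat(sprintf("<sr_signal> %d square pulses, %.1f s, seed %s, %s mode\n",
                nrow(x$pulses), x$total_duration, format(x$seed), x$mode))
  else
    cat(sprintf("<sr_signal> sampled series, %.1f s, %d samples\n",
                x$total_duration, nrow(x$series)))
  invisible(x)
}

#' Platform position at given times
#'
#' Right-continuous at pulse boundaries; pulse edges are linear ramps at the
#' signal's rate limit.  Times outside `[0, duration]` are an error.
#'
#' @param signal an `sr_signal`.
#' @param t numeric vector of times (s).
#' @return platform positions (m).
#' @export
position_at <- function(signal, t) {
  if (any(t < 0 | t > signal$total_duration))
    rlang::abort("t outside the signal's time range")
  if (signal$kind == "sampled") {
    return(stats::approx(signal$series$time_s, signal$series$position_m,
                         xout = t, rule = 1)$y)
  }
  p <- signal$pulses
  idx <- findInterval(t, p$t_start)
  idx[idx < 1] <- 1L
  prev <- c(0, p$position[-nrow(p)])  # position held before each pulse starts
  from <- prev[idx]
  to <- p$position[idx]
  ramp <- signal$rate_limit * (t - p$t_start[idx])
  from + sign(to - from) * pmin(abs(to - from), ramp)
}

#' Platform position series sampled at a fixed step
#'
#' @param signal an `sr_signal`.
#' @param dt sampling step (s).
#' @return tibble `time_s`, `position_m` covering `[0, duration]`.
#' @export
signal_series <- function(signal, dt) {
  tt <- seq(0, signal$total_duration, by = dt)
  tibble::tibble(time_s = tt, position_m = position_at(signal, tt))
}

#' Save / load a perturbation signal as a two-column CSV
#'
#' The on-disk dialect is `time_s,position_m`.  A loaded signal is a sampled
#' series (linear interpolation between samples); saving then loading a
#' sampled signal is lossless.
#'
#' @param signal an `sr_signal`.
#' @param path file path.
#' @param dt sampling step used when saving a pulse-based signal.
#' @export
write_signal_csv <- function(signal, path, dt = 0.01) {
  d <- if (signal$kind == "sampled") signal$series else signal_series(signal, dt)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @return `read_signal_csv` returns an `sr_signal` of kind `"sampled"`.
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0) rlang::abort("empty signal file")
  if (!all(c("time_s", "position_m") %in% names(d)))
    rlang::abort("signal CSV must have columns time_s, position_m")
  if (any(diff(d$time_s) <= 0)) rlang::abort("signal time column must be strictly increasing")
  sig <- list(series = tibble::as_tibble(d),
              total_duration = max(d$time_s) - min(d$time_s),
              seed = NA_integer_, mode = "sampled", rate_limit = NA_real_,
              kind = "sampled")
  if (min(d$time_s) != 0) {
    sig$series$time_s <- sig$series$time_s - min(d$time_s)
  }
  class(sig) <- "sr_signal"
  sig
}

#' Extract a time window from a signal
#'
#' Used to start an episode at an arbitrary offset of a longer recorded
#' platform trace.
#'
#' @param signal an `sr_signal`.
#' @param start window start time (s).
#' @param duration window length (s).
#' @return an `sr_signal` of kind `"sampled"` re-based to start at 0.
#' @export
signal_window <- function(signal, start, duration) {
  if (start < 0 || start + duration > signal$total_duration + 1e-9)
    rlang::abort("window outside the signal's time range")
  if (signal$kind == "sampled") {
    d <- signal$series
    keep <- d$time_s >= start - 1e-12 & d$time_s <= start + duration + 1e-12
    ser <- d[keep, ]
    ser$time_s <- ser$time_s - start
  } else {
    dt <- 0.01
    tt <- seq(0, duration, by = dt)
    ser <- tibble::tibble(time_s = tt, position_m = position_at(signal, start + tt))
  }
  out <- list(series = ser, total_duration = duration, seed = signal$seed,
              mode = "sampled", rate_limit = signal$rate_limit, kind = "sampled")
  class(out) <- "sr_signal"
  out
}
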