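#' Reflex time delays
#'
#' Default per-muscle loop delays between a proprioceptive stimulus and the
#' stimulation response, from EMG latency literature: tibialis anterior
#' 35 ms, soleus 44 ms, gastrocnemius 54 ms, vastus 100 ms, biceps femoris
#' short and long head 60 ms, rectus femoris 82 ms, gluteals and iliopsoas
#' 40 ms.
#'
#' @return tibble with `muscle` and `delay_ms`.
#' @export
delay_table <- function() {
  tibble::tibble(
    muscle = c("iliopsoas", "gluteals", "rectus_femoris", "biceps_femoris_lh",
               "biceps_femoris_sh", "vastus", "gastrocnemius", "soleus",
               "tibialis_anterior"),
    delay_ms = c(40, 40, 82, 60, 60, 100, 54, 44, 35)
  )
}

#' Reflex controller parameter presets
#'
#' Published optimized parameter sets for the three controller
#' architectures: `base` (force and length feedback), `length` (length
#' feedback only) and `force` (force feedback only).  Each set holds, per
#' muscle, the feedforward input `u0`, the force-feedback gain `g_ffb` (per
#' unit F/F_max), the length-feedback gain `g_lfb` (per unit l_CE/l_opt) and
#' the normalized length offset `l_off`, plus the four dead-zone parameters.
#' `controller_preset()` returns them as an `sr_controller`.
#'
#' These literature values were identified on a different physics engine and
#' anthropometry; [calibrated_preset()] returns parameter sets re-optimized
#' for this package's plant, which are the ones that keep this model upright.
#'
#' @param architecture `"base"`, `"length"` or `"force"`.
#' @param com_delay optional delay (s) on the COM signal gating the dead zone
#'   (0, 0.020 or 0.100 in the study variants).
#' @return an `sr_controller`: list with `gains` tibble (muscle, u0, g_ffb,
#'   g_lfb, l_off), `deadzone` (named numeric x_heel, x_toe, z_heel, z_toe,
#'   distances in m, transitions dimensionless), `architecture`, `com_delay`.
#' @export
controller_preset <- function(architecture = c("base", "length", "force"),
                              com_delay = 0) {
  architecture <- match.arg(architecture)
  mus <- c("iliopsoas", "gluteals", "rectus_femoris", "biceps_femoris_lh",
           "biceps_femoris_sh", "vastus", "gastrocnemius", "soleus",
           "tibialis_anterior")
  u0 <- list(
    base   = c(0.25, 0.14, 0.093, 0.26, 0.11, 0.26, 0.13, 0.26, 0.062),
    length = c(0.20, 0.034, 0.20, 0.32, 0.16, 0.24, 0.067, 0.33, 0.0076),
    force  = c(0.21, 0.14, 0.17, 0.30, 0.12, 0.30, 0.17, 0.21, 0.045)
  )
  g_ffb <- list(
    base   = c(1.01, 0.89, 0.24, 0.53, 0.25, -0.23, 0.27, 1.50, -1.11),
    length = rep(0, 9),
    force  = c(0.31, 1.38, 0.50, 0.11, 0.48, 0.031, 0.31, 1.36, -1.45)
  )
  g_lfb <- list(
    base   = c(0.72, 0.029, -0.54, -1.07, 0.66, 0.21, -0.23, 0.29, -0.19),
    length = c(0.23, -0.45, 0.12, -0.28, 0.22, -0.042, -0.63, 1.15, -0.38),
    force  = rep(0, 9)
  )
  l_off <- list(
    base   = c(1.02, 0.94, 0.64, 0.67, 0.76, 0.39, 0.86, 0.98, 1.09),
    length = c(0.52, 0.73, 0.67, 0.86, 0.26, 0.58, 0.86, 0.50, 0.70),
    force  = rep(0.65, 9)  # unused: force architecture has no length feedback
  )
  dz <- list(
    base   = c(x_heel = 0.0574, x_toe = 0.0124, z_heel = 0.15, z_toe = 0.71),
    length = c(x_heel = 0.0660, x_toe = 0.0266, z_heel = 0.27, z_toe = 0.67),
    force  = c(x_heel = 0.0599, x_toe = 0.0182, z_heel = 0.32, z_toe = 0.53)
  )
  new_controller(
    gains = tibble::tibble(muscle = mus, u0 = u0[[architecture]],
                           g_ffb = g_ffb[[architecture]],
                           g_lfb = g_lfb[[architecture]],
                           l_off = l_off[[architecture]]),
    deadzone = dz[[architecture]],
    architecture = architecture, com_delay = com_delay
  )
}

new_controller <- function(gains, deadzone, architecture, com_delay = 0) {
  x <- list(gains = gains, deadzone = deadzone, architecture = architecture,
            com_delay = com_delay)
  class(x) <- "sr_controller"
  validate_controller(x)
  x
}

validate_controller <- function(ctrl) {
  g <- ctrl$gains
  stopifnot(is.data.frame(g), nrow(g) == 9)
  if (any(g$u0 < 0.001 - 1e-12 | g$u0 > 1))
    rlang::abort("u0 out of bounds [0.001, 1]")
  if (any(abs(g$g_ffb) > 3 + 1e-12) || any(abs(g$g_lfb) > 3 + 1e-12))
    rlang::abort("feedback gains out of bounds [-3, 3]")
  dz <- ctrl$deadzone
  if (any(dz[c("x_heel", "x_toe")] < 0 | dz[c("x_heel", "x_toe")] > 0.10))
    rlang::abort("dead-zone distances must be within 10 cm of the contact points")
  if (any(dz[c("z_heel", "z_toe")] < 0 | dz[c("z_heel", "z_toe")] > 1))
    rlang::abort("dead-zone transitions must be in [0, 1]")
  invisible(ctrl)
}

#' @export
print.sr_controller <- function(x, ...) {
  cat(sprintf("<sr_controller> architecture '%s', COM delay %g ms\n",
              x$architecture, 1000 * x$com_delay))
  cat(sprintf("  dead zone: x_heel %.1f cm, x_toe %.1f cm, z_heel %.2f, z_toe %.2f\n",
              100 * x$deadzone["x_heel"], 100 * x$deadzone["x_toe"],
              x$deadzone["z_heel"], x$deadzone["z_toe"]))
  print(x$gains)
  invisible(x)
}

#' Apply an architecture to a parameter set
#'
#' The length-only architecture zeroes all force-feedback gains; the
#' force-only architecture zeroes all length-feedback gains.
#'
#' @param ctrl an `sr_controller`.
#' @param architecture target architecture.
#' @return the gated `sr_controller`.
#' @export
apply_architecture <- function(ctrl, architecture = c("base", "length", "force")) {
  architecture <- match.arg(architecture)
  if (architecture == "length") ctrl$gains$g_ffb <- rep(0, 9)
  if (architecture == "force") ctrl$gains$g_lfb <- rep(0, 9)
  ctrl$architecture <- architecture
  ctrl
}

#' Force feedback stimulation (Golgi tendon organ pathway)
#'
#' `u_ffb = g_eff * F_see(t - dt) / F_max` on the delayed, F_max-normalized
#' tendon force.
#'
#' @param f_norm delayed normalized SEE force (>= 0).
#' @param gain effective (dead-zone-gated) gain.
#' @return stimulation contribution (may be negative; clamped later).
#' @export
force_feedback <- function(f_norm, gain) {
  if (any(f_norm < 0)) rlang::abort("normalized force must be >= 0")
  gain * f_norm
}

#' Length feedback stimulation (muscle spindle pathway)
#'
#' `u_lfb = g_eff * (l_ce(t - dt)/l_opt - l_off)` when the delayed
#' normalized CE length exceeds the offset, else 0.
#'
#' @param l_norm delayed normalized CE length (> 0).
#' @param l_off normalized length offset.
#' @param gain effective (dead-zone-gated) gain.
#' @return stimulation contribution.
#' @export
length_feedback <- function(l_norm, l_off, gain) {
  if (any(l_norm <= 0)) rlang::abort("normalized length must be > 0")
  ifelse(l_norm > l_off, gain * (l_norm - l_off), 0)
}

#' Dead-zone-gated effective gain
#'
#' Piecewise-linear intermittent-control gate on the COM position inside the
#' base of support.  Let `b_h = heel_x + x_heel` and `b_t = toe_x - x_toe` be
#' the dead-zone edges (distances measured inward from the heel and toe
#' contact points, in the platform frame).  The effective gain is `-G` fully
#' beyond the heel-side transition band of width `z_heel * x_heel`, ramps
#' linearly to 0 at `b_h`, is 0 across the dead zone, ramps from 0 to `+G`
#' over the toe transition band of width `z_toe * x_toe`, and is `+G`
#' beyond.  It is continuous in the COM position.
#'
#' @param x_com COM x in the platform frame (vectorized).
#' @param heel_x,toe_x heel and toe contact point x in the same frame.
#' @param deadzone named numeric with `x_heel`, `x_toe`, `z_heel`, `z_toe`.
#' @param gain the muscle's feedback gain G.
#' @return the effective gain at each COM position.
#' @export
effective_gain <- function(x_com, heel_x, toe_x, deadzone, gain = 1) {
  b_h <- heel_x + deadzone[["x_heel"]]
  b_t <- toe_x - deadzone[["x_toe"]]
  if (b_h >= b_t)
    rlang::abort("ill-ordered dead-zone edges: heel edge must lie below toe edge")
  gain * vapply(x_com, function(x)
    rs_gate_cpp(x, heel_x, toe_x, deadzone[["x_heel"]], deadzone[["x_toe"]],
                deadzone[["z_heel"]], deadzone[["z_toe"]]), numeric(1))
}

#' Fixed-lag delayed signal channel
#'
#' A ring buffer guaranteeing an exact lag of `delay` (an integer multiple of
#' the simulation step).  Reads before `delay` has elapsed return the initial
#' value.
#'
#' @param delay delay in s.
#' @param dt simulation step in s; `delay/dt` must be integral.
#' @param init initial value returned before the buffer fills.
#' @return an `sr_channel` object.
#' @export
delayed_channel <- function(delay, dt, init = 0) {
  steps <- delay / dt
  if (abs(steps - round(steps)) > 1e-9)
    rlang::abort(sprintf("delay %g s is not an integer multiple of dt = %g s", delay, dt))
  steps <- as.integer(round(steps))
  env <- new.env(parent = emptyenv())
  env$buf <- rep(init, max(steps, 1))
  env$head <- length(env$buf)
  env$steps <- steps
  class(env) <- "sr_channel"
  env
}

#' Push a sample into a delayed channel
#' @param channel an `sr_channel`.
#' @param value the sample recorded at the current step.
#' @return the channel, invisibly.
#' @export
channel_push <- function(channel, value) {
  channel$head <- channel$head %% length(channel$buf) + 1L
  channel$buf[channel$head] <- value
  invisible(channel)
}

#' Read the delayed value from a channel
#'
#' Returns the sample recorded exactly `delay` steps ago.  With zero delay,
#' reading after a push returns the pushed value (identity).  Call *before*
#' pushing the current step's sample.
#'
#' @param channel an `sr_channel`.
#' @return the lagged sample.
#' @export
delayed_read <- function(channel) {
  if (channel$steps == 0L) return(channel$buf[channel$head])
  channel$buf[channel$head %% length(channel$buf) + 1L]
}

#' Total muscle stimulation
#'
#' Sum of the feedforward input and the two reflex contributions, clamped to
#' `[0.001, 1]`.
#'
#' @param u0 feedforward input.
#' @param u_ffb,u_lfb force- and length-feedback contributions.
#' @return stimulation in `[0.001, 1]`.
#' @export
stimulation <- function(u0, u_ffb = 0, u_lfb = 0) {
  pmin(1, pmax(0.001, u0 + u_ffb + u_lfb))
}

#' One controller evaluation
#'
#' Computes the per-muscle stimulations for both legs from delayed sensor
#' values and the COM-gated dead zone.  Parameters are identical in the left
#' and right leg; only the sensor values differ.
#'
#' @param ctrl an `sr_controller`.
#' @param sensors tibble with columns `muscle`, `leg` (`"left"`/`"right"`),
#'   `f_norm` (delayed SEE force / F_max) and `l_norm` (delayed CE length /
#'   l_opt).
#' @param x_com COM x (platform frame; already delayed if the architecture
#'   uses a COM trigger delay).
#' @param heel_x,toe_x contact point x positions in the same frame.
#' @return the sensors tibble with added columns `u_ffb`, `u_lfb`, `u`.
#' @export
controller_step <- function(ctrl, sensors, x_com, heel_x, toe_x) {
  gate <- effective_gain(x_com, heel_x, toe_x, ctrl$deadzone, gain = 1)
  g <- ctrl$gains
  i <- match(sensors$muscle, g$muscle)
  if (any(is.na(i))) rlang::abort("sensors contain unknown muscle names")
  u_ffb <- force_feedback(sensors$f_norm, gate * g$g_ffb[i])
  u_lfb <- length_feedback(sensors$l_norm, g$l_off[i], gate * g$g_lfb[i])
  dplyr::mutate(sensors, u_ffb = u_ffb, u_lfb = u_lfb,
                u = stimulation(g$u0[i], u_ffb, u_lfb))
}

#' Write / read a controller parameter CSV
#'
#' One row per muscle (u0, g_ffb, g_lfb, l_off) followed by four rows whose
#' `muscle` column names the dead-zone parameter.
#'
#' @param ctrl an `sr_controller`.
#' @param path file path.
#' @return `read_controller_csv` returns an `sr_controller`.
#' @export
write_controller_csv <- function(ctrl, path) {
  g <- ctrl$gains
  dz <- ctrl$deadzone
  extra <- tibble::tibble(muscle = paste0("deadzone_", names(dz)),
                          u0 = unname(dz), g_ffb = NA_real_, g_lfb = NA_real_,
                          l_off = NA_real_)
  utils::write.csv(rbind(g, extra), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_controller_csv
#' @param architecture architecture tag to attach on read.
#' @export
read_controller_csv <- function(path, architecture = "base") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  is_dz <- grepl("^deadzone_", d$muscle)
  dz <- stats::setNames(d$u0[is_dz], sub("^deadzone_", "", d$muscle[is_dz]))
  new_controller(tibble::as_tibble(d[!is_dz, ]), dz[c("x_heel", "x_toe", "z_heel", "z_toe")],
                 architecture)
}
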