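#' Episode configuration
#'
#' The simulation protocol: 1 s of joint-angle (PD) control so the muscles
#' can find an equilibrium, 1 s of quiet muscle-controlled stance, then the
#' platform perturbation until the episode reaches `t_total` (default 110 s).
#' The episode stops early if the chest drops below `chest_fall` (0.7 m).
#' The evaluation horizon of `horizon` (100 s) starts at perturbation onset
#' (`t_pd + t_quiet` = 2 s of simulated time), so effort and the upright
#' constraints are evaluated over simulation time `[2, 102]` s.
#'
#' @param dt integrator step (s); reflex delays must be integer multiples.
#' @param t_pd duration of the joint-angle control phase (s).
#' @param t_quiet duration of the quiet muscle-control phase (s).
#' @param t_total total episode duration (s).
#' @param horizon evaluation horizon T (s), counted from perturbation onset.
#' @param chest_fall chest height (m) below which the model counts as fallen.
#' @param chest_min required chest height (m) at the end of the horizon.
#' @param excursion_max allowed mean absolute ankle displacement (m).
#' @param pd_kp,pd_kd phase-1 PD gains per joint (hip, knee, ankle).
#' @param posture named numeric `hip`, `knee` flexion (rad) of the initial
#'   slightly flexed stance (ankle follows to keep the feet flat).
#' @param com_ahead initial COM position ahead of the ankle (m).
#' @param log_rate trajectory output rate (Hz).
#' @return a list of class `sr_episode_config`.
#' @export
episode_config <- function(dt = 5e-4, t_pd = 1, t_quiet = 1, t_total = 110,
                           horizon = 100, chest_fall = 0.7, chest_min = 1.3,
                           excursion_max = 0.05,
                           pd_kp = c(3000, 3000, 2000), pd_kd = c(60, 60, 30),
                           posture = c(hip = 0.04, knee = 0.08),
                           com_ahead = 0.05, log_rate = 100) {
  stopifnot(dt > 0, t_pd + t_quiet < t_total, horizon <= t_total - t_pd - t_quiet)
  structure(list(dt = dt, t_pd = t_pd, t_quiet = t_quiet, t_total = t_total,
                 horizon = horizon, chest_fall = chest_fall,
                 chest_min = chest_min, excursion_max = excursion_max,
                 pd_kp = pd_kp, pd_kd = pd_kd, posture = posture,
                 com_ahead = com_ahead, log_rate = log_rate),
            class = "sr_episode_config")
}

delay_steps <- function(delays, dt) {
  steps <- delays$delay_ms / 1000 / dt
  if (any(abs(steps - round(steps)) > 1e-9))
    rlang::abort("reflex delays must be integer multiples of dt")
  if (any(round(steps) < 1))
    rlang::abort("reflex delays must be at least one integrator step")
  as.integer(round(steps))
}

#' Run one full perturbed-standing episode
#'
#' Simulates the protocol (PD phase, quiet stance, perturbation) with the
#' given controller and returns trajectories, the survived duration, the
#' effort objective and the upright-stance constraint values.  The episode
#' is fully deterministic given its inputs.
#'
#' @param plant an `sr_plant` from [build_plant()].
#' @param muscles muscle table from [default_muscles()].
#' @param controller an `sr_controller`.
#' @param signal an `sr_signal` (its time 0 is mapped to perturbation onset);
#'   `NULL` runs quiet stance throughout.
#' @param config an [episode_config()].
#' @param delays delay table (tibble `muscle`, `delay_ms`), default
#'   [delay_table()].
#' @return an `sr_episode`: list with `trajectory` (tibble at `log_rate`,
#'   angles in rad and moments in N m averaged over legs, COM, chest height,
#'   ankle excursion, vertical GRF, platform position, summed squared
#'   activation), `survived` (s), `fell`, `effort`, `chest_T`, `excursion`,
#'   and the configuration used.
#' @examples
#' \dontrun{
#' plant <- build_plant()
#' ep <- run_episode(plant, default_muscles(), calibrated_preset("base"),
#'                   generate_signal(1, 108), episode_config(t_total = 12))
#' glance(ep)
#' }
#' @export
run_episode <- function(plant, muscles, controller, signal = NULL,
                        config = episode_config(), delays = delay_table()) {
  validate_controller(controller)
  mm <- muscle_matrix(muscles)
  g <- controller$gains
  ord <- match(muscles$muscle, g$muscle)
  if (any(is.na(ord)))
    rlang::abort("controller gains must cover every muscle in the muscle table")
  dord <- match(muscles$muscle, delays$muscle)
  if (any(is.na(dord))) rlang::abort("delay table must cover every muscle")
  dsteps <- delay_steps(delays[dord, ], config$dt)
  com_steps <- controller$com_delay / config$dt
  if (abs(com_steps - round(com_steps)) > 1e-9)
    rlang::abort("COM trigger delay must be an integer multiple of dt")

  st <- standing_state(plant, hip = config$posture[["hip"]],
                       knee = config$posture[["knee"]],
                       com_ahead = config$com_ahead)
  dz <- controller$deadzone
  # validate dead-zone ordering against the initial foot geometry
  pts <- body_points(plant, st)
  heel_x <- mean(pts$x[pts$point %in% c("heel_l", "heel_r")])
  toe_x <- mean(pts$x[pts$point %in% c("toe_l", "toe_r")])
  if (heel_x + dz[["x_heel"]] >= toe_x - dz[["x_toe"]])
    rlang::abort("ill-ordered dead-zone edges for this foot geometry")

  n_steps <- round(config$t_total / config$dt)
  onset <- config$t_pd + config$t_quiet
  tt <- seq(0, n_steps) * config$dt
  plat <- numeric(n_steps + 1)
  if (!is.null(signal)) {
    after <- tt >= onset
    ts <- pmin(tt[after] - onset, signal$total_duration)
    plat[after] <- position_at(signal, ts)
  }
  ctrl_list <- list(
    u0 = g$u0[ord], g_ffb = g$g_ffb[ord], g_lfb = g$g_lfb[ord],
    l_off = g$l_off[ord],
    x_heel = dz[["x_heel"]], x_toe = dz[["x_toe"]],
    z_heel = dz[["z_heel"]], z_toe = dz[["z_toe"]],
    delay_steps = dsteps, com_delay_steps = as.integer(round(com_steps))
  )
  cfg_list <- list(
    dt = config$dt, t_pd = config$t_pd, t_quiet = config$t_quiet,
    t_total = config$t_total, chest_fall = config$chest_fall,
    horizon = config$horizon, pd_kp = config$pd_kp, pd_kd = config$pd_kd,
    q0 = st$q, log_every = as.integer(round(1 / (config$log_rate * config$dt)))
  )
  res <- rs_run_episode_cpp(unclass(plant), mm, ctrl_list, cfg_list, plat)
  out <- list(
    trajectory = tibble::as_tibble(res$trajectory),
    survived = res$survived, fell = res$fell, effort = res$effort,
    excursion = res$excursion, chest_T = res$chest_T,
    clip_count = res$clip_count,
    config = config, controller = controller, onset = onset
  )
  class(out) <- "sr_episode"
  out
}

#' @export
print.sr_episode <- function(x, ...) {
  cat(sprintf("<sr_episode> %s after %.2f s (of %.0f s); effort %.3f\n",
              if (x$fell) "fell" else "stood", x$survived, x$config$t_total,
              x$effort))
  print(constraint_values(x))
  invisible(x)
}

#' Effort objective from activation trajectories
#'
#' Time-averaged summed squared activation,
#' `f = (1/T) * integral sum_i a_i(t)^2 dt`, evaluated with the trapezoid
#' rule over the horizon.
#'
#' @param activations a tibble with a `time` column and one column per
#'   muscle (activations in `[0, 1]`), or an `sr_episode` (which carries the
#'   pre-summed squared activations).
#' @param horizon averaging period T (s); defaults to the covered time span.
#' @return the effort value (>= 0).
#' @export
effort <- function(activations, horizon = NULL) {
  if (inherits(activations, "sr_episode")) {
    ep <- activations
    tr <- ep$trajectory
    keep <- tr$time >= ep$onset & tr$time <= ep$onset + ep$config$horizon
    d <- tibble::tibble(time = tr$time[keep], total = tr$sum_a2[keep])
    if (is.null(horizon)) horizon <- ep$config$horizon
  } else {
    a <- as.data.frame(activations)
    stopifnot("time" %in% names(a))
    vals <- as.matrix(a[setdiff(names(a), "time")])
    if (any(vals < 0 | vals > 1)) rlang::abort("activations must be in [0, 1]")
    d <- tibble::tibble(time = a$time, total = rowSums(vals^2))
    if (is.null(horizon)) horizon <- max(a$time) - min(a$time)
  }
  if (nrow(d) < 2) return(0)
  dt <- diff(d$time)
  sum(0.5 * (d$total[-1] + d$total[-nrow(d)]) * dt) / horizon
}

#' Upright-stance constraint values
#'
#' The three feasibility constraints on an episode: survived duration after
#' perturbation onset (must exceed the 100 s horizon), chest height at the
#' end of the horizon (must exceed 1.3 m), and mean absolute ankle
#' displacement relative to the platform (must stay below 0.05 m).
#'
#' @param episode an `sr_episode`.
#' @return tibble with `constraint`, `value`, `bound`, `satisfied`.
#' @export
constraint_values <- function(episode) {
  cfg <- episode$config
  dur <- episode$survived - episode$onset
  chest <- if (is.finite(episode$chest_T)) episode$chest_T else {
    tr <- episode$trajectory
    tr$chest_y[nrow(tr)]
  }
  tibble::tibble(
    constraint = c("duration", "chest_height", "ankle_excursion"),
    value = c(dur, chest, episode$excursion),
    bound = c(cfg$horizon, cfg$chest_min, cfg$excursion_max),
    satisfied = c(dur >= cfg$horizon, chest > cfg$chest_min,
                  episode$excursion < cfg$excursion_max)
  )
}

#' Normalized total constraint violation
#'
#' Sum of the per-constraint shortfalls, each normalized by its bound; zero
#' for a feasible episode.  This is the tier-1 quantity of the lexicographic
#' optimization score.
#'
#' @param episode an `sr_episode`.
#' @return non-negative violation.
#' @export
constraint_violation <- function(episode) {
  cv <- constraint_values(episode)
  shortfall <- c(max(0, cv$bound[1] - cv$value[1]) / cv$bound[1],
                 max(0, cv$bound[2] - cv$value[2]) / cv$bound[2],
                 max(0, cv$value[3] - cv$bound[3]) / cv$bound[3])
  sum(shortfall)
}

#' Export an episode trajectory as the plant CSV dialect
#'
#' Columns `time,trunk_x,trunk_y,trunk_pitch,hip,knee,ankle,com_x,com_y,
#' chest_y,ankle_x,grf_y` with all angles in degrees.
#'
#' @param episode an `sr_episode`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(episode, path) {
  tr <- episode$trajectory
  d <- data.frame(
    time = tr$time, trunk_x = tr$trunk_x, trunk_y = tr$trunk_y,
    trunk_pitch = tr$trunk_pitch * 180 / pi,
    hip = tr$hip * 180 / pi, knee = tr$knee * 180 / pi,
    ankle = tr$ankle * 180 / pi,
    com_x = tr$com_x, com_y = tr$com_y, chest_y = tr$chest_y,
    ankle_x = tr$ankle_x, grf_y = tr$grf_y
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Episode as an evaluation trajectory table
#'
#' Converts an episode to the comparison dialect used by [compare_trajectories()]:
#' `time_s, hip_deg, knee_deg, ankle_deg, hip_Nm, knee_Nm, ankle_Nm`, with
#' time measured from perturbation onset and moments averaged over legs.
#'
#' @param episode an `sr_episode`.
#' @param from,to time window in episode time (s); defaults to the
#'   evaluation horizon.
#' @return a tibble in the evaluation dialect.
#' @export
as_trajectory_table <- function(episode, from = NULL, to = NULL) {
  tr <- episode$trajectory
  if (is.null(from)) from <- episode$onset
  if (is.null(to)) to <- episode$onset + episode$config$horizon
  keep <- tr$time >= from - 1e-9 & tr$time <= to + 1e-9
  tibble::tibble(
    time_s = tr$time[keep] - from,
    hip_deg = tr$hip[keep] * 180 / pi,
    knee_deg = tr$knee[keep] * 180 / pi,
    ankle_deg = tr$ankle[keep] * 180 / pi,
    hip_Nm = tr$hip_moment[keep],
    knee_Nm = tr$knee_moment[keep],
    ankle_Nm = tr$ankle_moment[keep]
  )
}
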