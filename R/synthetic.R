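#' Measurement noise model for pseudo-experiments
#'
#' Band-limited Gaussian noise added to the noise-free simulated joint
#' angles and moments to emulate the measurement and inverse-dynamics noise
#' of processed experimental trajectories: white Gaussian noise low-pass
#' filtered (2nd-order Butterworth) at the stated bandwidth, then rescaled
#' to the stated standard deviation.
#'
#' The default magnitudes are calibrated to the model's signal content so
#' that pseudo-experiment correlations land in the strong-but-imperfect
#' band (r between roughly 0.9 and 1) where the evaluation tests are
#' sensitive to pipeline defects: perturbed-stance joint-angle excursions
#' have standard deviations of roughly 2-5 degrees (the ankle, held stiff
#' by the dead zone and tendon elasticity, is the smallest) and
#' joint-moment fluctuations of roughly 5-30 N m.  Sub-degree angle noise
#' is also what filtered marker-based kinematics typically carry.
#'
#' @param angle_sd angle noise SD (deg).
#' @param moment_sd moment noise SD (N m).
#' @param bandwidth noise bandwidth (Hz); must stay below the Nyquist rate
#'   of the output table.
#' @param seed RNG seed for the noise draws.
#' @return a named list.
#' @export
noise_model <- function(angle_sd = 0.6, moment_sd = 2, bandwidth = 5, seed = 1) {
  stopifnot(angle_sd >= 0, moment_sd >= 0, bandwidth > 0)
  list(angle_sd = angle_sd, moment_sd = moment_sd, bandwidth = bandwidth,
       seed = seed)
}

band_limited_noise <- function(n, fs, sd, bandwidth, ...) {
  if (sd == 0) return(rep(0, n))
  w <- stats::rnorm(n)
  f <- butterworth_lowpass(w, fs, fc = bandwidth)
  f * (sd / stats::sd(f))
}

#' Generate a pseudo-experimental dataset
#'
#' Runs one full episode with a reference controller and writes the joint
#' angle / moment trajectories in the evaluation CSV dialect at the output
#' rate, with band-limited measurement noise added.  This stands in for
#' processed perturbed-standing recordings so the evaluation stage can be
#' exercised without external data.
#'
#' @param plant,muscles,controller,signal,config,delays forwarded to
#'   [run_episode()].
#' @param noise a [noise_model()].
#' @param out_rate output sampling rate (Hz).
#' @param path optional CSV path to write.
#' @return the pseudo-experiment tibble (evaluation dialect), with the
#'   noise-free episode attached as attribute `"episode"`.
#' @export
pseudo_experiment <- function(plant, muscles, controller, signal,
                              noise = noise_model(), config = episode_config(),
                              delays = delay_table(), out_rate = 100,
                              path = NULL) {
  if (noise$bandwidth >= out_rate / 2)
    rlang::abort("noise bandwidth must stay below the output Nyquist rate")
  ep <- run_episode(plant, muscles, controller, signal, config, delays)
  if (ep$fell)
    rlang::abort(sprintf(
      "reference episode fell after %.2f s; pseudo-experiment generation aborted",
      ep$survived))
  tab <- as_trajectory_table(ep)
  tt <- seq(0, max(tab$time_s), by = 1 / out_rate)
  tab <- resample_to(tab, tt)
  set.seed(noise$seed)
  for (cn in trajectory_signals()$column) {
    sd_i <- if (grepl("_deg$", cn)) noise$angle_sd else noise$moment_sd
    tab[[cn]] <- tab[[cn]] + band_limited_noise(nrow(tab), out_rate, sd_i,
                                                noise$bandwidth)
  }
  if (!is.null(path)) write_trajectory_table(tab, path)
  attr(tab, "episode") <- ep
  tab
}

#' Paired pseudo-experiments for architecture discrimination
#'
#' Generates pseudo-experiments from two (or more) controller architectures
#' under the same perturbation signal, so the evaluation stage can be tested
#' for its ability to rank the generating architecture highest against its
#' own data.
#'
#' @param plant,muscles,signal,config,delays forwarded to [run_episode()].
#' @param controllers named list of `sr_controller`s (e.g. `length`,
#'   `force`).
#' @param noise a [noise_model()].
#' @return list with `pseudo` (named list of pseudo-experiment tables) and
#'   `sim` (named list of noise-free simulated tables).
#' @export
discrimination_fixture <- function(plant, muscles, controllers, signal,
                                   noise = noise_model(),
                                   config = episode_config(),
                                   delays = delay_table()) {
  if (length(controllers) < 2 || is.null(names(controllers)))
    rlang::abort("controllers must be a named list with at least two entries")
  pseudo <- list(); sim <- list()
  for (nm in names(controllers)) {
    if (!inherits(controllers[[nm]], "sr_controller"))
      rlang::abort(paste0("missing or invalid controller parameters for '", nm, "'"))
    pe <- pseudo_experiment(plant, muscles, controllers[[nm]], signal, noise,
                            config, delays)
    pseudo[[nm]] <- pe
    sim[[nm]] <- as_trajectory_table(attr(pe, "episode"))
  }
  list(pseudo = pseudo, sim = sim)
}

#' Write the small bundled test fixtures
#'
#' Regenerates the plain-text fixtures shipped with the package: a 10-s
#' perturbation signal, a 10-s simulated trajectory pair (noise-free and
#' noisy pseudo-experiment), and a small table for correlation checks.
#' Regeneration under the fixed seeds is byte-stable.
#'
#' @param dir output directory.
#' @return the paths written, invisibly.
#' @export
make_fixtures <- function(dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  sig <- generate_signal(seed = 42, duration = 10)
  p1 <- file.path(dir, "fixture_signal_10s.csv")
  write_signal_csv(sig, p1, dt = 0.01)
  plant <- build_plant()
  muscles <- default_muscles()
  ctrl <- calibrated_preset("base")
  cfg <- episode_config(t_total = 12, horizon = 10)
  round_tab <- function(tab) {
    for (cn in setdiff(names(tab), "time_s")) tab[[cn]] <- round(tab[[cn]], 6)
    tab
  }
  p2 <- file.path(dir, "fixture_sim_10s.csv")
  ep <- run_episode(plant, muscles, ctrl, sig, cfg)
  tab <- as_trajectory_table(ep)
  tab <- resample_to(tab, seq(0, max(tab$time_s), by = 0.02))  # 50 Hz fixture
  write_trajectory_table(round_tab(tab), p2)
  p3 <- file.path(dir, "fixture_pseudo_10s.csv")
  pe <- pseudo_experiment(plant, muscles, ctrl, sig, noise_model(seed = 7),
                          cfg, out_rate = 50)
  write_trajectory_table(round_tab(pe), p3)
  p4 <- file.path(dir, "fixture_pearson_toy.csv")
  set.seed(11)
  x <- round(stats::rnorm(10), 3)
  utils::write.csv(data.frame(x = x, y = round(2 * x + stats::rnorm(10, sd = 0.5), 3)),
                   p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
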