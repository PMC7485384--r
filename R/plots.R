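#' Plot an episode's joint angles, moments and platform motion
#'
#' @param object an `sr_episode`.
#' @param ... unused.
#' @return a ggplot with one facet per signal.
#' @export
autoplot.sr_episode <- function(object, ...) {
  tr <- object$trajectory
  d <- tibble::tibble(
    time = rep(tr$time, 7),
    value = c(tr$hip * 180 / pi, tr$knee * 180 / pi, tr$ankle * 180 / pi,
              tr$hip_moment, tr$knee_moment, tr$ankle_moment,
              tr$platform_x * 100),
    signal = rep(c("hip angle [deg]", "knee angle [deg]", "ankle angle [deg]",
                   "hip moment [Nm]", "knee moment [Nm]", "ankle moment [Nm]",
                   "platform [cm]"), each = nrow(tr))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation signal
#'
#' @param object an `sr_signal`.
#' @param dt sampling step for rendering.
#' @param ... unused.
#' @export
autoplot.sr_signal <- function(object, dt = 0.01, ...) {
  d <- signal_series(object, dt)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = 100 * .data$position_m)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "platform position [cm]") +
    ggplot2::theme_minimal()
}

#' Plot a comparison report
#'
#' @param object an `sr_comparison` from [compare_trajectories()].
#' @param ... unused.
#' @return bar chart of Pearson r per signal.
#' @export
autoplot.sr_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$signal <- factor(d$column, levels = trajectory_signals()$column)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signal, y = .data$r, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Plot the dead-zone gain gate
#'
#' Shows the effective-gain factor as a function of COM position for a
#' controller, with the heel/toe contact points marked.
#'
#' @param ctrl an `sr_controller`.
#' @param heel_x,toe_x contact point positions (m).
#' @param n grid resolution.
#' @return a ggplot.
#' @export
plot_deadzone <- function(ctrl, heel_x = -0.068, toe_x = 0.205, n = 400) {
  xs <- seq(heel_x - 0.05, toe_x + 0.05, length.out = n)
  d <- tibble::tibble(x_com = xs,
                      gate = effective_gain(xs, heel_x, toe_x, ctrl$deadzone))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_com, y = .data$gate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(heel_x, toe_x), linetype = 2) +
    ggplot2::labs(x = "COM x [m] (platform frame)",
                  y = "gain gate [-1, 1]") +
    ggplot2::theme_minimal()
}
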