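#' Tidy an episode into a long trajectory tibble
#'
#' @param x an `sr_episode`.
#' @param ... unused.
#' @return long tibble with `time`, `variable`, `value`.
#' @export
tidy.sr_episode <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, -"time", names_to = "variable",
                      values_to = "value")
}

#' One-row episode summary
#'
#' @param x an `sr_episode`.
#' @param ... unused.
#' @return tibble with survived duration, fall flag, effort, the three
#'   constraint values and overall feasibility.
#' @export
glance.sr_episode <- function(x, ...) {
  cv <- constraint_values(x)
  tibble::tibble(
    survived = x$survived, fell = x$fell, effort = x$effort,
    duration = cv$value[1], chest_T = cv$value[2], excursion = cv$value[3],
    feasible = all(cv$satisfied)
  )
}

#' Tidy a PSO run into its iteration history
#' @param x an `sr_pso`.
#' @param ... unused.
#' @return tibble `iteration`, `best_violation`, `best_effort`.
#' @export
tidy.sr_pso <- function(x, ...) x$history

#' One-row PSO summary
#' @param x an `sr_pso`.
#' @param ... unused.
#' @export
glance.sr_pso <- function(x, ...) {
  tibble::tibble(evaluations = x$evaluations,
                 best_violation = x$best_score$violation,
                 best_effort = x$best_score$effort,
                 feasible = x$best_score$violation == 0)
}

#' Tidy a perturbation signal into its pulse table
#' @param x an `sr_signal`.
#' @param ... unused.
#' @export
tidy.sr_signal <- function(x, ...) {
  if (x$kind == "pulses") x$pulses else x$series
}
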