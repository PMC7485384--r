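#' Optimization bounds for a controller architecture
#'
#' The decision vector z holds, per muscle, the feedforward input u0
#' (bounded to `[0.001, 1]`), the force-feedback gain (only if the
#' architecture uses force feedback; `[-3, 3]`), the length-feedback gain
#' and normalized length offset (only with length feedback; `[-3, 3]` and
#' `[0.2, 1.1]`), plus the four dead-zone parameters (edge distances within
#' 10 cm of the contact points, transition fractions in `[0, 1]`).  This
#' yields 40 parameters for the base architecture, 31 for length-only and 22
#' for force-only.
#'
#' @param architecture `"base"`, `"length"` or `"force"`.
#' @return tibble with `param`, `muscle` (NA for dead-zone entries), `lower`,
#'   `upper`.
#' @export
make_bounds <- function(architecture = c("base", "length", "force")) {
  architecture <- match.arg(architecture)
  mus <- muscle_names()
  rows <- list(tibble::tibble(param = "u0", muscle = mus, lower = 0.001, upper = 1))
  if (architecture %in% c("base", "force"))
    rows <- c(rows, list(tibble::tibble(param = "g_ffb", muscle = mus, lower = -3, upper = 3)))
  if (architecture %in% c("base", "length")) {
    rows <- c(rows, list(tibble::tibble(param = "g_lfb", muscle = mus, lower = -3, upper = 3)))
    rows <- c(rows, list(tibble::tibble(param = "l_off", muscle = mus, lower = 0.2, upper = 1.1)))
  }
  rows <- c(rows, list(tibble::tibble(
    param = c("x_toe", "x_heel", "z_toe", "z_heel"), muscle = NA_character_,
    lower = 0, upper = c(0.10, 0.10, 1, 1))))
  dplyr::bind_rows(rows)
}

#' Map a controller to/from an optimization vector
#'
#' @param ctrl an `sr_controller`.
#' @param architecture target architecture.
#' @return `params_to_vector`: numeric z in the order of
#'   [make_bounds()]; `vector_to_params`: an `sr_controller`.
#' @export
params_to_vector <- function(ctrl, architecture = ctrl$architecture) {
  b <- make_bounds(architecture)
  g <- ctrl$gains[match(muscle_names(), ctrl$gains$muscle), ]
  dz <- ctrl$deadzone
  vals <- c(u0 = list(g$u0), g_ffb = list(g$g_ffb), g_lfb = list(g$g_lfb),
            l_off = list(g$l_off))
  z <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    z[i] <- if (is.na(b$muscle[i])) dz[[b$param[i]]]
            else vals[[b$param[i]]][match(b$muscle[i], muscle_names())]
  }
  z
}

#' @rdname params_to_vector
#' @param z numeric decision vector matching [make_bounds()].
#' @param com_delay COM trigger delay (s) to attach.
#' @export
vector_to_params <- function(z, architecture = c("base", "length", "force"),
                             com_delay = 0) {
  architecture <- match.arg(architecture)
  b <- make_bounds(architecture)
  if (length(z) != nrow(b))
    rlang::abort(sprintf("z has length %d but architecture '%s' needs %d",
                         length(z), architecture, nrow(b)))
  mus <- muscle_names()
  pick <- function(p, default) {
    idx <- which(b$param == p)
    if (length(idx) == 0) return(rep(default, 9))
    z[idx][match(mus, b$muscle[idx])]
  }
  dzidx <- which(is.na(b$muscle))
  dz <- stats::setNames(z[dzidx], b$param[dzidx])[c("x_heel", "x_toe", "z_heel", "z_toe")]
  new_controller(
    gains = tibble::tibble(muscle = mus, u0 = pick("u0", NA),
                           g_ffb = pick("g_ffb", 0), g_lfb = pick("g_lfb", 0),
                           l_off = pick("l_off", 0.65)),
    deadzone = dz, architecture = architecture, com_delay = com_delay
  )
}

#' Lexicographic candidate score
#'
#' Tier 1 is the normalized total constraint violation; tier 2 the effort
#' objective.  Any feasible candidate (tier 1 = 0) beats any infeasible one;
#' among infeasible candidates lower violation wins; among feasible ones
#' lower effort wins.
#'
#' @param violation non-negative tier-1 violation.
#' @param effort tier-2 effort objective.
#' @return an `sr_score` list.
#' @export
lexicographic_score <- function(violation, effort) {
  stopifnot(violation >= 0)
  structure(list(violation = violation, effort = effort), class = "sr_score")
}

#' Compare two lexicographic scores
#'
#' @param a,b `sr_score` objects.
#' @return -1 if `a` is better, 1 if `b` is better, 0 if tied.
#' @export
lexicographic_compare <- function(a, b) {
  if (a$violation < b$violation) return(-1L)
  if (a$violation > b$violation) return(1L)
  if (a$effort < b$effort) return(-1L)
  if (a$effort > b$effort) return(1L)
  0L
}

#' Swarm configuration
#'
#' Standard global-best PSO constants (inertia 0.72, cognitive = social =
#' 1.49), velocity clamped to a fraction of each parameter's range, and
#' reflecting bounds.  Fully deterministic given the seed.
#'
#' @param n_particles swarm size (>= 2).
#' @param n_iter number of iterations.
#' @param inertia inertia weight.
#' @param c_cog,c_soc cognitive and social acceleration coefficients.
#' @param v_clamp velocity clamp as a fraction of the parameter range.
#' @param seed RNG seed.
#' @param warm_start optional decision vector used as one initial particle
#'   ("seeded from a good initial guess").
#' @return list of class `sr_swarm_config`.
#' @export
swarm_config <- function(n_particles = 24, n_iter = 60, inertia = 0.72,
                         c_cog = 1.49, c_soc = 1.49, v_clamp = 0.2,
                         seed = 1, warm_start = NULL) {
  stopifnot(n_particles >= 2, n_iter >= 1, c_cog > 0, c_soc > 0)
  structure(list(n_particles = n_particles, n_iter = n_iter, inertia = inertia,
                 c_cog = c_cog, c_soc = c_soc, v_clamp = v_clamp, seed = seed,
                 warm_start = warm_start), class = "sr_swarm_config")
}

#' Lexicographic particle swarm optimization
#'
#' Global-best PSO where candidates are ordered lexicographically:
#' constraint satisfaction strictly dominates the effort objective.  A
#' candidate whose evaluation fails with an error is scored as maximally
#' infeasible and the run continues.
#'
#' @param fn evaluation function mapping a decision vector to an
#'   [lexicographic_score()] (or a bare number, treated as a feasible score
#'   with that effort).
#' @param bounds tibble from [make_bounds()] (or any tibble with `lower`,
#'   `upper`).
#' @param config an [swarm_config()].
#' @return an `sr_pso`: list with `best` (decision vector), `best_score`,
#'   `history` tibble (iteration, best violation, best effort) and
#'   `evaluations` count.
#' @examples
#' sphere <- function(z) sum(z^2)
#' b <- tibble::tibble(lower = rep(-5, 3), upper = rep(5, 3))
#' res <- pso_optimize(sphere, b, swarm_config(n_particles = 12, n_iter = 50))
#' res$best_score$effort
#' @export
pso_optimize <- function(fn, bounds, config = swarm_config()) {
  lo <- bounds$lower; hi <- bounds$upper
  d <- length(lo)
  rng <- hi - lo
  vmax <- config$v_clamp * rng
  set.seed(config$seed)
  np <- config$n_particles
  X <- matrix(runif(np * d, rep(lo, each = np), rep(hi, each = np)), nrow = np)
  V <- matrix(runif(np * d, rep(-vmax, each = np), rep(vmax, each = np)), nrow = np)
  if (!is.null(config$warm_start)) {
    stopifnot(length(config$warm_start) == d)
    X[1, ] <- pmin(hi, pmax(lo, config$warm_start))
    V[1, ] <- 0
  }
  worst <- lexicographic_score(Inf, Inf)
  eval_safe <- function(z) {
    s <- tryCatch(fn(z), error = function(e) worst)
    if (is.numeric(s) && length(s) == 1) s <- lexicographic_score(0, s)
    s
  }
  pbest <- X
  pscore <- vector("list", np)
  gbest <- NULL; gscore <- worst; gidx <- NA_integer_
  history <- vector("list", config$n_iter + 1)
  nev <- 0L
  for (i in seq_len(np)) {
    pscore[[i]] <- eval_safe(X[i, ]); nev <- nev + 1L
    if (lexicographic_compare(pscore[[i]], gscore) < 0) {
      gscore <- pscore[[i]]; gbest <- X[i, ]; gidx <- i
    }
  }
  history[[1]] <- tibble::tibble(iteration = 0L, best_violation = gscore$violation,
                                 best_effort = gscore$effort)
  for (it in seq_len(config$n_iter)) {
    for (i in seq_len(np)) {
      r1 <- runif(d); r2 <- runif(d)
      V[i, ] <- config$inertia * V[i, ] +
        config$c_cog * r1 * (pbest[i, ] - X[i, ]) +
        config$c_soc * r2 * (gbest - X[i, ])
      V[i, ] <- pmin(vmax, pmax(-vmax, V[i, ]))
      X[i, ] <- X[i, ] + V[i, ]
      # reflect at the bounds
      below <- X[i, ] < lo; above <- X[i, ] > hi
      X[i, below] <- pmin(hi[below], 2 * lo[below] - X[i, below])
      X[i, above] <- pmax(lo[above], 2 * hi[above] - X[i, above])
      V[i, below | above] <- -V[i, below | above]
      s <- eval_safe(X[i, ]); nev <- nev + 1L
      if (lexicographic_compare(s, pscore[[i]]) < 0) {
        pscore[[i]] <- s; pbest[i, ] <- X[i, ]
      }
      if (lexicographic_compare(s, gscore) < 0) {
        gscore <- s; gbest <- X[i, ]; gidx <- i
      }
    }
    history[[it + 1]] <- tibble::tibble(iteration = it,
                                        best_violation = gscore$violation,
                                        best_effort = gscore$effort)
  }
  out <- list(best = gbest, best_score = gscore,
              history = dplyr::bind_rows(history), evaluations = nev,
              config = config)
  class(out) <- "sr_pso"
  out
}

#' @export
print.sr_pso <- function(x, ...) {
  cat(sprintf("<sr_pso> %d evaluations; best violation %.4g, best effort %.4g\n",
              x$evaluations, x$best_score$violation, x$best_score$effort))
  invisible(x)
}

#' Score a controller candidate by single shooting
#'
#' Runs one full episode with the candidate parameters and converts it into
#' the lexicographic score (normalized constraint violation, then effort).
#'
#' @param z decision vector.
#' @param architecture controller architecture.
#' @param plant,muscles,signal,config,delays forwarded to [run_episode()].
#' @param com_delay COM trigger delay (s).
#' @return an [lexicographic_score()].
#' @export
evaluate_controller <- function(z, architecture, plant, muscles, signal,
                                config = episode_config(),
                                delays = delay_table(), com_delay = 0) {
  ctrl <- vector_to_params(z, architecture, com_delay = com_delay)
  ep <- run_episode(plant, muscles, ctrl, signal, config, delays)
  lexicographic_score(constraint_violation(ep), ep$effort)
}

#' Optimize a controller architecture
#'
#' Lexicographic PSO over the architecture's decision vector, evaluating
#' each candidate by one full simulated episode (single shooting).
#'
#' @param plant,muscles,signal,config,delays forwarded to [run_episode()].
#' @param architecture controller architecture.
#' @param swarm an [swarm_config()]; its `warm_start` may also be an
#'   `sr_controller`.
#' @param com_delay COM trigger delay (s).
#' @return list with `controller` (best `sr_controller`), `pso` (the
#'   `sr_pso`), and `episode` (verification episode of the best candidate).
#' @export
optimize_controller <- function(plant, muscles, architecture, signal,
                                swarm = swarm_config(),
                                config = episode_config(),
                                delays = delay_table(), com_delay = 0) {
  if (inherits(swarm$warm_start, "sr_controller"))
    swarm$warm_start <- params_to_vector(swarm$warm_start, architecture)
  b <- make_bounds(architecture)
  fn <- function(z) evaluate_controller(z, architecture, plant, muscles,
                                        signal, config, delays, com_delay)
  pso <- pso_optimize(fn, b, swarm)
  ctrl <- vector_to_params(pso$best, architecture, com_delay = com_delay)
  ep <- run_episode(plant, muscles, ctrl, signal, config, delays)
  list(controller = ctrl, pso = pso, episode = ep)
}

#' Re-optimize a controller across reflex-delay settings
#'
#' Repeats the optimization for a list of delay-table overrides (and/or COM
#' trigger delays) and collates the outcomes.
#'
#' @param settings list; each element a list with optional `delays` (delay
#'   table) and `com_delay` (s), plus a `label`.
#' @param plant,muscles,architecture,signal,swarm,config forwarded to
#'   [optimize_controller()].
#' @return tibble with one row per setting: label, com_delay, feasibility,
#'   violation, effort, survived duration; the fitted controllers in a
#'   list-column.
#' @export
delay_sweep <- function(settings, plant, muscles, architecture, signal,
                        swarm = swarm_config(), config = episode_config()) {
  if (length(settings) == 0)
    return(tibble::tibble(label = character(0), com_delay = numeric(0),
                          violation = numeric(0), effort = numeric(0),
                          survived = numeric(0), feasible = logical(0),
                          controller = list()))
  rows <- lapply(settings, function(s) {
    delays <- if (!is.null(s$delays)) s$delays else delay_table()
    cd <- if (!is.null(s$com_delay)) s$com_delay else 0
    fit <- optimize_controller(plant, muscles, architecture, signal, swarm,
                               config, delays, com_delay = cd)
    tibble::tibble(label = s$label, com_delay = cd,
                   violation = fit$pso$best_score$violation,
                   effort = fit$pso$best_score$effort,
                   survived = fit$episode$survived,
                   feasible = fit$pso$best_score$violation == 0,
                   controller = list(fit$controller))
  })
  dplyr::bind_rows(rows)
}
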