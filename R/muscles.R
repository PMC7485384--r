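#' Default muscle parameter table
#'
#' The nine muscles per leg: all mono- and bi-articular muscles of the human
#' leg in the sagittal plane (iliopsoas, gluteals, rectus femoris, biceps
#' femoris long and short head, vastus, gastrocnemius, soleus, tibialis
#' anterior).  Muscles are four-element Hill-type: a contractile element (CE)
#' with force-length and force-velocity curves, a parallel elastic element
#' with damping, a series elastic element (SEE, the tendon) and a buffer
#' elastic element that prevents the CE from collapsing.  Curve shapes and
#' most constants follow the reflex-walking muscle model family; the rectus
#' femoris and biceps femoris short head use their published values (optimal
#' CE length 8.1 cm / 12 cm, maximum isometric force 1200 N each, tendon
#' slack length 35 cm / 10 cm, pennation projection factor 0.5 / 0.7), and
#' the tibialis anterior maximum isometric force is raised to 4000 N so the
#' dorsiflexor can resist the platform perturbations.
#'
#' Attachment geometry (signed moment arms, in m) is a documented default
#' adapted from the same model family: positive arms produce flexion
#' (dorsiflexion) moments and shorten with flexion.  The musculotendon
#' resting length at the upright reference posture is
#' `l_slack + pennation * l_opt`.
#'
#' @return tibble, one row per muscle, with Hill parameters
#'   (`f_max` N, `l_opt` m, `l_slack` m, `pennation`, `eps_ref` SEE reference
#'   strain, `v_max` maximum CE contraction rate in `l_opt`/s, `fl_width`,
#'   `fv_n`, `fv_k` curve constants, `damping` dimensionless CE damping,
#'   `tau_act`/`tau_deact` activation time constants in s) and geometry
#'   columns `r_hip`, `r_knee`, `r_ankle` (signed moment arm, 0 = joint not
#'   spanned), `phi_*` (reference angle, rad) and `shape_*`
#'   (`"constant"` or `"cosine"`).
#' @examples
#' default_muscles()
#' @export
default_muscles <- function() {
  tb <- tibble::tribble(
    ~muscle,              ~f_max, ~l_opt, ~l_slack, ~pennation, ~r_hip, ~r_knee, ~r_ankle,
    "iliopsoas",            2000,  0.11,   0.10,      0.5,       0.10,   0.00,    0.00,
    "gluteals",             1500,  0.11,   0.13,      0.5,      -0.10,   0.00,    0.00,
    "rectus_femoris",       1200,  0.081,  0.35,      0.5,       0.08,  -0.06,    0.00,
    "biceps_femoris_lh",    3000,  0.10,   0.31,      0.7,      -0.08,   0.05,    0.00,
    "biceps_femoris_sh",    1200,  0.12,   0.10,      0.7,       0.00,   0.05,    0.00,
    "vastus",               6000,  0.08,   0.23,      0.7,       0.00,  -0.06,    0.00,
    "gastrocnemius",        1500,  0.05,   0.40,      0.7,       0.00,   0.05,   -0.05,
    "soleus",               4000,  0.04,   0.26,      0.5,       0.00,   0.00,   -0.05,
    "tibialis_anterior",    4000,  0.06,   0.24,      0.7,       0.00,   0.00,    0.04
  )
  tb$eps_ref <- 0.04
  tb$v_max <- 12
  tb$fl_width <- 0.56
  tb$fv_n <- 1.5
  tb$fv_k <- 5
  tb$damping <- 0.05
  tb$tau_act <- 0.01
  tb$tau_deact <- 0.04
  for (j in c("hip", "knee", "ankle")) {
    tb[[paste0("phi_", j)]] <- 0
    tb[[paste0("shape_", j)]] <- "constant"
  }
  tb
}

#' Canonical muscle name order
#' @return character vector of the nine muscle names.
#' @export
muscle_names <- function() default_muscles()$muscle

validate_muscles <- function(muscles) {
  req <- c("muscle", "f_max", "l_opt", "l_slack", "pennation", "eps_ref",
           "v_max", "fl_width", "fv_n", "fv_k", "damping", "tau_act",
           "tau_deact", "r_hip", "r_knee", "r_ankle")
  miss <- setdiff(req, names(muscles))
  if (length(miss) > 0)
    rlang::abort(paste("muscle table missing columns:", paste(miss, collapse = ", ")))
  with(muscles, {
    if (any(f_max <= 0)) rlang::abort("f_max must be > 0")
    if (any(l_opt <= 0)) rlang::abort("l_opt must be > 0")
    if (any(l_slack < 0)) rlang::abort("l_slack must be >= 0")
    if (any(pennation <= 0 | pennation > 1)) rlang::abort("pennation must be in (0, 1]")
  })
  invisible(muscles)
}

# matrix layout the C++ core expects
muscle_matrix <- function(muscles) {
  validate_muscles(muscles)
  shp <- function(s) ifelse(s == "cosine", 1, 0)
  m <- cbind(muscles$f_max, muscles$l_opt, muscles$l_slack, muscles$pennation,
             muscles$eps_ref, muscles$v_max, muscles$fl_width, muscles$fv_n,
             muscles$fv_k, muscles$damping, muscles$tau_act, muscles$tau_deact,
             muscles$r_hip, muscles$phi_hip, shp(muscles$shape_hip),
             muscles$r_knee, muscles$phi_knee, shp(muscles$shape_knee),
             muscles$r_ankle, muscles$phi_ankle, shp(muscles$shape_ankle))
  rownames(m) <- muscles$muscle
  m
}

#' Musculotendon lengths and moment arms at a posture
#'
#' @param muscles muscle table (see [default_muscles()]).
#' @param hip,knee,ankle joint angles (rad, flexion/dorsiflexion positive).
#' @return tibble with `muscle`, `l_mtu` (m) and the instantaneous signed
#'   moment arms `r_hip`, `r_knee`, `r_ankle` (m).
#' @export
musculotendon_length <- function(muscles, hip = 0, knee = 0, ankle = 0) {
  g <- rs_muscle_geometry_cpp(muscle_matrix(muscles), c(hip, knee, ankle))
  tibble::tibble(muscle = muscles$muscle, l_mtu = g$lmtu,
                 r_hip = g$moment_arms[, 1], r_knee = g$moment_arms[, 2],
                 r_ankle = g$moment_arms[, 3])
}

#' Series elastic element force
#'
#' Zero below the slack length, then quadratic in strain:
#' `F = f_max * ((l_see - l_slack) / (l_slack * eps_ref))^2`, which equals
#' `f_max` at the reference strain `eps_ref`.
#'
#' @param muscles muscle table.
#' @param muscle muscle name.
#' @param l_see series element length (m), vectorized.
#' @return force in N.
#' @export
see_force <- function(muscles, muscle, l_see) {
  i <- match(muscle, muscles$muscle)
  if (is.na(i)) rlang::abort(paste("unknown muscle:", muscle))
  if (any(l_see < 0)) rlang::abort("l_see must be >= 0")
  m <- muscle_matrix(muscles)
  vapply(l_see, function(l) rs_see_force_cpp(m, i, l), numeric(1))
}

#' Contractile element velocity from the four-element force balance
#'
#' Solves `F_see = pennation * (a f_max f_l f_v(v) + F_pe + damping - F_be)`
#' for the CE velocity.  The solution is clipped at the maximum shortening /
#' lengthening rate (`v_max`), in which case `clipped` is 1.
#'
#' @param muscles muscle table.
#' @param muscle muscle name.
#' @param l_ce contractile element length (m).
#' @param activation activation in `[0, 1]`.
#' @param l_mtu musculotendon length (m).
#' @return tibble with `dlce_dt` (m/s), normalized `vbar`, force-balance
#'   `residual` (N), `clipped` flag and element forces `f_see`, `f_l` (the
#'   force-length factor), `f_pe`, `f_be`.
#' @export
contraction_dynamics <- function(muscles, muscle, l_ce, activation, l_mtu) {
  i <- match(muscle, muscles$muscle)
  if (is.na(i)) rlang::abort(paste("unknown muscle:", muscle))
  if (l_ce <= 0) rlang::abort("l_ce must be > 0")
  if (activation < 0 || activation > 1) rlang::abort("activation must be in [0, 1]")
  r <- rs_contraction_cpp(muscle_matrix(muscles), i, l_ce, activation, l_mtu)
  tibble::as_tibble(r)
}

#' First-order activation dynamics
#'
#' Excitation-contraction coupling with distinct rise and fall time
#' constants: `a' = a + dt * (u - a) / tau`, with `tau = tau_act` while the
#' (saturated) input exceeds the activation and `tau_deact` otherwise.  The
#' input is clamped to `[0, 1]` and the result stays in `[0, 1]`.
#'
#' @param a current activation.
#' @param u neural stimulation (clamped to `[0, 1]`).
#' @param dt time step (s).
#' @param tau_act,tau_deact rise and fall time constants (s).
#' @return updated activation.
#' @export
activation_dynamics <- function(a, u, dt, tau_act = 0.01, tau_deact = 0.04) {
  u <- pmin(1, pmax(0, u))
  tau <- ifelse(u > a, tau_act, tau_deact)
  pmin(1, pmax(0, a + dt * (u - a) / tau))
}

#' Joint moments produced by a set of muscle forces
#'
#' Moment at each joint is the sum over spanning muscles of the SEE force
#' times the signed instantaneous moment arm.
#'
#' @param muscles muscle table.
#' @param forces named numeric of SEE forces (N), names matching
#'   `muscles$muscle`.
#' @param hip,knee,ankle joint angles (rad).
#' @return tibble with `joint` (hip/knee/ankle) and `moment` (N m,
#'   flexion/dorsiflexion positive).
#' @export
joint_moments_from_muscles <- function(muscles, forces, hip = 0, knee = 0,
                                       ankle = 0) {
  geo <- musculotendon_length(muscles, hip, knee, ankle)
  f <- forces[geo$muscle]
  if (any(is.na(f))) rlang::abort("forces must be named for every muscle")
  tibble::tibble(
    joint = c("hip", "knee", "ankle"),
    moment = c(sum(geo$r_hip * f), sum(geo$r_knee * f), sum(geo$r_ankle * f))
  )
}
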