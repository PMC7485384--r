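#' Default segment anthropometry
#'
#' Segment masses, lengths, centre-of-mass offsets and moments of inertia for
#' the seven-segment sagittal model (trunk including head and arms, and a
#' thigh, shank and foot per leg).  Masses follow standard cadaver-based body
#' segment fractions (trunk-head-arms 67.8%, thigh 10.0%, shank 4.65%, foot
#' 1.45% of total mass per leg segment), segment lengths are fractions of
#' stature, COM offsets sit at 43.3% of segment length from the proximal
#' joint (45% up the trunk), and inertias use standard radii of gyration.
#' Every value can be overridden before calling [build_plant()].
#'
#' @param total_mass whole-body mass in kg.
#' @param height stature in m.
#' @return a tibble with one row per segment type: `segment`, `mass` (kg; per
#'   single segment, so thigh/shank/foot are per leg), `length` (m),
#'   `com_offset` (m from the proximal joint), `inertia` (kg m^2 about the
#'   segment COM).
#' @examples
#' default_anthropometry(80, 1.80)
#' @export
default_anthropometry <- function(total_mass = 80, height = 1.80) {
  stopifnot(total_mass > 0, height > 0)
  l_trunk <- 0.440 * height
  l_thigh <- 0.245 * height
  l_shank <- 0.246 * height
  l_foot  <- 0.152 * height
  m <- c(trunk = 0.678, thigh = 0.100, shank = 0.0465, foot = 0.0145) * total_mass
  len <- c(trunk = l_trunk, thigh = l_thigh, shank = l_shank, foot = l_foot)
  com <- c(trunk = 0.450 * l_trunk, thigh = 0.433 * l_thigh,
           shank = 0.433 * l_shank, foot = 0.500 * l_foot)
  rg <- c(trunk = 0.496 * l_trunk, thigh = 0.323 * l_thigh,
          shank = 0.302 * l_shank, foot = 0.475 * l_foot)
  tibble::tibble(
    segment = c("trunk", "thigh", "shank", "foot"),
    mass = unname(m), length = unname(len),
    com_offset = unname(com), inertia = unname(m * rg^2)
  )
}

#' Default foot-platform contact parameters
#'
#' The platform is driven kinematically; the feet interact with its surface
#' through a penetration-based spring-damper normal force
#' `F_n = max(0, pen * (stiffness + damping * pen_rate))` at a heel and a toe
#' point per foot, and a regularized Coulomb friction force
#' `F_t = -mu * F_n * tanh(v_slip / v_reg)`.
#'
#' @param stiffness vertical contact stiffness, N/m per contact point.
#' @param damping contact damping, N s/m^2 (acts proportionally to
#'   penetration).
#' @param mu Coulomb friction coefficient.
#' @param v_reg regularization velocity for the friction law, m/s.
#' @return a named list of contact parameters.
#' @export
default_contact <- function(stiffness = 8e4, damping = 8e4, mu = 1.0,
                            v_reg = 0.1) {
  list(stiffness = stiffness, damping = damping, mu = mu, v_reg = v_reg)
}

#' Build the seven-segment standing model
#'
#' Assembles the sagittal-plane rigid-body model: a floating trunk (including
#' head and arms), and per leg a thigh, shank and foot connected by revolute
#' hip, knee and ankle joints, standing on a kinematically driven platform
#' with heel and toe contact points on each foot.  The platform mass (1000 kg
#' in the modelled apparatus) is retained as metadata only: the platform is
#' position-driven, so the human cannot perturb it.
#'
#' Coordinate conventions: x points forward (toward the toes), y up.  The
#' nine generalized coordinates are hip-point x and y, trunk angle, and per
#' leg the hip, knee and ankle angle; all joint angles are zero in upright
#' stance with flexion (and ankle dorsiflexion) positive.
#'
#' @param anthropometry a tibble as returned by [default_anthropometry()].
#' @param contact contact parameters from [default_contact()].
#' @param foot_geometry list with `ankle_height` (m above the sole),
#'   `heel_back` and `toe_front` (m, horizontal distances of heel/toe contact
#'   points from the ankle).  `NULL` scales the defaults from the foot length.
#' @param gravity gravitational acceleration, m/s^2.
#' @param platform_mass platform mass in kg (metadata; the platform motion is
#'   prescribed).
#' @return an object of class `sr_plant`.
#' @examples
#' plant <- build_plant()
#' plant$n_segments
#' @export
build_plant <- function(anthropometry = default_anthropometry(),
                        contact = default_contact(),
                        foot_geometry = NULL,
                        gravity = 9.80665,
                        platform_mass = 1000) {
  req <- c("segment", "mass", "length", "com_offset", "inertia")
  if (!all(req %in% names(anthropometry)))
    rlang::abort(paste("anthropometry must have columns:", paste(req, collapse = ", ")))
  seg <- function(s) {
    row <- anthropometry[anthropometry$segment == s, ]
    if (nrow(row) != 1) rlang::abort(paste0("missing segment '", s, "' in anthropometry"))
    as.list(row)
  }
  for (s in c("trunk", "thigh", "shank", "foot")) {
    r <- seg(s)
    for (f in c("mass", "length", "inertia")) {
      if (!is.finite(r[[f]]) || r[[f]] <= 0)
        rlang::abort(paste0("segment '", s, "': field '", f, "' must be > 0"))
    }
    if (r$com_offset < 0 || r$com_offset > r$length)
      rlang::abort(paste0("segment '", s, "': field 'com_offset' must lie in [0, length]"))
  }
  tr <- seg("trunk"); th <- seg("thigh"); sh <- seg("shank"); ft <- seg("foot")
  if (is.null(foot_geometry)) {
    foot_geometry <- list(ankle_height = 0.26 * ft$length,
                          heel_back = 0.25 * ft$length,
                          toe_front = 0.75 * ft$length)
  }
  if (foot_geometry$heel_back <= 0 || foot_geometry$toe_front <= 0)
    rlang::abort("foot_geometry: heel_back and toe_front must be > 0")
  for (f in c("stiffness", "damping", "mu", "v_reg"))
    if (contact[[f]] <= 0) rlang::abort(paste0("contact: field '", f, "' must be > 0"))
  p <- list(
    m_trunk = tr$mass, l_trunk = tr$length, c_trunk = tr$com_offset, i_trunk = tr$inertia,
    m_thigh = th$mass, l_thigh = th$length, c_thigh = th$com_offset, i_thigh = th$inertia,
    m_shank = sh$mass, l_shank = sh$length, c_shank = sh$com_offset, i_shank = sh$inertia,
    m_foot = ft$mass, i_foot = ft$inertia,
    a_heel = foot_geometry$heel_back, b_toe = foot_geometry$toe_front,
    h_ankle = foot_geometry$ankle_height,
    foot_cx = 0.5 * (foot_geometry$toe_front - foot_geometry$heel_back),
    foot_cy = 0.5 * foot_geometry$ankle_height,
    contact_stiffness = contact$stiffness, contact_damping = contact$damping,
    friction_mu = contact$mu, friction_vreg = contact$v_reg,
    gravity = gravity,
    platform_mass = platform_mass,
    n_segments = 7L, n_joints = 6L, n_contact_points = 4L,
    anthropometry = anthropometry
  )
  class(p) <- "sr_plant"
  p
}

#' @export
print.sr_plant <- function(x, ...) {
  cat("<sr_plant> 7-segment sagittal standing model\n")
  cat(sprintf("  total mass %.1f kg, chest height (upright) %.2f m\n",
              total_mass(x), x$h_ankle + x$l_shank + x$l_thigh + x$l_trunk))
  cat(sprintf("  contact: k=%.0f N/m, mu=%.2f; platform %.0f kg (kinematic)\n",
              x$contact_stiffness, x$friction_mu, x$platform_mass))
  invisible(x)
}

#' Total model mass
#' @param plant an `sr_plant`.
#' @return total mass in kg.
#' @export
total_mass <- function(plant) {
  plant$m_trunk + 2 * (plant$m_thigh + plant$m_shank + plant$m_foot)
}

#' Construct a plant state
#'
#' @param trunk_x,trunk_y hip-point position (m).
#' @param pitch trunk forward-lean angle (rad, forward positive).
#' @param hip,knee,ankle joint angles (rad, flexion/dorsiflexion positive);
#'   scalars are mirrored to both legs.
#' @param qdot generalized velocities (length 9), default zero.
#' @return list with elements `q` and `qd` (length-9 numeric, internal layout
#'   `c(x, y, trunk_angle, hipL, kneeL, ankleL, hipR, kneeR, ankleR)`; the
#'   internal trunk angle is `-pitch`).
#' @export
plant_state <- function(trunk_x = 0, trunk_y = 0.95, pitch = 0,
                        hip = 0, knee = 0, ankle = 0, qdot = rep(0, 9)) {
  q <- c(trunk_x, trunk_y, -pitch, hip, knee, ankle, hip, knee, ankle)
  if (!all(is.finite(q)) || !all(is.finite(qdot)))
    rlang::abort("plant state must be finite")
  list(q = q, qd = qdot)
}

#' Upright standing configuration
#'
#' Computes the initial configuration used at the start of an episode: a
#' slightly flexed stance with flat feet (`ankle = knee - hip` keeps the sole
#' horizontal) and the whole-body COM placed a given distance ahead of the
#' ankle.
#'
#' @param plant an `sr_plant`.
#' @param hip,knee hip and knee flexion (rad).
#' @param com_ahead distance (m) of the COM forward of the ankle joint.
#' @return a state list as from [plant_state()].
#' @export
standing_state <- function(plant, hip = 0.04, knee = 0.08, com_ahead = 0.05) {
  ankle <- knee - hip
  a_th <- hip; a_sh <- hip - knee
  y_h <- plant$h_ankle + plant$l_thigh * cos(a_th) + plant$l_shank * cos(a_sh)
  x_h <- -(plant$l_thigh * sin(a_th) + plant$l_shank * sin(a_sh))  # ankle at x=0
  st <- plant_state(x_h, y_h, 0, hip, knee, ankle)
  com <- com_position(plant, st)
  st$q[1] <- st$q[1] + (0 + com_ahead - com$x)
  st
}

#' Forward dynamics of the standing model
#'
#' Computes generalized accelerations from the current state, applied joint
#' moments, gravity and foot-platform contact.
#'
#' @param plant an `sr_plant`.
#' @param state state list from [plant_state()].
#' @param joint_moments length-6 numeric: hip, knee, ankle moment for the
#'   left then right leg (N m, flexion/dorsiflexion positive).
#' @param platform_velocity horizontal platform velocity (m/s).
#' @param contact if `FALSE` the feet are free (used for in-air tests).
#' @return a list with `qdd` (length 9), total vertical and horizontal ground
#'   reaction force `grf_y`, `grf_x`, and a 4 x 2 matrix `contact_forces`
#'   (heel L, toe L, heel R, toe R; columns fx, fy).
#' @export
forward_dynamics <- function(plant, state, joint_moments = rep(0, 6),
                             platform_velocity = 0, contact = TRUE) {
  if (!all(is.finite(state$q)) || !all(is.finite(state$qd)))
    rlang::abort("state must be finite")
  if (length(joint_moments) != 6)
    rlang::abort("joint_moments must have length 6 (hip, knee, ankle x 2 legs)")
  rs_forward_dynamics_cpp(unclass(plant), state$q, state$qd,
                          as.numeric(joint_moments), platform_velocity, contact)
}

#' Integrate the passive (or PD-held) model forward in time
#'
#' Fixed-step semi-implicit Euler integration of the plant without muscles.
#' Optionally a per-joint PD controller holds a reference posture (used for
#' the joint-angle control phase and for settling tests), and a platform
#' position series can be prescribed.
#'
#' @param plant an `sr_plant`.
#' @param state initial state.
#' @param dt time step (s), must be > 0.
#' @param duration simulated time (s).
#' @param contact enable foot contact.
#' @param pd `NULL`, or list with `kp`, `kd` (length-3: hip, knee, ankle) and
#'   `q_ref` (length-9 reference coordinates).
#' @param platform optional numeric vector of platform positions sampled at
#'   `dt` (length at least `duration/dt + 1`).
#' @param log_every store every n-th step (default 1).
#' @return a list with a trajectory tibble (`t`, `q`, `qd` columns), total
#'   mechanical `energy` (J) per logged step, vertical GRF, and the final
#'   generalized accelerations.
#' @export
simulate_passive <- function(plant, state, dt = 5e-4, duration = 1,
                             contact = TRUE, pd = NULL, platform = numeric(0),
                             log_every = 1) {
  if (dt <= 0) rlang::abort("dt must be > 0")
  n <- round(duration / dt)
  pd_on <- !is.null(pd)
  kp <- if (pd_on) pd$kp else rep(0, 3)
  kd <- if (pd_on) pd$kd else rep(0, 3)
  qref <- if (pd_on) pd$q_ref else rep(0, 9)
  res <- rs_passive_sim_cpp(unclass(plant), state$q, state$qd, dt, n, contact,
                            kp, kd, qref, pd_on, platform, log_every)
  res$trajectory <- tibble::tibble(
    time = res$t,
    q = lapply(seq_len(nrow(res$q)), function(i) res$q[i, ]),
    qd = lapply(seq_len(nrow(res$qd)), function(i) res$qd[i, ]),
    energy = res$energy, grf_y = res$grf_y
  )
  res
}

#' Whole-body centre of mass
#'
#' @param plant an `sr_plant`.
#' @param state a state list (or a length-9 q vector).
#' @return tibble with columns `x`, `y` (m).
#' @export
com_position <- function(plant, state) {
  q <- if (is.list(state)) state$q else state
  v <- rs_com_cpp(unclass(plant), q)
  tibble::tibble(x = v[1], y = v[2])
}

#' Landmark points of the model
#'
#' @inheritParams com_position
#' @return tibble with columns `point`, `x`, `y` for the hip, knees, ankles,
#'   heel and toe contact points, the chest (top of trunk) and the COM.
#' @export
body_points <- function(plant, state) {
  q <- if (is.list(state)) state$q else state
  pts <- rs_points_cpp(unclass(plant), q)
  tibble::tibble(
    point = names(pts),
    x = vapply(pts, `[`, numeric(1), 1),
    y = vapply(pts, `[`, numeric(1), 2)
  )
}

#' Chest height
#'
#' Height of the chest point (top of the trunk segment); an episode is
#' stopped early when it drops below 0.7 m, and upright termination requires
#' at least 1.3 m.
#'
#' @inheritParams com_position
#' @return chest height in m.
#' @export
chest_height <- function(plant, state) {
  q <- if (is.list(state)) state$q else state
  pts <- rs_points_cpp(unclass(plant), q)
  pts$chest[2]
}

#' Horizontal ankle excursion
#'
#' Ankle x-position (averaged over legs) in the platform frame, relative to a
#' reference value (its position at perturbation onset inside an episode).
#'
#' @inheritParams com_position
#' @param platform_x current platform position (m).
#' @param reference reference ankle-minus-platform position (m).
#' @return relative ankle position in m.
#' @export
ankle_x <- function(plant, state, platform_x = 0, reference = 0) {
  q <- if (is.list(state)) state$q else state
  pts <- rs_points_cpp(unclass(plant), q)
  mean(c(pts$ankle_l[1], pts$ankle_r[1])) - platform_x - reference
}

#' Total mechanical energy of the model
#' @inheritParams com_position
#' @return kinetic plus gravitational potential energy (J).
#' @export
mechanical_energy <- function(plant, state) {
  rs_energy_cpp(unclass(plant), state$q, state$qd)
}
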