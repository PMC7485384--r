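test_that("model assembles with seven segments and conserves total mass", {
  expect_identical(sr_plant$n_segments, 7L)
  expect_identical(sr_plant$n_joints, 6L)
  expect_identical(sr_plant$n_contact_points, 4L)
  expect_equal(total_mass(sr_plant), 80)
  # scaling the anthropometry conserves the requested total
  for (M in c(60, 95.5)) {
    p <- build_plant(default_anthropometry(total_mass = M))
    expect_equal(total_mass(p), M, tolerance = 1e-12)
  }
  expect_equal(sr_plant$platform_mass, 1000)
})

test_that("invalid segment parameters are rejected with a named-field report", {
  bad <- default_anthropometry()
  bad$length[bad$segment == "shank"] <- 0
  expect_error(build_plant(bad), "shank.*length")
  bad2 <- default_anthropometry()
  bad2$mass[bad2$segment == "trunk"] <- -1
  expect_error(build_plant(bad2), "trunk.*mass")
  bad3 <- default_anthropometry()
  bad3$com_offset[bad3$segment == "thigh"] <- 10
  expect_error(build_plant(bad3), "thigh.*com_offset")
})

test_that("free fall: no contact and no moments gives vertical acceleration -g", {
  st <- standing_state(sr_plant)
  fd <- forward_dynamics(sr_plant, st, contact = FALSE)
  expect_equal(fd$qdd[2], -sr_plant$gravity, tolerance = 1e-10)
  expect_equal(fd$qdd[-2], rep(0, 8), tolerance = 1e-9)
  expect_equal(fd$grf_y, 0)
})

test_that("ballistic trajectory matches the closed form", {
  st <- plant_state(0, 2, qdot = rep(0, 9))
  dt <- 1e-4
  r <- simulate_passive(sr_plant, st, dt = dt, duration = 0.5, contact = FALSE)
  tr <- r$trajectory
  y <- vapply(tr$q, `[`, numeric(1), 2)
  expect_equal(y, 2 - 0.5 * sr_plant$gravity * tr$time^2, tolerance = 1e-2)
})

test_that("dt -> 0 limit: a single tiny step leaves the state unchanged", {
  st <- plant_state(0.1, 1.2, pitch = 0.2, hip = 0.3, knee = 0.2, ankle = -0.1,
                    qdot = runif(9, -1, 1))
  r <- simulate_passive(sr_plant, st, dt = 1e-10, duration = 1e-10, contact = FALSE)
  qf <- r$trajectory$q[[nrow(r$trajectory)]]
  expect_equal(qf, st$q, tolerance = 1e-8)
})

test_that("passive contact-free swing conserves mechanical energy to < 0.1%", {
  st <- plant_state(0, 2, pitch = 0.3, hip = 0.4, knee = 0.3, ankle = -0.1,
                    qdot = c(0, 0, 0.5, -0.3, 0.2, 0, 0.1, 0, 0.2))
  r <- simulate_passive(sr_plant, st, dt = 1e-4, duration = 1, contact = FALSE,
                        log_every = 100)
  E <- r$trajectory$energy
  expect_lt((max(E) - min(E)) / abs(E[1]), 1e-3)
})

test_that("halving dt shrinks the trajectory difference (integrator converges)", {
  st <- plant_state(0, 2, pitch = 0.2, hip = 0.3, knee = 0.2, ankle = 0.1,
                    qdot = c(0, 0, 0.4, -0.2, 0.1, 0, 0, 0.1, 0))
  qf <- function(dt) {
    r <- simulate_passive(sr_plant, st, dt = dt, duration = 1, contact = FALSE,
                          log_every = round(1 / dt))
    r$trajectory$q[[nrow(r$trajectory)]]
  }
  e1 <- max(abs(qf(4e-4) - qf(2e-4)))
  e2 <- max(abs(qf(2e-4) - qf(1e-4)))
  expect_lt(e2, e1)           # converging
  expect_lt(e2 / e1, 0.75)    # at roughly first order or better
})

test_that("COM is translation-equivariant and sits over the base of support", {
  st <- standing_state(sr_plant)
  c0 <- com_position(sr_plant, st)
  pts <- body_points(sr_plant, st)
  heel <- pts$x[pts$point == "heel_l"]; toe <- pts$x[pts$point == "toe_l"]
  expect_gt(c0$x, heel); expect_lt(c0$x, toe)
  for (dx in c(-1.3, 0.4)) {
    st2 <- st; st2$q[1] <- st$q[1] + dx
    c2 <- com_position(sr_plant, st2)
    expect_equal(c2$x, c0$x + dx, tolerance = 1e-12)
    expect_equal(c2$y, c0$y, tolerance = 1e-12)
  }
})

test_that("chest height and ankle excursion behave geometrically", {
  st <- standing_state(sr_plant)
  h0 <- chest_height(sr_plant, st)
  expect_gt(h0, 1.3)  # upright posture is well above the constraint bound
  st2 <- st; st2$q[2] <- st$q[2] - 1
  expect_equal(chest_height(sr_plant, st2), h0 - 1, tolerance = 1e-12)
  expect_equal(ankle_x(sr_plant, st, platform_x = 0,
                       reference = ankle_x(sr_plant, st)), 0, tolerance = 1e-12)
})

test_that("contact: feet above the platform produce zero force", {
  st <- standing_state(sr_plant)
  st$q[2] <- st$q[2] + 0.05
  fd <- forward_dynamics(sr_plant, st)
  expect_equal(fd$grf_y, 0)
  expect_equal(unname(fd$contact_forces), matrix(0, 4, 2))
})

test_that("settled quiet stance carries body weight within 2% at near-zero accel", {
  st <- standing_state(sr_plant)
  pd <- list(kp = c(3000, 3000, 2000), kd = c(60, 60, 30), q_ref = st$q)
  r <- simulate_passive(sr_plant, st, dt = 5e-4, duration = 3, contact = TRUE,
                        pd = pd, log_every = 500)
  w <- total_mass(sr_plant) * sr_plant$gravity
  expect_lt(abs(r$final_grf_y - w) / w, 0.02)
  expect_lt(max(abs(r$final_qdd)), 0.5)  # settled to near-equilibrium
  # normal forces unilateral, friction within the cone
  qf <- r$trajectory$q[[nrow(r$trajectory)]]
  qdf <- r$trajectory$qd[[nrow(r$trajectory)]]
  fd <- forward_dynamics(sr_plant, list(q = qf, qd = qdf))
  cf <- fd$contact_forces
  expect_true(all(cf[, 2] >= 0))
  expect_true(all(abs(cf[, 1]) <= sr_plant$friction_mu * cf[, 2] + 1e-9))
})

test_that("a platform step drags the settled model with it when friction is high", {
  st <- standing_state(sr_plant)
  pd <- list(kp = c(3000, 3000, 2000), kd = c(60, 60, 30), q_ref = st$q)
  dt <- 5e-4
  n <- round(3 / dt)
  # settle 1.5 s, then ramp the platform 5 cm over 0.1 s
  plat <- numeric(n + 2)
  t <- seq_len(n + 2) * dt
  plat <- pmin(0.05, pmax(0, (t - 1.5) * 0.5))
  r <- simulate_passive(sr_plant, st, dt = dt, duration = 3, contact = TRUE,
                        pd = pd, platform = plat, log_every = 500)
  qf <- r$trajectory$q[[nrow(r$trajectory)]]
  pts <- body_points(sr_plant, qf)
  ank0 <- body_points(sr_plant, st)$x[3]
  ankf <- pts$x[pts$point == "ankle_l"]
  expect_equal(unname(ankf - ank0), 0.05, tolerance = 0.015)  # feet followed the platform
})

test_that("mirrored initial conditions produce mirrored trajectories", {
  st <- standing_state(sr_plant)
  st$q[4:6] <- c(0.05, 0.09, 0.02); st$q[7:9] <- c(0.03, 0.07, 0.05)
  st$qd[4:9] <- c(0.1, -0.2, 0.05, -0.1, 0.3, 0)
  sw <- st
  sw$q[4:6] <- st$q[7:9]; sw$q[7:9] <- st$q[4:6]
  sw$qd[4:6] <- st$qd[7:9]; sw$qd[7:9] <- st$qd[4:6]
  r1 <- simulate_passive(sr_plant, st, dt = 5e-4, duration = 0.5, log_every = 100)
  r2 <- simulate_passive(sr_plant, sw, dt = 5e-4, duration = 0.5, log_every = 100)
  q1 <- do.call(rbind, r1$trajectory$q)
  q2 <- do.call(rbind, r2$trajectory$q)
  expect_equal(q1[, c(1:3, 7:9, 4:6)], q2, tolerance = 1e-10)
})
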