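test_that("default reflex delays match the published table", {
  d <- delay_table()
  expected <- c(tibialis_anterior = 35, soleus = 44, gastrocnemius = 54,
                vastus = 100, biceps_femoris_sh = 60, biceps_femoris_lh = 60,
                rectus_femoris = 82, gluteals = 40, iliopsoas = 40)
  expect_equal(setNames(d$delay_ms, d$muscle)[names(expected)], expected)
})

test_that("force feedback is linear in the delayed normalized force", {
  expect_equal(force_feedback(0.4, 0), 0)
  expect_equal(force_feedback(0.4, 1.5), 0.6)
  # published force-model tibialis anterior gain
  expect_equal(force_feedback(0.2, -1.45), -0.29)
  expect_error(force_feedback(-0.1, 1), "force")
})

test_that("length feedback is thresholded at the offset length", {
  expect_equal(length_feedback(0.5, 0.5, 2), 0)
  expect_equal(length_feedback(0.3, 0.5, 2), 0)     # below offset: silent
  expect_equal(length_feedback(0.3, 0.5, -3), 0)    # regardless of gain
  # published length-model soleus gain and offset
  expect_equal(length_feedback(0.6, 0.50, 1.15), 0.115, tolerance = 1e-12)
})

test_that("dead-zone gate matches an independent piecewise oracle on a fine grid", {
  heel_x <- -0.068; toe_x <- 0.205
  dz <- c(x_heel = 0.0574, x_toe = 0.0124, z_heel = 0.15, z_toe = 0.71)
  # independent piecewise-linear formula, written directly from its definition
  oracle <- function(x, G = 1) {
    b_h <- heel_x + dz[["x_heel"]]; b_t <- toe_x - dz[["x_toe"]]
    w_h <- dz[["z_heel"]] * dz[["x_heel"]]; w_t <- dz[["z_toe"]] * dz[["x_toe"]]
    if (x < b_h - w_h) return(-G)
    if (x < b_h) return(-G * (b_h - x) / w_h)
    if (x <= b_t) return(0)
    if (x <= b_t + w_t) return(G * (x - b_t) / w_t)
    G
  }
  xs <- seq(heel_x - 0.05, toe_x + 0.05, length.out = 1000)
  got <- effective_gain(xs, heel_x, toe_x, dz, gain = 1.5)
  want <- vapply(xs, oracle, numeric(1), G = 1.5)
  expect_equal(got, want, tolerance = 1e-12)
  # midpoint of the dead zone: exactly zero
  b_h <- heel_x + dz[["x_heel"]]; b_t <- toe_x - dz[["x_toe"]]
  expect_equal(effective_gain((b_h + b_t) / 2, heel_x, toe_x, dz, 2), 0)
  # midpoint of the toe transition band: +G/2
  w_t <- dz[["z_toe"]] * dz[["x_toe"]]
  expect_equal(effective_gain(b_t + w_t / 2, heel_x, toe_x, dz, 2), 1,
               tolerance = 1e-12)
  # continuity in x_com (steps bounded by the steepest ramp slope) and |g_eff| <= |G|
  w_min <- min(dz[["z_heel"]] * dz[["x_heel"]], dz[["z_toe"]] * dz[["x_toe"]])
  expect_true(all(abs(diff(got)) < 1.05 * 1.5 * max(diff(xs)) / w_min))
  expect_true(all(abs(got) <= 1.5 + 1e-12))
})

test_that("ill-ordered dead-zone edges are a configuration error", {
  dz <- c(x_heel = 0.10, x_toe = 0.10, z_heel = 0.5, z_toe = 0.5)
  expect_error(effective_gain(0, -0.02, 0.05, dz), "ill-ordered")
})

test_that("delayed channels reproduce inputs at the exact configured lag", {
  # zero delay: identity
  ch0 <- delayed_channel(0, 1e-3)
  channel_push(ch0, 5)
  expect_equal(delayed_read(ch0), 5)
  # constant input passes through unchanged
  ch <- delayed_channel(0.044, 1e-3, init = 7)
  for (i in 1:100) { v <- delayed_read(ch); channel_push(ch, 7); expect_equal(v, 7) }
  # a unit pulse at step t0 reappears exactly delay/dt steps later (soleus 44 ms)
  d_steps <- 44
  x <- numeric(300); x[100] <- 1
  ch2 <- delayed_channel(0.044, 1e-3, init = 0)
  y <- numeric(300)
  for (i in seq_along(x)) { y[i] <- delayed_read(ch2); channel_push(ch2, x[i]) }
  expect_equal(which(y == 1), 100 + d_steps)
  # the compiled in-loop buffer behaves identically
  y2 <- rs_delay_probe_cpp(x, d_steps, 0)
  expect_equal(y2, y)
  # before the delay has elapsed the initial value is returned
  ch3 <- delayed_channel(0.01, 1e-3, init = 3)
  channel_push(ch3, 9)
  expect_equal(delayed_read(ch3), 3)
  # a delay that is not a multiple of dt is a configuration error
  expect_error(delayed_channel(0.0445, 1e-3), "multiple")
})

test_that("stimulation clamps the summed drive to [0.001, 1]", {
  expect_equal(stimulation(0.26), 0.26)
  expect_equal(stimulation(0.26, 1.2), 1)
  expect_equal(stimulation(0.062, -0.5), 0.001)
  set.seed(3)
  u <- stimulation(runif(100, 0, 1), runif(100, -3, 3), runif(100, -3, 3))
  expect_true(all(u >= 0.001 & u <= 1))
})

test_that("published presets load, validate and respect architecture gating", {
  for (a in c("base", "length", "force")) {
    ctrl <- controller_preset(a)
    expect_s3_class(ctrl, "sr_controller")
    expect_equal(nrow(ctrl$gains), 9)
  }
  len <- controller_preset("length")
  expect_true(all(len$gains$g_ffb == 0))
  frc <- controller_preset("force")
  expect_true(all(frc$gains$g_lfb == 0))
  # spot-check published values
  base <- controller_preset("base")
  expect_equal(base$gains$g_ffb[base$gains$muscle == "soleus"], 1.50)
  expect_equal(base$gains$u0[base$gains$muscle == "tibialis_anterior"], 0.062)
  expect_equal(unname(base$deadzone["x_heel"]), 0.0574)
  # gating an edited controller
  b2 <- apply_architecture(base, "length")
  expect_true(all(b2$gains$g_ffb == 0))
})

test_that("controller_step: dead zone silences feedback; mirrored and gated", {
  ctrl <- controller_preset("base")
  sens <- tibble::tibble(
    muscle = rep(muscle_names(), 2), leg = rep(c("left", "right"), each = 9),
    f_norm = rep(runif(9, 0, 0.5), 2), l_norm = rep(runif(9, 0.4, 1.2), 2)
  )
  heel_x <- -0.068; toe_x <- 0.205
  b_h <- heel_x + ctrl$deadzone[["x_heel"]]; b_t <- toe_x - ctrl$deadzone[["x_toe"]]
  # COM inside the dead zone: stimulation is the clamped feedforward only
  out <- controller_step(ctrl, sens, (b_h + b_t) / 2, heel_x, toe_x)
  i <- match(out$muscle, ctrl$gains$muscle)
  expect_equal(out$u, stimulation(ctrl$gains$u0[i]))
  # identical sensor values in both legs give identical stimulations
  out2 <- controller_step(ctrl, sens, toe_x + 0.05, heel_x, toe_x)
  expect_equal(out2$u[out2$leg == "left"], out2$u[out2$leg == "right"])
  expect_true(all(out2$u >= 0.001 & out2$u <= 1))
  # length-only architecture is invariant to any force-feedback gains
  len <- controller_preset("length")
  len2 <- len; len2$gains$g_ffb <- runif(9, -3, 3)
  len2 <- apply_architecture(len2, "length")
  o1 <- controller_step(len, sens, toe_x + 0.05, heel_x, toe_x)
  o2 <- controller_step(len2, sens, toe_x + 0.05, heel_x, toe_x)
  expect_equal(o1$u, o2$u)
})

test_that("controller CSV round-trips losslessly", {
  ctrl <- controller_preset("base")
  path <- withr::local_tempfile(fileext = ".csv")
  write_controller_csv(ctrl, path)
  back <- read_controller_csv(path, architecture = "base")
  expect_equal(back$gains, ctrl$gains, tolerance = 1e-12)
  expect_equal(back$deadzone, ctrl$deadzone, tolerance = 1e-12)
})
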