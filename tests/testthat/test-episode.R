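fake_episode <- function(duration, chest_T, excursion, t_total = 110,
                         horizon = 100) {
  cfg <- episode_config(t_total = t_total, horizon = horizon)
  structure(list(
    trajectory = tibble::tibble(time = c(0, duration + 2), chest_y = c(1.7, chest_T)),
    survived = duration + 2, fell = duration < horizon, effort = 1,
    excursion = excursion, chest_T = chest_T, onset = 2, config = cfg
  ), class = "sr_episode")
}

test_that("effort: closed forms and independent quadrature oracle", {
  tt <- seq(0, 10, by = 0.01)
  zero <- tibble::tibble(time = tt, m1 = 0, m2 = 0)
  expect_equal(effort(zero), 0)
  half <- tibble::tibble(time = tt, m1 = rep(0.5, length(tt)))
  expect_equal(effort(half), 0.25, tolerance = 1e-12)
  # random activation traces against a trapezoid-rule oracle
  set.seed(13)
  a <- matrix(runif(length(tt) * 4), ncol = 4)
  tab <- tibble::as_tibble(as.data.frame(a))
  tab$time <- tt
  got <- effort(tab)
  s <- rowSums(a^2)
  oracle <- sum((s[-1] + s[-length(s)]) / 2 * diff(tt)) / (max(tt) - min(tt))
  expect_equal(got, oracle, tolerance = 1e-9)
  # invariant to resampling rate within quadrature tolerance
  tt2 <- seq(0, 10, by = 0.001)
  tab2 <- tibble::tibble(time = tt2, m1 = sin(tt2)^2 / 2 + 0.3)
  tab1 <- tibble::tibble(time = tt, m1 = sin(tt)^2 / 2 + 0.3)
  expect_equal(effort(tab1), effort(tab2), tolerance = 1e-4)
  expect_error(effort(tibble::tibble(time = tt, m1 = 2)), "\\[0, 1\\]")
})

test_that("constraint values flag violations at the stated bounds", {
  # early fall at 42 s after onset: duration constraint violated
  cv1 <- constraint_values(fake_episode(42, 1.0, 0.01))
  expect_false(cv1$satisfied[cv1$constraint == "duration"])
  # stationary ankle: excursion 0 < 0.05 satisfied
  expect_true(cv1$satisfied[cv1$constraint == "ankle_excursion"])
  # chest ends at 1.29 m: boundary violation of the 1.3 m bound
  cv2 <- constraint_values(fake_episode(105, 1.29, 0.01))
  expect_false(cv2$satisfied[cv2$constraint == "chest_height"])
  expect_true(cv2$satisfied[cv2$constraint == "duration"])
  cv3 <- constraint_values(fake_episode(105, 1.7, 0.06))
  expect_false(cv3$satisfied[cv3$constraint == "ankle_excursion"])
  # violation is 0 iff feasible, positive otherwise
  expect_equal(constraint_violation(fake_episode(105, 1.7, 0.01)), 0)
  expect_gt(constraint_violation(fake_episode(42, 1.0, 0.01)), 0)
})

test_that("episodes are deterministic and platform motion starts at onset", {
  sig <- generate_signal(seed = 17, duration = 10)
  cfg <- short_config()
  ctrl <- calibrated_preset("base")
  e1 <- run_episode(sr_plant, sr_mus, ctrl, sig, cfg)
  e2 <- run_episode(sr_plant, sr_mus, ctrl, sig, cfg)
  expect_identical(e1$trajectory, e2$trajectory)
  expect_identical(e1$effort, e2$effort)
  # phases: platform still until exactly t_pd + t_quiet = 2 s
  tr <- e1$trajectory
  expect_true(all(tr$platform_x[tr$time < 2] == 0))
  # a different perturbation cannot influence the pre-onset trajectory
  sig2 <- generate_signal(seed = 18, duration = 10)
  e3 <- run_episode(sr_plant, sr_mus, ctrl, sig2, cfg)
  pre <- tr$time <= 2
  expect_identical(tr[pre, ], e3$trajectory[e3$trajectory$time <= 2, ])
})

test_that("the calibrated base preset survives quiet stance", {
  cfg <- episode_config(t_total = 30, horizon = 27)
  ep <- run_episode(sr_plant, sr_mus, calibrated_preset("base"), NULL, cfg)
  expect_false(ep$fell)
  expect_equal(ep$survived, 30)
  expect_gt(ep$chest_T, 1.3)
})

test_that("a controller with minimal feedforward drive collapses", {
  ctrl <- calibrated_preset("base")
  ctrl$gains$u0 <- rep(0.001, 9)
  ctrl$gains$g_ffb <- rep(0, 9)
  ctrl$gains$g_lfb <- rep(0, 9)
  cfg <- episode_config(t_total = 20, horizon = 17)
  ep <- run_episode(sr_plant, sr_mus, ctrl, NULL, cfg)
  expect_true(ep$fell)
  expect_lt(ep$survived, 20)
})

test_that("episode effort agrees with the logged activation quadrature", {
  sig <- generate_signal(seed = 17, duration = 10)
  ep <- run_episode(sr_plant, sr_mus, calibrated_preset("base"), sig, short_config())
  expect_gte(ep$effort, 0)
  expect_equal(effort(ep), ep$effort, tolerance = 0.02)
})

test_that("trajectory CSV export writes the documented dialect in degrees", {
  ep <- run_episode(sr_plant, sr_mus, calibrated_preset("base"), NULL,
                    short_config(t_total = 4, horizon = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(ep, path)
  d <- utils::read.csv(path)
  expect_named(d, c("time", "trunk_x", "trunk_y", "trunk_pitch", "hip", "knee",
                    "ankle", "com_x", "com_y", "chest_y", "ankle_x", "grf_y"))
  expect_equal(d$hip, ep$trajectory$hip * 180 / pi, tolerance = 1e-9)
  tab <- as_trajectory_table(ep, from = 2, to = 4)
  expect_named(tab, c("time_s", "hip_deg", "knee_deg", "ankle_deg",
                      "hip_Nm", "knee_Nm", "ankle_Nm"))
  expect_equal(tab$time_s[1], 0)
})
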