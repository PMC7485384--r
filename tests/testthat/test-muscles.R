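test_that("the muscle set contains the nine leg muscles with published defaults", {
  expect_setequal(sr_mus$muscle,
                  c("iliopsoas", "gluteals", "rectus_femoris", "biceps_femoris_lh",
                    "biceps_femoris_sh", "vastus", "gastrocnemius", "soleus",
                    "tibialis_anterior"))
  expect_equal(nrow(sr_mus), 9)
  rf <- sr_mus[sr_mus$muscle == "rectus_femoris", ]
  expect_equal(rf$l_opt, 0.081)
  expect_equal(rf$f_max, 1200)
  expect_equal(rf$l_slack, 0.35)
  expect_equal(rf$pennation, 0.5)
  sh <- sr_mus[sr_mus$muscle == "biceps_femoris_sh", ]
  expect_equal(sh$l_opt, 0.12)
  expect_equal(sh$f_max, 1200)
  expect_equal(sh$l_slack, 0.10)
  expect_equal(sh$pennation, 0.7)
  ta <- sr_mus[sr_mus$muscle == "tibialis_anterior", ]
  expect_equal(ta$f_max, 4000)
})

test_that("musculotendon length: reference posture, monotonicity, biarticularity", {
  geo0 <- musculotendon_length(sr_mus)
  expect_equal(geo0$l_mtu,
               sr_mus$l_slack + sr_mus$pennation * sr_mus$l_opt, tolerance = 1e-12)
  # plantarflexion (negative ankle angle) shortens the soleus MTU
  sol <- function(a) {
    g <- musculotendon_length(sr_mus, ankle = a)
    g$l_mtu[g$muscle == "soleus"]
  }
  expect_lt(sol(-0.3), sol(0))
  expect_gt(sol(0.3), sol(0))  # dorsiflexion stretches it
  # gastrocnemius responds to both knee and ankle angles
  gas <- function(k, a) {
    g <- musculotendon_length(sr_mus, knee = k, ankle = a)
    g$l_mtu[g$muscle == "gastrocnemius"]
  }
  expect_false(isTRUE(all.equal(gas(0.3, 0), gas(0, 0))))
  expect_false(isTRUE(all.equal(gas(0, 0.3), gas(0, 0))))
  # smooth + monotone over the physiological range for a spanned joint
  ls <- vapply(seq(-0.5, 0.5, length.out = 21), sol, numeric(1))
  expect_true(all(diff(ls) > 0))
})

test_that("series elastic element force follows the quadratic strain curve", {
  for (mn in c("soleus", "rectus_femoris")) {
    m <- sr_mus[sr_mus$muscle == mn, ]
    expect_equal(see_force(sr_mus, mn, m$l_slack), 0)
    expect_equal(see_force(sr_mus, mn, 0.5 * m$l_slack), 0)
    expect_equal(see_force(sr_mus, mn, m$l_slack * (1 + m$eps_ref)), m$f_max,
                 tolerance = 1e-9)
    # mid-stretch value against the closed-form curve evaluated independently
    lmid <- m$l_slack * (1 + 0.37 * m$eps_ref)
    expect_equal(see_force(sr_mus, mn, lmid), m$f_max * 0.37^2, tolerance = 1e-9)
    # strictly increasing beyond slack
    ls <- m$l_slack * (1 + seq(0.01, 0.08, by = 0.01))
    expect_true(all(diff(see_force(sr_mus, mn, ls)) > 0))
  }
})

test_that("contraction dynamics solve the four-element force balance", {
  m <- sr_mus[sr_mus$muscle == "soleus", ]
  # isometric at full activation and optimal CE length: the SEE must carry
  # pennation * F_max, i.e. be stretched to strain sqrt(pennation) * eps_ref
  l_see <- m$l_slack * (1 + sqrt(m$pennation) * m$eps_ref)
  l_mtu <- l_see + m$pennation * m$l_opt
  r <- contraction_dynamics(sr_mus, "soleus", m$l_opt, 1, l_mtu)
  expect_equal(r$dlce_dt, 0, tolerance = 1e-6)
  expect_equal(r$f_see, m$pennation * m$f_max, tolerance = 1e-6)
  expect_lt(abs(r$residual), 1e-6 * m$f_max)
  # slack SEE, shortened CE, zero activation: only passive elements drive the
  # CE, and the buffer element pushes it back out (lengthening)
  lce <- 0.4 * m$l_opt
  r2 <- contraction_dynamics(sr_mus, "soleus", lce, 0, m$l_slack * 0.9)
  expect_gt(r2$f_be, 0)
  expect_gt(r2$dlce_dt, 0)
  # stretched SEE demanding more than isometric force: CE must lengthen,
  # delivering above-isometric force (force-velocity lengthening branch)
  l_see3 <- m$l_slack * (1 + 1.15 * sqrt(m$pennation) * m$eps_ref)
  r3 <- contraction_dynamics(sr_mus, "soleus", m$l_opt, 1, l_see3 + m$pennation * m$l_opt)
  expect_gt(r3$dlce_dt, 0)
  expect_gt(r3$f_see, m$pennation * m$f_max)
})

test_that("force-balance residual stays below 1e-6 F_max across random states", {
  set.seed(42)
  for (i in 1:200) {
    mi <- sample(nrow(sr_mus), 1)
    m <- sr_mus[mi, ]
    lce <- runif(1, 0.5, 1.5) * m$l_opt
    act <- runif(1)
    lmtu <- m$l_slack * runif(1, 0.97, 1.06) + m$pennation * lce
    r <- contraction_dynamics(sr_mus, m$muscle, lce, act, lmtu)
    if (!r$clipped) expect_lt(abs(r$residual), 1e-6 * m$f_max)
    expect_gte(r$f_see, 0)
  }
})

test_that("activation dynamics: fixed point, exponential rise, saturation", {
  expect_equal(activation_dynamics(0.4, 0.4, 0.01), 0.4)
  # step response reaches ~63% of the gap after one rise time constant
  a <- 0; dt <- 1e-4
  for (i in seq_len(round(0.01 / dt))) a <- activation_dynamics(a, 1, dt)
  expect_equal(a, 1 - exp(-1), tolerance = 0.01)
  # fall uses the slower time constant
  a2 <- 1
  for (i in seq_len(round(0.04 / dt))) a2 <- activation_dynamics(a2, 0, dt)
  expect_equal(a2, exp(-1), tolerance = 0.01)
  # out-of-range input is saturated, activation stays in [0, 1]
  expect_equal(activation_dynamics(1, 1.7, 0.1), 1)
  a3 <- 0.5
  set.seed(1)
  for (i in 1:500) {
    a3 <- activation_dynamics(a3, runif(1, -2, 3), 0.01)
    expect_gte(a3, 0); expect_lte(a3, 1)
  }
})

test_that("joint moments sum force times signed lever arm over spanning muscles", {
  f0 <- setNames(rep(0, 9), sr_mus$muscle)
  m0 <- joint_moments_from_muscles(sr_mus, f0)
  expect_equal(m0$moment, c(0, 0, 0))
  # single muscle: vastus 100 N on a 0.06 m extension lever -> -6 N m at knee
  f1 <- f0; f1["vastus"] <- 100
  m1 <- joint_moments_from_muscles(sr_mus, f1)
  expect_equal(m1$moment[m1$joint == "knee"], -6, tolerance = 1e-12)
  expect_equal(m1$moment[m1$joint == "hip"], 0)
  # antagonist pair with equal and opposite moments cancels
  rv <- sr_mus$r_knee[sr_mus$muscle == "vastus"]
  rb <- sr_mus$r_knee[sr_mus$muscle == "biceps_femoris_sh"]
  f2 <- f0; f2["vastus"] <- 120; f2["biceps_femoris_sh"] <- 120 * abs(rv) / rb
  m2 <- joint_moments_from_muscles(sr_mus, f2)
  expect_equal(m2$moment[m2$joint == "knee"], 0, tolerance = 1e-12)
})
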