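test_that("bounds have the architecture-dependent dimension and ranges", {
  b <- make_bounds("base")
  expect_equal(nrow(b), 40)  # 9 u0 + 9 g_ffb + 9 g_lfb + 9 l_off + 4 dead zone
  expect_equal(nrow(make_bounds("length")), 31)
  expect_equal(nrow(make_bounds("force")), 22)
  expect_false(any(make_bounds("force")$param == "l_off"))
  expect_false(any(make_bounds("length")$param == "g_ffb"))
  u0b <- b[b$param == "u0", ]
  expect_true(all(u0b$lower == 0.001 & u0b$upper == 1))
  expect_true(all(b$lower[b$param == "g_lfb"] == -3))
  expect_true(all(b$upper[b$param == "l_off"] == 1.1))
  expect_true(all(b$upper[b$param %in% c("x_toe", "x_heel")] == 0.10))
})

test_that("published presets lie within the optimization bounds", {
  for (a in c("base", "length", "force")) {
    z <- params_to_vector(controller_preset(a), a)
    b <- make_bounds(a)
    expect_true(all(z >= b$lower - 1e-12 & z <= b$upper + 1e-12))
    # round trip through the vector mapping
    ctrl2 <- vector_to_params(z, a)
    expect_equal(params_to_vector(ctrl2, a), z, tolerance = 1e-12)
  }
})

test_that("lexicographic ordering: feasibility dominates, then effort", {
  expect_equal(lexicographic_compare(lexicographic_score(0, 5.0),
                                     lexicographic_score(0.2, 0.1)), -1L)
  expect_equal(lexicographic_compare(lexicographic_score(0, 2),
                                     lexicographic_score(0, 1)), 1L)
  expect_equal(lexicographic_compare(lexicographic_score(0.5, 1),
                                     lexicographic_score(0.5, 1)), 0L)
  # exhaustive property on random score pairs
  set.seed(99)
  for (i in 1:500) {
    va <- sample(c(0, runif(1, 0, 2)), 1); vb <- sample(c(0, runif(1, 0, 2)), 1)
    ea <- runif(1, 0, 10); eb <- runif(1, 0, 10)
    a <- lexicographic_score(va, ea); b <- lexicographic_score(vb, eb)
    cmp <- lexicographic_compare(a, b)
    if (va == 0 && vb > 0) expect_equal(cmp, -1L)
    if (va > 0 && vb == 0) expect_equal(cmp, 1L)
    if (va == vb) expect_equal(cmp, sign(ea - eb))
    if (va > 0 && vb > 0 && va != vb) expect_equal(cmp, sign(va - vb))
    # antisymmetry
    expect_equal(lexicographic_compare(b, a), -cmp)
  }
})

test_that("PSO recovers the optimum of a 10-D sphere within 1e-3", {
  b <- tibble::tibble(lower = rep(-5, 10), upper = rep(5, 10))
  res <- pso_optimize(function(z) sum(z^2), b,
                      swarm_config(n_particles = 20, n_iter = 100, seed = 2))
  expect_lt(res$best_score$effort, 1e-3)
  expect_lt(max(abs(res$best)), 0.05)
})

test_that("PSO solves a constrained toy from the feasible side", {
  # minimize x^2 subject to x > 1: optimum at x = 1
  fn <- function(z) lexicographic_score(max(0, 1 - z[1]), z[1]^2)
  b <- tibble::tibble(lower = -4, upper = 4)
  res <- pso_optimize(fn, b, swarm_config(n_particles = 15, n_iter = 60, seed = 3))
  expect_equal(res$best_score$violation, 0)
  expect_equal(res$best[1], 1, tolerance = 1e-3)
  expect_gte(res$best[1], 1)  # converged from the feasible side
})

test_that("PSO is deterministic under a fixed seed and monotone in its best score", {
  b <- tibble::tibble(lower = rep(-2, 4), upper = rep(2, 4))
  fn <- function(z) sum((z - 0.5)^2)
  r1 <- pso_optimize(fn, b, swarm_config(n_particles = 10, n_iter = 30, seed = 11))
  r2 <- pso_optimize(fn, b, swarm_config(n_particles = 10, n_iter = 30, seed = 11))
  expect_identical(r1$best, r2$best)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best_effort) <= 1e-15))
  expect_true(all(diff(r1$history$best_violation) <= 1e-15))
})

test_that("all visited candidates respect the bounds after reflection", {
  b <- tibble::tibble(lower = c(-1, 0), upper = c(1, 0.5))
  seen <- list()
  fn <- function(z) { seen[[length(seen) + 1]] <<- z; sum(z^2) }
  invisible(pso_optimize(fn, b, swarm_config(n_particles = 8, n_iter = 25, seed = 4)))
  Z <- do.call(rbind, seen)
  expect_true(all(Z[, 1] >= -1 - 1e-12 & Z[, 1] <= 1 + 1e-12))
  expect_true(all(Z[, 2] >= -1e-12 & Z[, 2] <= 0.5 + 1e-12))
})

test_that("a crashing evaluation is scored maximally infeasible and the run continues", {
  b <- tibble::tibble(lower = -1, upper = 1)
  fn <- function(z) { if (abs(z[1]) < 0.2) stop("boom"); abs(z[1]) }
  res <- pso_optimize(fn, b, swarm_config(n_particles = 10, n_iter = 20, seed = 5))
  expect_equal(res$best_score$violation, 0)
  expect_gte(abs(res$best[1]), 0.2)
  expect_lt(res$best_score$effort, 0.35)
})

test_that("warm start: the final solution is never worse than the preset", {
  b <- tibble::tibble(lower = rep(-3, 5), upper = rep(3, 5))
  fn <- function(z) lexicographic_score(max(0, 0.5 - z[1]), sum(z^2))
  warm <- c(0.6, 0, 0, 0, 0)   # feasible preset
  warm_score <- fn(warm)
  res <- pso_optimize(fn, b, swarm_config(n_particles = 8, n_iter = 15, seed = 6,
                                          warm_start = warm))
  expect_lte(lexicographic_compare(res$best_score, warm_score), 0)
})

test_that("delay sweep bookkeeping: empty list and result collation", {
  empty <- delay_sweep(list(), sr_plant, sr_mus, "base", NULL)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("label", "com_delay", "violation", "effort", "controller")
                  %in% names(empty)))
  # two settings -> two rows with the configured delays recorded; the COM
  # trigger delay variant runs with otherwise identical configuration
  slow <- delay_table(); slow$delay_ms <- slow$delay_ms + 20
  res <- delay_sweep(
    list(list(label = "default", delays = delay_table()),
         list(label = "com20", com_delay = 0.020)),
    sr_plant, sr_mus, "base", NULL,
    swarm = swarm_config(n_particles = 3, n_iter = 2, seed = 1,
                         warm_start = calibrated_preset("base")),
    config = short_config())
  expect_equal(nrow(res), 2)
  expect_equal(res$label, c("default", "com20"))
  expect_equal(res$com_delay, c(0, 0.020))
  expect_s3_class(res$controller[[1]], "sr_controller")
})
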