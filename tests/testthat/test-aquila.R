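test_that("direction factor flips sign at one half", {
  expect_identical(direction_factor(0.3), 1)
  expect_identical(direction_factor(0.7), -1)
  expect_identical(direction_factor(0.5), -1)   # boundary takes else-branch
  expect_error(direction_factor(1.2), "\\[0, 1\\]")
})

test_that("the search control factor starts at 2e and decays monotonically", {
  expect_equal(m_scf(0, 250, r = 0.3), 2 * exp(1))
  expect_equal(m_scf(0, 250, r = 0.7), -2 * exp(1))
  T_max <- 250
  expect_equal(abs(m_scf(sqrt(10 * T_max), T_max, r = 0.1)), 2)
  vals <- vapply(0:T_max, function(t) abs(m_scf(t, T_max, r = 0)), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals <= 2 * exp(1) + 1e-12))
})

test_that("Levy steps are reproducible and heavy-tailed", {
  set.seed(10); a <- levy_flight(5)
  set.seed(10); b <- levy_flight(5)
  expect_identical(a, b)
  set.seed(11)
  draws <- replicate(1e5, levy_flight(1))
  k <- mean((draws - mean(draws))^4) / mean((draws - mean(draws))^2)^2
  expect_gt(k, 10)                              # far beyond Gaussian 3
  expect_error(levy_flight(0), ">= 1")
})

test_that("search step plug-in identities hold", {
  cfg <- ao_config(pop_size = 5, max_iter = 100, seed = 1)
  lb <- rep(-1e6, 3); ub <- rep(1e6, 3)   # wide box: no clamping in play
  best <- c(1, -2, 3); mean_pos <- c(0.5, 0.5, 0.5); cur <- c(0, 1, 0)

  expect_equal(step1_vertical_dive(best, mean_pos, t = 100, T = 100,
                                   lb, ub, r = 1),
               mean_pos - best)
  expect_equal(step1_vertical_dive(best, mean_pos, t = 0, T = 100,
                                   lb, ub, r = 0),
               best + mean_pos)

  rnd <- c(2, 2, 2)
  # zero factor or current == best: glide returns the random solution
  expect_equal(step2_glide(rnd, best, cur, 10, 100, lb, ub, cfg, factor = 0),
               rnd)
  set.seed(2)
  expect_equal(step2_glide(rnd, best, best, 10, 100, lb, ub, cfg), rnd)

  # at t = T the prey-attack term vanishes: pure box draw
  sp_lb <- rep(-4, 3); sp_ub <- rep(6, 3)
  set.seed(3)
  p <- step3_search_around(rnd, best, t = 100, T = 100, sp_lb, sp_ub, cfg,
                           r1 = 0.25, r2 = 0.9)
  expect_equal(p, sp_lb + 0.25 * (sp_ub - sp_lb))
  set.seed(3)
  p2 <- step3_search_around(rnd, best, t = 10, T = 100, sp_lb, sp_ub, cfg,
                            r1 = 0.25, r2 = 0)
  expect_equal(p2, sp_lb + 0.25 * (sp_ub - sp_lb))

  # QF(1) = 1 for any draw; G2(T) = 0 kills the Levy term
  expect_equal(quality_function(1, 250, 0.123), 1)
  expect_equal(quality_function(1, 250, 0.987), 1)
  set.seed(4)
  p4 <- step4_walk_grab(best, cur, t = 100, T = 100, lb, ub, cfg,
                        qf_r = 0.5, g1_r = 1, r = 0.5)
  qf <- quality_function(100, 100, 0.5)
  expect_equal(p4, qf * best - cur * 0.5)   # G1 = 1, G2 = 0
})

test_that("all step outputs stay inside the box under random inputs", {
  cfg <- ao_config(pop_size = 5, max_iter = 50, seed = 1)
  set.seed(99)
  for (i in 1:250) {
    d <- sample(2:8, 1)
    lb <- runif(d, -10, 0); ub <- runif(d, 1, 10)
    rnd_p <- runif(d, lb, ub); best <- runif(d, lb, ub)
    cur <- runif(d, lb, ub); mp <- runif(d, lb, ub)
    t <- sample(50, 1)
    outs <- list(step1_vertical_dive(best, mp, t, 50, lb, ub),
                 step2_glide(rnd_p, best, cur, t, 50, lb, ub, cfg),
                 step3_search_around(rnd_p, best, t, 50, lb, ub, cfg),
                 step4_walk_grab(best, cur, t, 50, lb, ub, cfg))
    for (o in outs) {
      expect_true(all(o >= lb - 1e-12))
      expect_true(all(o <= ub + 1e-12))
    }
  }
})

test_that("the optimizer is greedy, monotone and seed-deterministic", {
  sp <- search_space(rep(-5, 4), rep(5, 4))
  cfg <- ao_config(pop_size = 10, max_iter = 40, seed = 5)
  res <- ao_optimize(function(x) sum(x^2), sp, cfg)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$best_fitness, res$history[length(res$history)])
  expect_identical(length(res$history), 40L)
  expect_identical(res$evaluations, 10L + 10L * 40L)
  expect_true(all(res$best_position >= sp$lb & res$best_position <= sp$ub))
  res2 <- ao_optimize(function(x) sum(x^2), sp, cfg)
  expect_identical(res, res2)

  flat <- ao_optimize(function(x) 7, sp, cfg)
  expect_true(all(flat$history == 7))
  expect_equal(flat$best_fitness, 7)

  expect_error(ao_optimize(function(x) NaN, sp, cfg), "non-finite")
})

test_that("variants differ on identical seeds but share the skeleton", {
  sp <- search_space(rep(-5, 4), rep(5, 4))
  a <- ao_optimize(benchmarks()$sphere, sp,
                   ao_config(pop_size = 10, max_iter = 30, seed = 2,
                             variant = "MAO"))
  b <- ao_optimize(benchmarks()$sphere, sp,
                   ao_config(pop_size = 10, max_iter = 30, seed = 2,
                             variant = "AO"))
  expect_false(isTRUE(all.equal(a$best_position, b$best_position)))
  expect_true(all(diff(b$history) <= 0))
})

test_that("log-masked dimensions are searched in log10 coordinates", {
  sp <- search_space(c(1e-6, -1), c(1, 1), log_mask = c(TRUE, FALSE))
  res <- ao_optimize(function(p) (p[1] + 3)^2 + p[2]^2, sp,
                     ao_config(pop_size = 15, max_iter = 60, seed = 3))
  # optimum of the transformed coordinate is log10(x) = -3, i.e. x = 1e-3
  expect_lt(abs(res$best_position[1] + 3), 0.05)
})

test_that("benchmark objectives vanish at the origin", {
  b <- benchmarks()
  expect_equal(b$sphere(rep(0, 10)), 0)
  expect_equal(b$rastrigin(rep(0, 10)), 0)
  expect_equal(b$ackley(rep(0, 10)), 0, tolerance = 1e-12)
  expect_gt(b$rastrigin(rep(0.5, 10)), 0)
})
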