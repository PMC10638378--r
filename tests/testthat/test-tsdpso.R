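test_that("mean particle distance matches the direct formula", {
  expect_equal(mean_particle_distance(matrix(c(1, 2), 1, 2)), 0)
  pos <- rbind(c(0, 0), c(3, 4))
  expect_equal(mean_particle_distance(pos, 1), 2.5)
  expect_equal(mean_particle_distance(pos), c(2.5, 2.5))
  same <- matrix(1, 5, 3)
  expect_equal(mean_particle_distance(same), rep(0, 5))
  expect_error(mean_particle_distance(pos, 7), "out of range")
})

test_that("evolution factor normalizes the spread statistic into [0,1]", {
  expect_equal(evolution_factor(1, 1, 5), 0)
  expect_equal(evolution_factor(5, 1, 5), 1)
  expect_equal(evolution_factor(3, 1, 5), 0.5)
  expect_equal(evolution_factor(2, 2, 2), 0)  # collapsed swarm
  expect_error(evolution_factor(0.5, 1, 5), "d_g")
})

test_that("state classification uses quartile bins with inclusive upper edges", {
  expect_equal(classify_state(0.10), 1L)
  expect_equal(classify_state(0.25), 1L)
  expect_equal(classify_state(0.251), 2L)
  expect_equal(classify_state(0.5), 2L)
  expect_equal(classify_state(0.75), 3L)
  expect_equal(classify_state(0.76), 4L)
  expect_equal(classify_state(1), 4L)
  expect_error(classify_state(1.2), "0, 1")
})

test_that("transition matrix is tridiagonal row-stochastic for any persistence", {
  for (x in c(0, 0.3, 0.6, 1)) {
    P <- transition_matrix(x)
    expect_equal(rowSums(P), rep(1, 4))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(diag(P), rep(x, 4))
    expect_equal(P[1, 3:4], c(0, 0))
    expect_equal(P[4, 1:2], c(0, 0))
  }
  expect_error(transition_matrix(1.5), "0, 1")
})

test_that("next_state honours point masses and deterministic mode", {
  set.seed(1)
  expect_equal(next_state(3, transition_matrix(1)), 3L)
  expect_equal(next_state(1, transition_matrix(0)), 2L)
  expect_equal(next_state(4, transition_matrix(0.99999)), 4L)
  expect_equal(next_state(3, mode = "deterministic"), 3L)
  bad <- matrix(0.5, 4, 4)
  expect_error(next_state(1, bad), "summing to 1")
})

test_that("inertia schedule is w = 0.5 Ef + 0.4", {
  expect_equal(inertia_weight(1), 0.9)
  expect_equal(inertia_weight(0), 0.4)
  expect_equal(inertia_weight(0.5), 0.65)
  expect_error(inertia_weight(-0.1), "0, 1")
})

test_that("state-dependent acceleration coefficients match the fixed table", {
  expect_equal(state_parameters(1)[c("c1", "c2")], list(c1 = 2, c2 = 2))
  expect_equal(state_parameters(2)[c("c1", "c2")], list(c1 = 2.1, c2 = 1.9))
  expect_equal(state_parameters(3)[c("c1", "c2")], list(c1 = 2.2, c2 = 1.8))
  expect_equal(state_parameters(4)[c("c1", "c2")], list(c1 = 1.8, c2 = 2.2))
})

test_that("delay selection follows the per-state rule and caps at history depth", {
  pol <- delay_policy(tau_max = 10)
  expect_equal(select_delays(1, 100, pol), c(0L, 0L))
  expect_equal(select_delays(4, 0, pol), c(0L, 0L))
  set.seed(5)
  for (i in 1:50) {
    t3 <- select_delays(3, 100, pol)
    expect_true(t3[1] %in% 1:10)
    expect_equal(t3[2], 0L)
    t2 <- select_delays(2, 100, pol)
    expect_equal(t2[1], 0L)
    expect_true(t2[2] %in% 1:10)
    t4 <- select_delays(4, 3, pol)
    expect_true(all(t4 %in% 1:3))
  }
})

test_that("traction term scales the delayed-gbest pull by relative fitness", {
  w <- c(2, -1, 0.5)
  expect_equal(traction_term(1, 1, 3, w, rep(0, 3), 0.8), rep(0, 3))
  expect_equal(traction_term(3, 1, 3, w, rep(0, 3), 1), w)
  expect_equal(traction_term(5, 5, 5, w, rep(0, 3), 1), rep(0, 3))
  expect_error(traction_term(1, 0, 2, c(1, 2), c(1)), "same length")
})

test_that("switching-delay velocity update reduces to the standard rule at zero delay", {
  v <- c(1, -2); x <- c(0.5, 0.5); p <- c(2, 2); g <- c(-1, 3)
  expect_equal(
    tsdpso_velocity_update(v, x, p, g, 0.7, 2, 2, 0.3, 0.6, v_max = 4),
    pso_velocity_update(v, x, p, g, 0.7, 2, 2, 0.3, 0.6, v_max = 4))
  expect_equal(
    tsdpso_velocity_update(v, x, p, g, 1, 0, 0, 0.3, 0.6, traction = c(1, 1)),
    v + c(1, 1))
})

test_that("degenerate-config TSDPSO replays standard PSO step for step", {
  obj <- benchmark_objective("sphere", 5)
  cfg <- swarm_config(max_iterations = 50, convergence_tolerance = 0)
  a <- optimize_pso(obj, cfg, seed = 7)
  b <- optimize_tsdpso(obj, cfg,
                       delay_policy = delay_policy(tau_max = 0),
                       traction = traction_config(enabled = FALSE),
                       state_mode = "deterministic",
                       adaptive_inertia = FALSE, seed = 7)
  expect_identical(a$convergence_curve, b$convergence_curve)
  expect_identical(a$gbest_position, b$gbest_position)
  expect_identical(a$gbest_fitness, b$gbest_fitness)
})

test_that("TSDPSO run is deterministic under seed with a valid state trace", {
  obj <- benchmark_objective("rastrigin", 5)
  cfg <- swarm_config(max_iterations = 60, convergence_tolerance = 0)
  r1 <- optimize_tsdpso(obj, cfg, seed = 11)
  r2 <- optimize_tsdpso(obj, cfg, seed = 11)
  expect_identical(r1, r2)
  expect_true(all(r1$state_trace %in% 1:4))
  expect_length(r1$state_trace, r1$iterations_used)
  expect_true(all(diff(r1$convergence_curve) <= 0))
})

test_that("a constant objective terminates flat with states in range", {
  const <- list(dimension = 2, lower = c(-1, -1), upper = c(1, 1),
                evaluate = function(x) 7)
  res <- optimize_tsdpso(const, swarm_config(max_iterations = 10,
                                             convergence_tolerance = 0),
                         seed = 1)
  expect_equal(unique(res$convergence_curve), 7)
  expect_true(all(res$state_trace %in% 1:4))
})

test_that("traction is never applied before the stall threshold is reached", {
  # a particle whose pbest improved within the window has stall_count < 10;
  # verify via the loop bookkeeping on a short deterministic run
  obj <- benchmark_objective("sphere", 3)
  res <- optimize_tsdpso(obj, swarm_config(max_iterations = 9,
                                           convergence_tolerance = 0),
                         traction = traction_config(stall_threshold = 10),
                         seed = 2)
  # with only 9 iterations no particle can have stalled 10 times, so a run
  # with traction disabled must be identical
  res2 <- optimize_tsdpso(obj, swarm_config(max_iterations = 9,
                                            convergence_tolerance = 0),
                          traction = traction_config(enabled = FALSE),
                          seed = 2)
  expect_identical(res$convergence_curve, res2$convergence_curve)
})

test_that("tidy/glance/autoplot expose the optimization trace", {
  obj <- benchmark_objective("sphere", 2)
  res <- optimize_tsdpso(obj, swarm_config(max_iterations = 15,
                                           convergence_tolerance = 0),
                         seed = 1)
  td <- tidy(res)
  expect_named(td, c("iteration", "best_fitness", "state"))
  expect_equal(nrow(td), res$iterations_used + 1)
  gl <- glance(res)
  expect_equal(gl$gbest_fitness, res$gbest_fitness)
  expect_s3_class(autoplot(res), "ggplot")
})
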