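test_that("the exploration coefficient decays linearly from 2 to 0", {
  expect_equal(gwo_decay(0, 10), 2)
  expect_equal(gwo_decay(10, 10), 0)
  expect_equal(gwo_decay(5, 10), 1)
  expect_error(gwo_decay(11, 10), "0 <= t")
})

test_that("coefficient vectors respect their ranges", {
  withr::with_seed(1, {
    for (a in c(2, 1.3, 0.4)) {
      k <- gwo_coefficients(a, 50)
      expect_true(all(abs(k$A) <= a))
      expect_true(all(k$C >= 0 & k$C <= 2))
    }
    # a = 0 forces A to zero whatever the randoms
    k0 <- gwo_coefficients(0, 20)
    expect_equal(k0$A, rep(0, 20))
  })
})

test_that("with zero decay the update averages the three leaders", {
  withr::with_seed(2, {
    # decay_a = 0 makes every A zero, so the move is (X1+X2+X3)/3 exactly
    out <- gwo_update_position(c(0, 0), alpha = c(1, 2), beta = c(3, 4),
                               delta = c(5, 6), decay_a = 0)
    expect_equal(out, c(3, 4))
    # 1-D: X = 0, leaders all 4 -> 4
    expect_equal(gwo_update_position(0, 4, 4, 4, 0), 4)
  })
})

test_that("GWO minimises simple quadratics for most seeds", {
  hits2d <- sum(vapply(1:10, function(s) {
    r <- gwo_optimize(function(x) sum(x^2),
                      gwo_config(c(-5, -5), c(5, 5), n_agents = 10,
                                 max_iter = 100, seed = s))
    r$best_fitness < 1e-2
  }, logical(1)))
  expect_gte(hits2d, 9)

  hits1d <- sum(vapply(1:10, function(s) {
    r <- gwo_optimize(function(x) (x - 3)^2,
                      gwo_config(0, 5, n_agents = 10, max_iter = 50, seed = s))
    abs(r$best_position - 3) < 0.1
  }, logical(1)))
  expect_gte(hits1d, 9)
})

test_that("best-ever tracking, bounds and history monotonicity hold", {
  seen <- new.env()
  seen$fits <- numeric(0)
  seen$pos <- list()
  obj <- function(x) {
    f <- sum((x - 1)^2)
    seen$fits <- c(seen$fits, f)
    seen$pos <- c(seen$pos, list(x))
    f
  }
  cfg <- gwo_config(c(-2, -2, -2), c(2, 2, 2), n_agents = 5, max_iter = 20,
                    seed = 11)
  r <- gwo_optimize(obj, cfg)
  # the reported optimum is exactly the best evaluation ever made
  expect_equal(r$best_fitness, min(seen$fits))
  expect_equal(r$n_evals, length(seen$fits))
  # every evaluated position stayed inside the box
  expect_true(all(vapply(seen$pos, function(p) all(p >= -2 & p <= 2),
                         logical(1))))
  expect_true(all(r$best_position >= -2 & r$best_position <= 2))
  expect_true(all(diff(r$fitness_history) <= 0))
  expect_equal(r$best_fitness, r$fitness_history[length(r$fitness_history)])

  # max_iter = 1 with 3 agents: result is the best of the initial evaluations
  seen$fits <- numeric(0)
  r1 <- gwo_optimize(obj, gwo_config(c(-2, -2, -2), c(2, 2, 2), n_agents = 3,
                                     max_iter = 1, seed = 4))
  expect_equal(r1$best_fitness, min(seen$fits[1:3]))
})

test_that("identical seeds give bit-identical results and more budget never hurts", {
  cfg <- gwo_config(c(-5, -5), c(5, 5), n_agents = 8, max_iter = 30, seed = 99)
  obj <- function(x) sum(x^2) + 0.1 * sum(sin(3 * x))
  r1 <- gwo_optimize(obj, cfg)
  r2 <- gwo_optimize(obj, cfg)
  expect_identical(r1, r2)

  # statistically over seeds: doubling the budget does not worsen the optimum
  short <- vapply(1:8, function(s) gwo_optimize(
    function(x) sum(x^2), gwo_config(c(-5, -5), c(5, 5), max_iter = 20,
                                     seed = s))$best_fitness, numeric(1))
  long <- vapply(1:8, function(s) gwo_optimize(
    function(x) sum(x^2), gwo_config(c(-5, -5), c(5, 5), max_iter = 40,
                                     seed = s))$best_fitness, numeric(1))
  expect_lte(median(long), median(short))
})

test_that("configuration and objective errors are caught", {
  expect_error(gwo_config(0, 5, n_agents = 2), "3 agents")
  expect_error(gwo_config(0, 5, max_iter = 0), "max_iter")
  expect_error(gwo_config(c(1, 1), c(1, 2)), "lower < upper")
  expect_error(gwo_config(0, 5, warm_start_position = 9), "inside the bounds")
  expect_error(
    gwo_optimize(function(x) NaN, gwo_config(0, 1, seed = 1)),
    "non-finite"
  )
})

test_that("warm start pins one agent and tidy/glance expose the run", {
  obj <- function(x) sum((x - 1)^2)
  cfg <- gwo_config(rep(-2, 3), rep(2, 3), n_agents = 5, max_iter = 1,
                    seed = 5, warm_start_position = c(1, 1, 1))
  r <- gwo_optimize(obj, cfg)
  expect_equal(r$best_fitness, 0)  # the warm agent is already optimal
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_named(td, c("iteration", "best_fitness"))
  gl <- glance(r)
  expect_equal(gl$n_agents, 5)
})
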