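#' Grey Wolf Optimizer configuration
#'
#' The Grey Wolf Optimizer (GWO) is a population metaheuristic in which the
#' three best agents found so far (alpha, beta, delta) steer the whole pack.
#' Exploration is controlled by a coefficient that decays linearly from 2 to 0
#' over the iterations.
#'
#' The defaults (10 agents, 10 iterations) are the published operating point
#' for per-beat template scaling; cheap objectives tolerate far larger
#' budgets.
#'
#' @param lower,upper Numeric vectors of per-dimension bounds (recycled to a
#'   common length); `lower < upper` componentwise.
#' @param n_agents Number of wolves; at least 3 so alpha/beta/delta exist.
#' @param max_iter Number of iterations, at least 1.
#' @param seed Integer seed; the optimizer is bit-reproducible given the seed.
#' @param warm_start_position Optional numeric vector: one agent is pinned to
#'   this position at initialisation (the rest stay random).
#' @return A `gwo_config` list.
#' @export
gwo_config <- function(lower, upper, n_agents = 10L, max_iter = 10L,
                       seed = 1L, warm_start_position = NULL) {
  dim <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort("Bounds must be finite with lower < upper in every dimension.")
  }
  if (n_agents < 3L) abort("GWO needs at least 3 agents (alpha, beta, delta).")
  if (max_iter < 1L) abort("max_iter must be >= 1.")
  if (!is.null(warm_start_position)) {
    warm_start_position <- rep_len(as.numeric(warm_start_position), dim)
    if (any(warm_start_position < lower | warm_start_position > upper)) {
      abort("warm_start_position must lie inside the bounds.")
    }
  }
  structure(
    list(lower = lower, upper = upper, dim = dim,
         n_agents = as.integer(n_agents), max_iter = as.integer(max_iter),
         seed = as.integer(seed), warm_start_position = warm_start_position),
    class = "gwo_config"
  )
}

#' Linear decay of the GWO exploration coefficient
#'
#' Returns `2 - 2 t / max_iter`: the coefficient decreases linearly from 2 at
#' `t = 0` to 0 at `t = max_iter`.
#'
#' @param t Current iteration, `0 <= t <= max_iter`.
#' @param max_iter Total number of iterations.
#' @return The decay value in `[0, 2]`.
#' @export
gwo_decay <- function(t, max_iter) {
  if (t < 0 || t > max_iter) abort("t must satisfy 0 <= t <= max_iter.")
  2 - (2 * t) / max_iter
}

#' Draw the GWO coefficient vectors A and C
#'
#' `A = 2 a r1 - a` with `r1 ~ U[0,1]` per dimension (so `A` ranges over
#' `[-2a, 2a]`), and `C = 2 r2` with `r2 ~ U[0,1]` (so `C` ranges over
#' `[0, 2]`). Fresh randoms are drawn on every call from the current RNG
#' state.
#'
#' @param decay_a Current decay coefficient in `[0, 2]`.
#' @param dim Dimensionality.
#' @return List with numeric vectors `A` and `C`.
#' @export
gwo_coefficients <- function(decay_a, dim) {
  if (decay_a < 0 || decay_a > 2) abort("decay_a must be in [0, 2].")
  r1 <- runif(dim)
  r2 <- runif(dim)
  list(A = 2 * decay_a * r1 - decay_a, C = 2 * r2)
}

#' Leader-guided position update
#'
#' One wolf's move: for each leader L in (alpha, beta, delta), draw
#' independent coefficient vectors, form the encircling distance
#' `D_L = |C . X_L - X|` and the candidate `X_L - A . D_L`, then average the
#' three candidates. The caller clips the result to the search box.
#'
#' @param x Current position (numeric vector).
#' @param alpha,beta,delta Leader positions.
#' @param decay_a Current decay coefficient.
#' @return The proposed new position (unclipped).
#' @export
gwo_update_position <- function(x, alpha, beta, delta, decay_a) {
  dim <- length(x)
  move_towards <- function(leader) {
    k <- gwo_coefficients(decay_a, dim)
    d <- abs(k$C * leader - x)
    leader - k$A * d
  }
  (move_towards(alpha) + move_towards(beta) + move_towards(delta)) / 3
}

#' Run the Grey Wolf Optimizer
#'
#' Minimises `objective` over the bounded box in `cfg`. Agents start uniform
#' in the box (optionally one warm-started). Each iteration evaluates all
#' agents, updates the saved alpha/beta/delta leaders — the three best
#' solutions seen so far, improved in place with ties resolved in favour of
#' the earlier-evaluated agent — and moves every agent by
#' [gwo_update_position()] with componentwise clipping to the box.
#'
#' Because the leaders only ever improve, the returned history (the alpha
#' fitness after each iteration) is monotonically non-increasing.
#'
#' @param objective Function mapping a numeric vector to a finite scalar.
#' @param cfg A [gwo_config()].
#' @return A `gwo_result` with `best_position`, `best_fitness`,
#'   `fitness_history` (length `max_iter`) and `n_evals`.
#' @examples
#' res <- gwo_optimize(function(x) sum(x^2),
#'                     gwo_config(c(-5, -5), c(5, 5), max_iter = 50, seed = 7))
#' res$best_fitness
#' @export
gwo_optimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "gwo_config"))
  withr::with_seed(cfg$seed, gwo_optimize_impl(objective, cfg))
}

gwo_optimize_impl <- function(objective, cfg) {
  n <- cfg$n_agents
  dim <- cfg$dim
  pos <- matrix(runif(n * dim, rep(cfg$lower, each = n), rep(cfg$upper, each = n)),
                nrow = n)
  if (!is.null(cfg$warm_start_position)) {
    pos[1, ] <- cfg$warm_start_position
  }
  clip <- function(p) pmin(pmax(p, cfg$lower), cfg$upper)
  eval_agent <- function(p) {
    f <- objective(p)
    if (!is.finite(f)) {
      abort(paste0("Objective returned a non-finite value at position (",
                   paste(signif(p, 6), collapse = ", "), ")."))
    }
    f
  }
  # Leaders persist across iterations: alpha/beta/delta hold the three best
  # solutions seen so far and are only ever improved (strict <, so the
  # earlier-evaluated agent wins ties).
  alpha_fit <- beta_fit <- delta_fit <- Inf
  alpha <- beta <- delta <- rep(NA_real_, dim)
  history <- numeric(cfg$max_iter)
  n_evals <- 0L
  for (t in seq_len(cfg$max_iter)) {
    for (i in seq_len(n)) {
      f <- eval_agent(pos[i, ])
      n_evals <- n_evals + 1L
      if (f < alpha_fit) {
        delta_fit <- beta_fit; delta <- beta
        beta_fit <- alpha_fit; beta <- alpha
        alpha_fit <- f; alpha <- pos[i, ]
      } else if (f < beta_fit) {
        delta_fit <- beta_fit; delta <- beta
        beta_fit <- f; beta <- pos[i, ]
      } else if (f < delta_fit) {
        delta_fit <- f; delta <- pos[i, ]
      }
    }
    history[t] <- alpha_fit
    # first move explores at full a = 2; a reaches 0 only after the last
    # evaluated iteration
    decay_a <- gwo_decay(t - 1, cfg$max_iter)
    for (i in seq_len(n)) {
      pos[i, ] <- clip(gwo_update_position(pos[i, ], alpha, beta, delta, decay_a))
    }
  }
  structure(
    list(best_position = alpha, best_fitness = alpha_fit,
         fitness_history = history, n_evals = n_evals, config = cfg),
    class = "gwo_result"
  )
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf("<gwo_result: best fitness %.6g after %d evaluations (dim %d)>\n",
              x$best_fitness, x$n_evals, length(x$best_position)))
  invisible(x)
}

#' @export
tidy.gwo_result <- function(x, ...) {
  tibble(iteration = seq_along(x$fitness_history),
         best_fitness = x$fitness_history)
}

#' @export
glance.gwo_result <- function(x, ...) {
  tibble(best_fitness = x$best_fitness,
         n_evals = x$n_evals,
         n_agents = x$config$n_agents,
         max_iter = x$config$max_iter,
         dim = x$config$dim)
}

#' @export
autoplot.gwo_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iteration, y = .data$best_fitness)) +
    geom_line() +
    labs(x = "Iteration", y = "Best-ever fitness",
         title = "GWO convergence") +
    theme_minimal()
}
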