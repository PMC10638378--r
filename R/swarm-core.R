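#' Swarm configuration
#'
#' Bundles the shared settings of the particle swarm optimizers. Defaults
#' follow the common small-swarm setup used for SVM hyperparameter tuning:
#' 20 particles, 500 iterations, acceleration coefficients 2/2, initial
#' inertia weight 0.9, velocity cap 4 and a convergence tolerance of 1e-3
#' on the best fitness.
#'
#' @param swarm_size Number of particles.
#' @param max_iterations Iteration budget.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param inertia Inertia weight `w` (the TSDPSO optimizer replaces it each
#'   iteration with its evolution-factor schedule unless told otherwise).
#' @param v_max Elementwise velocity cap; velocities are clamped to
#'   `[-v_max, v_max]`.
#' @param convergence_tolerance Stop once the best fitness drops to or below
#'   this value (assumes a minimization target with optimum near 0; set to
#'   `-Inf` to always run the full budget).
#' @param rand_mode `"vector"` (default) draws `r1` and `r2` per coordinate;
#'   `"scalar"` draws one of each per particle per iteration. Per-coordinate
#'   draws are the standard practical choice — per-particle scalars confine
#'   each move to a two-difference-vector plane and visibly stall
#'   convergence.
#' @return A list of class `"swarm_config"`.
#' @export
swarm_config <- function(swarm_size = 20, max_iterations = 500,
                         c1 = 2, c2 = 2, inertia = 0.9, v_max = 4,
                         convergence_tolerance = 1e-3,
                         rand_mode = c("vector", "scalar")) {
  rand_mode <- match.arg(rand_mode)
  stopifnot(swarm_size >= 1, max_iterations >= 1, c1 > 0, c2 > 0, v_max > 0)
  structure(
    list(swarm_size = as.integer(swarm_size),
         max_iterations = as.integer(max_iterations),
         c1 = c1, c2 = c2, inertia = inertia, v_max = v_max,
         convergence_tolerance = convergence_tolerance,
         rand_mode = rand_mode),
    class = "swarm_config"
  )
}

validate_objective <- function(objective) {
  stopifnot(is.list(objective), is.function(objective$evaluate))
  d <- objective$dimension
  if (is.null(d) || d < 1) stop("objective dimension must be >= 1", call. = FALSE)
  lower <- objective$lower
  upper <- objective$upper
  if (length(lower) != d || length(upper) != d || any(lower >= upper)) {
    stop("objective bounds must satisfy lower < upper elementwise",
         call. = FALSE)
  }
  objective
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly inside the search box, velocities uniformly
#' in `[-v_max, v_max]`; each particle's personal best starts at its initial
#' position and the global best is the best initial fitness. Deterministic
#' given `seed`.
#'
#' @param objective A list with fields `dimension`, `lower`, `upper` and
#'   `evaluate` (see [benchmark_objective()]).
#' @param config A [swarm_config()].
#' @param seed Integer seed.
#' @return A swarm state list: `position` and `velocity` matrices
#'   (particles by coordinates), `fitness`, `pbest_position`,
#'   `pbest_fitness`, `stall_count`, `gbest_position`, `gbest_fitness`.
#' @export
initialize_swarm <- function(objective, config = swarm_config(), seed = 1L) {
  objective <- validate_objective(objective)
  set.seed(seed)
  s <- config$swarm_size
  d <- objective$dimension
  u <- matrix(stats::runif(s * d), s, d)
  position <- sweep(sweep(u, 2, objective$upper - objective$lower, "*"),
                    2, objective$lower, "+")
  velocity <- matrix(stats::runif(s * d, -config$v_max, config$v_max), s, d)
  fitness <- apply(position, 1, objective$evaluate)
  if (any(!is.finite(fitness))) {
    stop("objective returned a non-finite value during initialization for particle ",
         which(!is.finite(fitness))[1], call. = FALSE)
  }
  g <- which.min(fitness)
  list(position = position, velocity = velocity, fitness = fitness,
       pbest_position = position, pbest_fitness = fitness,
       stall_count = integer(s),
       gbest_position = position[g, ], gbest_fitness = fitness[g])
}

#' Canonical PSO velocity update
#'
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, clamped elementwise to
#' `[-v_max, v_max]`. `r1` and `r2` may be scalars or per-coordinate vectors.
#'
#' @param velocity,position,pbest,gbest Numeric vectors of equal length.
#' @param inertia,c1,c2 Update coefficients.
#' @param r1,r2 Uniform draws in `[0, 1]`.
#' @param v_max Velocity cap (default unbounded).
#' @return The new velocity vector.
#' @export
pso_velocity_update <- function(velocity, position, pbest, gbest,
                                inertia, c1, c2, r1, r2, v_max = Inf) {
  d <- length(velocity)
  if (length(position) != d || length(pbest) != d || length(gbest) != d) {
    stop("velocity, position, pbest and gbest must have the same length",
         call. = FALSE)
  }
  v <- inertia * velocity + c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  pmin(pmax(v, -v_max), v_max)
}

#' PSO position update with box clamping
#'
#' `x' = x + v`, clamped into the search box; any coordinate that hits a
#' bound has its velocity coordinate zeroed so the particle does not keep
#' pushing against the wall.
#'
#' @param position,velocity Numeric vectors of equal length.
#' @param lower,upper Box bounds.
#' @return A list with the new `position` and (possibly zeroed) `velocity`.
#' @export
pso_position_update <- function(position, velocity, lower, upper) {
  if (length(position) != length(velocity)) {
    stop("position and velocity must have the same length", call. = FALSE)
  }
  x <- position + velocity
  clamped <- x < lower | x > upper
  x <- pmin(pmax(x, lower), upper)
  velocity[clamped] <- 0
  list(position = x, velocity = velocity)
}

draw_r <- function(config, d) {
  if (config$rand_mode == "scalar") stats::runif(1) else stats::runif(d)
}

update_bests <- function(swarm) {
  improved <- swarm$fitness < swarm$pbest_fitness
  swarm$pbest_fitness[improved] <- swarm$fitness[improved]
  swarm$pbest_position[improved, ] <- swarm$position[improved, , drop = FALSE]
  swarm$stall_count <- ifelse(improved, 0L, swarm$stall_count + 1L)
  g <- which.min(swarm$pbest_fitness)
  if (swarm$pbest_fitness[g] < swarm$gbest_fitness) {
    swarm$gbest_fitness <- swarm$pbest_fitness[g]
    swarm$gbest_position <- swarm$pbest_position[g, ]
  }
  swarm
}

new_pso_result <- function(swarm, curve, iterations_used, method,
                           state_trace = integer(0)) {
  structure(
    list(gbest_position = swarm$gbest_position,
         gbest_fitness = swarm$gbest_fitness,
         convergence_curve = curve,
         iterations_used = iterations_used,
         state_trace = state_trace,
         method = method),
    class = "pso_result"
  )
}

#' Standard particle swarm optimization
#'
#' Runs the canonical global-best PSO: every particle follows its own best
#' position and the swarm's best position with constant inertia and
#' acceleration coefficients. Stops at the iteration budget or once the best
#' fitness reaches `convergence_tolerance`.
#'
#' @inheritParams initialize_swarm
#' @return A `"pso_result"`: `gbest_position`, `gbest_fitness`,
#'   `convergence_curve` (best fitness after initialization and after each
#'   iteration), `iterations_used`, empty `state_trace`, and `method`.
#'   [tidy.pso_result()], [glance.pso_result()] and [autoplot.pso_result()]
#'   apply.
#' @examples
#' obj <- benchmark_objective("sphere", dimension = 2)
#' res <- optimize_pso(obj, swarm_config(max_iterations = 50), seed = 1)
#' res$gbest_fitness
#' @export
optimize_pso <- function(objective, config = swarm_config(), seed = 1L) {
  objective <- validate_objective(objective)
  swarm <- initialize_swarm(objective, config, seed)
  d <- objective$dimension
  curve <- numeric(config$max_iterations + 1)
  curve[1] <- swarm$gbest_fitness
  iterations_used <- 0L
  for (k in seq_len(config$max_iterations)) {
    if (swarm$gbest_fitness <= config$convergence_tolerance) break
    for (i in seq_len(config$swarm_size)) {
      r1 <- draw_r(config, d)
      r2 <- draw_r(config, d)
      v <- pso_velocity_update(swarm$velocity[i, ], swarm$position[i, ],
                               swarm$pbest_position[i, ],
                               swarm$gbest_position,
                               config$inertia, config$c1, config$c2,
                               r1, r2, config$v_max)
      upd <- pso_position_update(swarm$position[i, ], v,
                                 objective$lower, objective$upper)
      swarm$position[i, ] <- upd$position
      swarm$velocity[i, ] <- upd$velocity
    }
    swarm$fitness <- apply(swarm$position, 1, objective$evaluate)
    if (any(!is.finite(swarm$fitness))) {
      stop("objective returned a non-finite value for particle ",
           which(!is.finite(swarm$fitness))[1], " at iteration ", k,
           call. = FALSE)
    }
    swarm <- update_bests(swarm)
    iterations_used <- k
    curve[k + 1] <- swarm$gbest_fitness
  }
  new_pso_result(swarm, curve[seq_len(iterations_used + 1)],
                 iterations_used, "pso")
}
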