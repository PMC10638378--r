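#' @title Traction switching-delay PSO building blocks
#' @description
#' The TSDPSO optimizer augments standard PSO with four mechanisms:
#'
#' * an *evolution factor* summarising the swarm's spatial spread, which
#'   classifies each iteration into one of four evolutionary states
#'   (1 convergence, 2 exploration, 3 development, 4 jump-out);
#' * a Markov chain over those states whose tridiagonal transition matrix
#'   adds stochastic persistence to the classification;
#' * state-dependent acceleration coefficients and *switching delays*: the
#'   velocity update may read the personal and global best positions from
#'   several iterations in the past;
#' * a *traction operation* that adds a pull toward the delayed global best
#'   for particles whose personal best has stalled.
#'
#' The low-level pieces are exported individually so each contract can be
#' tested; [optimize_tsdpso()] wires them into the full loop.
#' @name tsdpso-components
NULL

#' Mean distance from each particle to the rest of the swarm
#'
#' For particle i, `d_i = (1/s) * sum_j ||x_i - x_j||`, the average Euclidean
#' distance over all s swarm members (the zero self-term included).
#'
#' @param positions A particles-by-coordinates numeric matrix.
#' @param i Optional particle index; if omitted all `d_i` are returned.
#' @return A numeric vector (or scalar when `i` is given).
#' @export
mean_particle_distance <- function(positions, i = NULL) {
  positions <- as.matrix(positions)
  s <- nrow(positions)
  dm <- as.matrix(stats::dist(positions))
  d <- rowSums(dm) / s
  if (is.null(i)) return(unname(d))
  if (i < 1 || i > s) stop("particle index out of range", call. = FALSE)
  unname(d[i])
}

#' Evolution factor
#'
#' `E_f = (d_g - d_min) / (d_max - d_min)` where `d_g` is the mean distance
#' of the globally best particle and `d_min`, `d_max` are the extremes of the
#' per-particle mean distances. A fully collapsed swarm (`d_max == d_min`)
#' returns 0: no spread means the convergence state.
#'
#' @param d_g,d_min,d_max Mean-distance statistics.
#' @return A value in `[0, 1]`.
#' @export
evolution_factor <- function(d_g, d_min, d_max) {
  if (d_g < d_min || d_g > d_max) {
    stop("d_g must lie in [d_min, d_max]", call. = FALSE)
  }
  if (d_max == d_min) return(0)
  (d_g - d_min) / (d_max - d_min)
}

#' Classify the evolutionary state from the evolution factor
#'
#' Quartile thresholds, upper edges inclusive: state 1 for
#' `E_f <= 0.25`, 2 for `(0.25, 0.5]`, 3 for `(0.5, 0.75]`, 4 above.
#'
#' @param E_f Evolution factor in `[0, 1]`.
#' @return Integer state in `1:4`.
#' @export
classify_state <- function(E_f) {
  if (E_f < 0 || E_f > 1) stop("E_f must lie in [0, 1]", call. = FALSE)
  if (E_f <= 0.25) 1L else if (E_f <= 0.5) 2L else if (E_f <= 0.75) 3L else 4L
}

#' State transition matrix with persistence parameter x
#'
#' The 4x4 tridiagonal stochastic matrix: each state keeps probability `x`
#' and spreads `1 - x` over its adjacent states (split evenly for the two
#' interior states, wholly to the single neighbour for states 1 and 4).
#'
#' @param x Persistence probability in `[0, 1]`.
#' @return A 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(x = 0.6) {
  if (x < 0 || x > 1) stop("x must lie in [0, 1]", call. = FALSE)
  h <- (1 - x) / 2
  matrix(c(x,      1 - x,  0,      0,
           h,      x,      h,      0,
           0,      h,      x,      h,
           0,      0,      1 - x,  x),
         nrow = 4, byrow = TRUE)
}

#' Sample the next evolutionary state
#'
#' In `"markov"` mode (the default) the evolution-factor classification
#' *proposes* a state and the next state is sampled from that row of the
#' transition matrix, adding stochastic persistence to adjacent states. In
#' `"deterministic"` mode the proposal is returned unchanged (pure
#' evolution-factor classification; no RNG consumed).
#'
#' @param proposed Proposed state in `1:4` (from [classify_state()]).
#' @param matrix A 4x4 row-stochastic matrix from [transition_matrix()].
#' @param mode `"markov"` or `"deterministic"`.
#' @return Integer state in `1:4`.
#' @export
next_state <- function(proposed, matrix = transition_matrix(),
                       mode = c("markov", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(proposed %in% 1:4)
  if (any(abs(rowSums(matrix) - 1) > 1e-9) || any(matrix < 0)) {
    stop("transition matrix rows must be probabilities summing to 1",
         call. = FALSE)
  }
  if (mode == "deterministic") return(as.integer(proposed))
  sample.int(4L, 1L, prob = matrix[proposed, ])
}

#' Inertia weight schedule
#'
#' `w(E_f) = 0.5 * E_f + 0.4`, ranging over `[0.4, 0.9]`: a spread-out swarm
#' (large `E_f`) keeps a large inertia for global search, a collapsed swarm
#' a small one for local refinement.
#'
#' @param E_f Evolution factor in `[0, 1]`.
#' @return The inertia weight.
#' @export
inertia_weight <- function(E_f) {
  if (E_f < 0 || E_f > 1) stop("E_f must lie in [0, 1]", call. = FALSE)
  0.5 * E_f + 0.4
}

#' State-dependent acceleration coefficients
#'
#' The fixed mapping: convergence (2, 2), exploration (2.1, 1.9),
#' development (2.2, 1.8), jump-out (1.8, 2.2).
#'
#' @param state Integer state in `1:4`.
#' @return A list with fields `state`, `c1`, `c2`.
#' @export
state_parameters <- function(state) {
  stopifnot(state %in% 1:4)
  c1 <- c(2, 2.1, 2.2, 1.8)[state]
  c2 <- c(2, 1.9, 1.8, 2.2)[state]
  list(state = as.integer(state), c1 = c1, c2 = c2)
}

#' Delay-selection policy
#'
#' @param tau_max Largest admissible delay (iterations).
#' @param delayed_terms Which best position the exploration state delays;
#'   the qualitative guidance is ambiguous, the default delays gbest only.
#' @return A list of class `"delay_policy"`.
#' @export
delay_policy <- function(tau_max = 10, delayed_terms = c("gbest", "pbest")) {
  delayed_terms <- match.arg(delayed_terms)
  stopifnot(tau_max >= 0)
  structure(list(tau_max = as.integer(tau_max), delayed_terms = delayed_terms),
            class = "delay_policy")
}

#' Select velocity-update delays for the current state
#'
#' Per-state rule, with `m = min(k, tau_max)`:
#' convergence uses no delay `(0, 0)`; exploration delays the global-best
#' term, `tau2` uniform on `1..m`; development delays the personal-best term,
#' `tau1` uniform on `1..m`; jump-out delays both independently. `m = 0`
#' (no history yet, or `tau_max = 0`) forces a zero delay and consumes no
#' random numbers.
#'
#' @param state Integer state in `1:4`.
#' @param k Completed-iteration count (history depth available).
#' @param policy A [delay_policy()].
#' @return Integer vector `c(tau1, tau2)`.
#' @export
select_delays <- function(state, k, policy = delay_policy()) {
  stopifnot(state %in% 1:4, k >= 0)
  m <- min(k, policy$tau_max)
  draw <- function() if (m >= 1) sample.int(m, 1L) else 0L
  if (policy$delayed_terms == "pbest" && state == 2L) state <- 3L
  switch(state,
         c(0L, 0L),
         c(0L, draw()),
         c(draw(), 0L),
         c(draw(), draw()))
}

#' Traction term for a stalled particle
#'
#' `PO = ((f_i - f_min) / (f_avg - f_min)) * rand * (gbest_delayed -
#' pbest_delayed)`: particles with poor fitness relative to the swarm are
#' pulled hardest toward the (delayed) global best. A degenerate swarm with
#' `f_avg == f_min` yields a zero traction factor — a converged swarm needs
#' no traction.
#'
#' @param f_i Particle fitness.
#' @param f_min,f_avg Swarm minimum and mean fitness (`f_min <= f_avg`).
#' @param gbest_delayed,pbest_delayed Delayed best positions (equal length).
#' @param rand_draw Uniform draw in `[0, 1]`.
#' @return The traction velocity contribution.
#' @export
traction_term <- function(f_i, f_min, f_avg, gbest_delayed, pbest_delayed,
                          rand_draw) {
  if (length(gbest_delayed) != length(pbest_delayed)) {
    stop("delayed position vectors must have the same length", call. = FALSE)
  }
  factor <- if (f_avg == f_min) 0 else (f_i - f_min) / (f_avg - f_min)
  factor * rand_draw * (gbest_delayed - pbest_delayed)
}

#' Traction configuration
#'
#' @param stall_threshold Consecutive iterations without a personal-best
#'   improvement after which a particle is considered trapped (default 10,
#'   "the last 10 movements").
#' @param enabled Disable to run switching-delay PSO without traction.
#' @return A list of class `"traction_config"`.
#' @export
traction_config <- function(stall_threshold = 10, enabled = TRUE) {
  stopifnot(stall_threshold >= 1)
  structure(list(stall_threshold = as.integer(stall_threshold),
                 enabled = isTRUE(enabled)),
            class = "traction_config")
}

#' Switching-delay velocity update
#'
#' The TSDPSO velocity rule: the canonical three-term update evaluated
#' against *delayed* personal/global best positions, plus an optional
#' traction term, clamped to `[-v_max, v_max]`. With zero delays and no
#' traction it reduces exactly to [pso_velocity_update()].
#'
#' @inheritParams pso_velocity_update
#' @param pbest_delayed,gbest_delayed Best positions read `tau1`/`tau2`
#'   iterations in the past (clamped at iteration 0).
#' @param traction Optional traction vector from [traction_term()].
#' @return The new velocity vector.
#' @export
tsdpso_velocity_update <- function(velocity, position, pbest_delayed,
                                   gbest_delayed, inertia, c1, c2, r1, r2,
                                   v_max = Inf, traction = NULL) {
  v <- inertia * velocity + c1 * r1 * (pbest_delayed - position) +
    c2 * r2 * (gbest_delayed - position)
  if (!is.null(traction)) {
    if (length(traction) != length(v)) {
      stop("traction term has wrong length", call. = FALSE)
    }
    v <- v + traction
  }
  pmin(pmax(v, -v_max), v_max)
}

#' Traction switching-delay particle swarm optimization
#'
#' The full TSDPSO loop. Each iteration: compute per-particle mean distances
#' and the evolution factor from the current positions; set the inertia
#' weight from the evolution factor; classify the state and (in Markov mode)
#' sample the next state from the transition matrix; look up the
#' state-dependent acceleration coefficients and delays; update every
#' particle against the delayed personal/global bests, adding the traction
#' term for particles stalled at least `stall_threshold` iterations; then
#' evaluate, update the bests and record the state trace.
#'
#' With `delay_policy(tau_max = 0)`, `traction_config(enabled = FALSE)`,
#' `state_mode = "deterministic"` and `adaptive_inertia = FALSE` the loop
#' consumes the same random-number stream as [optimize_pso()] and reproduces
#' it step for step under a shared seed.
#'
#' @inheritParams optimize_pso
#' @param delay_policy A [delay_policy()].
#' @param traction A [traction_config()].
#' @param transition_x Persistence parameter of the transition matrix.
#' @param state_mode `"markov"` (sampled persistence, default) or
#'   `"deterministic"` (pure evolution-factor classification).
#' @param adaptive_inertia Use the `w(E_f)` schedule (default); otherwise the
#'   constant `config$inertia`.
#' @return A `"pso_result"` whose `state_trace` holds the state used at each
#'   iteration.
#' @examples
#' obj <- benchmark_objective("sphere", dimension = 5)
#' res <- optimize_tsdpso(obj, swarm_config(max_iterations = 100), seed = 1)
#' glance(res)
#' @export
optimize_tsdpso <- function(objective, config = swarm_config(),
                            delay_policy = tsdpso::delay_policy(),
                            traction = traction_config(),
                            transition_x = 0.6,
                            state_mode = c("markov", "deterministic"),
                            adaptive_inertia = TRUE,
                            seed = 1L) {
  state_mode <- match.arg(state_mode)
  objective <- validate_objective(objective)
  P <- transition_matrix(transition_x)
  swarm <- initialize_swarm(objective, config, seed)
  d <- objective$dimension
  s <- config$swarm_size
  depth <- delay_policy$tau_max + 1L
  # ring buffers of pbest/gbest positions for delayed lookups
  pbest_hist <- vector("list", depth)
  gbest_hist <- vector("list", depth)
  slot <- function(iter) (iter %% depth) + 1L
  pbest_hist[[slot(0)]] <- swarm$pbest_position
  gbest_hist[[slot(0)]] <- swarm$gbest_position
  curve <- numeric(config$max_iterations + 1)
  curve[1] <- swarm$gbest_fitness
  state_trace <- integer(config$max_iterations)
  iterations_used <- 0L

  for (k in seq_len(config$max_iterations)) {
    if (swarm$gbest_fitness <= config$convergence_tolerance) break
    completed <- k - 1L

    if (adaptive_inertia || state_mode != "deterministic" ||
        delay_policy$tau_max > 0 || traction$enabled) {
      dists <- mean_particle_distance(swarm$position)
      g_idx <- which.min(swarm$pbest_fitness)
      E_f <- evolution_factor(dists[g_idx], min(dists), max(dists))
      proposed <- classify_state(E_f)
      state <- if (state_mode == "markov") next_state(proposed, P) else proposed
    } else {
      E_f <- 1
      state <- 1L
    }
    w <- if (adaptive_inertia) inertia_weight(E_f) else config$inertia
    par <- if (state_mode == "deterministic" && delay_policy$tau_max == 0 &&
               !traction$enabled && !adaptive_inertia) {
      # degenerate configuration: keep the configured coefficients so the
      # run is step-identical to standard PSO
      list(c1 = config$c1, c2 = config$c2)
    } else {
      state_parameters(state)
    }
    taus <- select_delays(state, completed, delay_policy)
    lag1 <- max(completed - taus[1], 0L)
    lag2 <- max(completed - taus[2], 0L)
    pbest_lag <- pbest_hist[[slot(lag1)]]
    gbest_lag <- gbest_hist[[slot(lag2)]]
    f_min <- min(swarm$fitness)
    f_avg <- mean(swarm$fitness)

    for (i in seq_len(s)) {
      r1 <- draw_r(config, d)
      r2 <- draw_r(config, d)
      po <- NULL
      if (traction$enabled && swarm$stall_count[i] >= traction$stall_threshold) {
        po <- traction_term(swarm$fitness[i], f_min, f_avg,
                            gbest_hist[[slot(lag1)]], pbest_lag[i, ],
                            stats::runif(1))
      }
      v <- tsdpso_velocity_update(swarm$velocity[i, ], swarm$position[i, ],
                                  pbest_lag[i, ], gbest_lag,
                                  w, par$c1, par$c2, r1, r2,
                                  config$v_max, traction = po)
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
    pbest_hist[[slot(k)]] <- swarm$pbest_position
    gbest_hist[[slot(k)]] <- swarm$gbest_position
    state_trace[k] <- state
    iterations_used <- k
    curve[k + 1] <- swarm$gbest_fitness
  }
  new_pso_result(swarm, curve[seq_len(iterations_used + 1)],
                 iterations_used, "tsdpso",
                 state_trace[seq_len(iterations_used)])
}
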