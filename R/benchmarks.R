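#' Benchmark objective functions for optimizer validation
#'
#' A registry of six classical continuous minimization test functions
#' (Griewank, Rastrigin, Alpine, Ackley, Rosenbrock, Sphere), each with its
#' conventional symmetric search box and known global optimum. All six attain
#' a minimum of 0 (Rastrigin/Griewank/Ackley/Alpine/Sphere at the origin,
#' Rosenbrock at the all-ones point) in their standard forms.
#'
#' Two functions additionally carry an `"as_printed"` variant reflecting a
#' corrupted typeset form occasionally found in the applied literature:
#' an Ackley whose second exponential contains `cos(pi * i)` (constant in x)
#' and a Rosenbrock missing the square on `x_i` in its first term. The
#' standard forms are the default everywhere; the variants exist only for
#' fidelity experiments and do not attain 0 at the registered optimum.
#'
#' @param dimension Number of coordinates `n` for the registered descriptors.
#' @return A named list of benchmark descriptors. Each descriptor is a list
#'   with fields `name`, `dimension`, `lower`, `upper`, `evaluate`
#'   (a function of a numeric vector), `known_optimum_value` and
#'   `known_optimum_point`.
#' @examples
#' reg <- benchmark_registry(dimension = 4)
#' reg$sphere$evaluate(c(0, 0, 0, 0))
#' @export
benchmark_registry <- function(dimension = 10) {
  stopifnot(is.numeric(dimension), length(dimension) == 1, dimension >= 1)
  n <- as.integer(dimension)
  make <- function(name, half_width, fn, opt_point, opt_value = 0) {
    list(
      name = name,
      dimension = n,
      lower = rep(-half_width, n),
      upper = rep(half_width, n),
      evaluate = fn,
      known_optimum_value = opt_value,
      known_optimum_point = opt_point
    )
  }
  list(
    griewank = make("griewank", 600,
      function(x) 1 + sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))),
      rep(0, n)),
    rastrigin = make("rastrigin", 5.12,
      function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      rep(0, n)),
    alpine = make("alpine", 10,
      function(x) sum(abs(x * sin(x) + 0.1 * x)),
      rep(0, n)),
    ackley = make("ackley", 32,
      function(x) {
        n <- length(x)
        -20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))) +
          20 + exp(1)
      },
      rep(0, n)),
    rosenbrock = make("rosenbrock", 30,
      function(x) {
        i <- seq_len(length(x) - 1)
        sum(100 * (x[i + 1] - x[i]^2)^2 + (x[i] - 1)^2)
      },
      rep(1, n)),
    sphere = make("sphere", 30, function(x) sum(x^2), rep(0, n))
  )
}

# as-printed variants; kept out of the registry on purpose
.benchmark_variants <- list(
  ackley = function(x) {
    n <- length(x)
    -20 * exp(-0.2 * sqrt(1 / n) * sum(x^2)) -
      exp(mean(cos(pi * seq_len(n)))) + 20 + exp(1)
  },
  rosenbrock = function(x) {
    i <- seq_len(length(x) - 1)
    sum(100 * (x[i + 1] - x[i])^2 + (x[i] - 1)^2)
  }
)

#' Evaluate a benchmark function by name
#'
#' Lookup is case-insensitive and accepts `"rastigin"` as an alias for
#' `"rastrigin"` (a spelling that circulates in the applied literature).
#'
#' @param name Benchmark name, e.g. `"sphere"`.
#' @param x Numeric vector at which to evaluate.
#' @param variant `"standard"` (default) or, for `ackley` and `rosenbrock`
#'   only, `"as_printed"` (see [benchmark_registry()]).
#' @return The scalar function value.
#' @examples
#' evaluate_benchmark("sphere", c(1, 2, 3))
#' evaluate_benchmark("rastigin", rep(0, 4))
#' @export
evaluate_benchmark <- function(name, x, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (!is.numeric(x) || length(x) == 0) {
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  key <- tolower(name)
  if (key == "rastigin") key <- "rastrigin"
  reg <- benchmark_registry(dimension = length(x))
  if (!key %in% names(reg)) {
    stop("unknown benchmark function: ", name, call. = FALSE)
  }
  if (variant == "as_printed") {
    fn <- .benchmark_variants[[key]]
    if (is.null(fn)) {
      stop("no 'as_printed' variant for benchmark: ", key, call. = FALSE)
    }
    return(fn(x))
  }
  reg[[key]]$evaluate(x)
}

#' Build an objective specification from a registered benchmark
#'
#' Convenience bridge between the benchmark registry and the optimizers:
#' returns the `dimension`/`lower`/`upper`/`evaluate` contract that
#' [optimize_pso()] and [optimize_tsdpso()] consume.
#'
#' @inheritParams evaluate_benchmark
#' @param dimension Problem dimension.
#' @return A list with fields `dimension`, `lower`, `upper`, `evaluate`.
#' @export
benchmark_objective <- function(name, dimension = 10) {
  key <- tolower(name)
  if (key == "rastigin") key <- "rastrigin"
  reg <- benchmark_registry(dimension = dimension)
  if (!key %in% names(reg)) {
    stop("unknown benchmark function: ", name, call. = FALSE)
  }
  b <- reg[[key]]
  list(dimension = b$dimension, lower = b$lower, upper = b$upper,
       evaluate = b$evaluate)
}
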