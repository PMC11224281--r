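#' Define a box-constrained search space
#'
#' @param lower,upper Per-coordinate bounds; scalars are recycled to
#'   `dimension`. Every lower bound must be strictly below its upper bound.
#' @param dimension Number of problem parameters (>= 1). May be omitted when
#'   `lower`/`upper` are full-length vectors.
#' @return An object of class `search_space` with elements `lower`, `upper`
#'   and `dimension`.
#' @examples
#' search_space(-100, 100, 10)
#' @export
search_space <- function(lower, upper, dimension = NULL) {
  if (is.null(dimension)) dimension <- max(length(lower), length(upper))
  stopifnot(is.numeric(dimension), length(dimension) == 1, dimension >= 1)
  dimension <- as.integer(dimension)
  lower <- rep_len(as.numeric(lower), dimension)
  upper <- rep_len(as.numeric(upper), dimension)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound")
  }
  structure(
    list(lower = lower, upper = upper, dimension = dimension),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf(
    "<search_space> dimension %d, bounds [%s, %s]\n", x$dimension,
    format(x$lower[1]), format(x$upper[1])
  ))
  invisible(x)
}

#' Osprey optimizer settings
#'
#' Settings for [osprey_optimize()]. The `"ooa"` variant is the plain osprey
#' optimization algorithm: a two-phase, greedy, population-based minimizer.
#' The `"mop"` variant replaces the uniform step factors of the global
#' (exploration) phase with iterates of a sinusoidal chaos map and applies a
#' multiplicative Gaussian mutation to every candidate of both phases before
#' clipping and greedy selection.
#'
#' @param variant `"mop"` (default) or `"ooa"`.
#' @param pop_size Population size N (>= 2). Default 30.
#' @param iterations Total iterations T (>= 1). Default 200.
#' @param chaos_a Sinusoidal map gain `a` in (0, 4]. Default 2.3, the
#'   classical choice for which iterates remain inside (0, 1).
#' @param chaos_p0 Chaos seed in (0, 1), away from the fixed points. Default
#'   0.7. Each (member, coordinate) stream is seeded from a jittered copy.
#' @param chaos_burn_in Iterates discarded before use. Default 100.
#' @param mutation Apply the Gaussian mutation in the `"mop"` variant?
#'   Default `TRUE`. Ignored for `"ooa"`.
#' @return A list of class `osprey_options`.
#' @export
osprey_options <- function(variant = c("mop", "ooa"), pop_size = 30,
                           iterations = 200, chaos_a = 2.3, chaos_p0 = 0.7,
                           chaos_burn_in = 100, mutation = TRUE) {
  variant <- match.arg(variant)
  stopifnot(
    is.numeric(pop_size), length(pop_size) == 1, pop_size >= 2,
    is.numeric(iterations), length(iterations) == 1, iterations >= 1,
    is.numeric(chaos_a), chaos_a > 0, chaos_a <= 4,
    is.numeric(chaos_p0), chaos_p0 > 0, chaos_p0 < 1,
    is.numeric(chaos_burn_in), chaos_burn_in >= 0,
    is.logical(mutation), length(mutation) == 1
  )
  structure(
    list(
      variant = variant, pop_size = as.integer(pop_size),
      iterations = as.integer(iterations), chaos_a = chaos_a,
      chaos_p0 = chaos_p0, chaos_burn_in = as.integer(chaos_burn_in),
      mutation = mutation
    ),
    class = "osprey_options"
  )
}

#' Clip a position onto the search-space box
#'
#' Coordinate-wise projection onto `[lower, upper]`.
#'
#' @param x Numeric vector of length `space$dimension`.
#' @param space A [search_space()].
#' @return The projected vector.
#' @export
clip_to_bounds <- function(x, space) {
  pmin(pmax(x, space$lower), space$upper)
}

#' Fish set of a population member
#'
#' Indices of all members with strictly smaller fitness than member `i`,
#' united with the index of the best member. Never empty: for the best member
#' itself (and under all-equal fitness) it is the best index alone. Ties for
#' the best are broken by lowest index.
#'
#' @param fitness Numeric fitness vector of the population.
#' @param i Member index.
#' @return Sorted integer vector of candidate prey indices.
#' @export
fish_set <- function(fitness, i) {
  stopifnot(i >= 1, i <= length(fitness))
  best <- which.min(fitness)
  sort(union(which(fitness < fitness[i]), best))
}

#' Iterates of the sinusoidal chaos map
#'
#' Generates `p <- a * p^2 * sin(pi * p)` iterates, discarding the first
#' `burn_in`. For `a = 2.3` the orbit remains inside (0, 1).
#'
#' @param p0 Seed in (0, 1); the endpoints are fixed points and are rejected.
#' @param a Map gain in (0, 4]. Default 2.3.
#' @param length Number of iterates returned.
#' @param burn_in Leading iterates discarded. Default 0.
#' @return Numeric vector of `length` iterates.
#' @examples
#' sinusoidal_chaos_stream(0.5, 2.3, 3) # 0.575, ...
#' @export
sinusoidal_chaos_stream <- function(p0, a = 2.3, length, burn_in = 0) {
  stopifnot(is.numeric(p0), length(p0) == 1, is.numeric(a), a > 0, a <= 4,
            length >= 1, burn_in >= 0)
  if (p0 <= 0 || p0 >= 1) {
    stop("degenerate chaos seed: p0 must lie strictly inside (0, 1)")
  }
  p <- p0
  for (k in seq_len(burn_in)) p <- a * p^2 * sin(pi * p)
  out <- numeric(length)
  for (k in seq_len(length)) {
    p <- a * p^2 * sin(pi * p)
    out[k] <- p
  }
  out
}

# One synchronous step of the chaos map for a matrix of stream states.
.chaos_step <- function(P, a) a * P^2 * sin(pi * P)

#' Multiplicative Gaussian mutation
#'
#' Perturbs a position coordinate-wise as `x * (1 + k * g)` with independent
#' standard-normal draws `g` (one per coordinate) and a scale `k` in [0, 1].
#' The zero vector is a fixed point of the mutation for any `k`.
#'
#' @param x Numeric position.
#' @param k Mutation scale in [0, 1].
#' @param g Standard-normal draws; defaults to fresh draws from the current
#'   random stream.
#' @return The mutated position (not clipped).
#' @export
gaussian_mutation <- function(x, k, g = stats::rnorm(length(x))) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k <= 1,
            length(g) == length(x))
  x * (1 + k * g)
}

# Phase-1 (global) candidate: move toward a randomly chosen fish.
.phase1_candidate <- function(y, sa, r, I) y + r * (sa - I * y)

# Phase-2 (local) candidate: additive step with a 1/t envelope.
.phase2_candidate <- function(y, r, t, space) {
  y + (space$lower + r * (space$upper - space$lower)) / t
}

#' Initialize an osprey population
#'
#' Positions drawn uniformly inside the box, one row per member, and the
#' objective evaluated for every row.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param space A [search_space()].
#' @param n Population size (>= 2).
#' @return List with elements `Y` (n x m position matrix) and `fitness`.
#' @export
initialize_population <- function(objective, space, n) {
  stopifnot(n >= 2)
  m <- space$dimension
  r <- matrix(stats::runif(n * m), n, m)
  Y <- matrix(space$lower, n, m, byrow = TRUE) +
    r * matrix(space$upper - space$lower, n, m, byrow = TRUE)
  fitness <- apply(Y, 1, function(y) .checked_objective(objective, y))
  list(Y = Y, fitness = fitness)
}

.checked_objective <- function(objective, y) {
  v <- objective(y)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
    stop("objective returned a non-finite value at position (",
         paste(signif(y, 4), collapse = ", "), ")")
  }
  as.numeric(v)
}

#' Minimize an objective with the (modified) osprey optimizer
#'
#' Runs the two-phase osprey optimization loop: in every iteration each
#' member first moves toward a randomly chosen strictly-better member (or the
#' global best), then takes a local step whose magnitude shrinks as 1/t. Each
#' candidate is clipped to the box and accepted only on strict improvement.
#' In the `"mop"` variant the per-coordinate step factors of the phase-1
#' (global) move are iterates of per-(member, coordinate) sinusoidal chaos
#' streams — the chaotic attractor supplies aggressive, structured
#' exploration factors — while the local phase keeps uniform draws, and each
#' candidate of either phase is additionally perturbed by a multiplicative
#' Gaussian mutation with scale `k = u * (1 - t/T) / sqrt(m)`,
#' `u ~ U(0, 1)` per member and phase.
#'
#' @param objective Function from a numeric position to a finite scalar to be
#'   minimized. A non-finite return value aborts with the offending position.
#' @param space A [search_space()].
#' @param options An [osprey_options()] list.
#' @param seed Optional integer seed; when given, results are reproducible
#'   bit-for-bit.
#' @return Object of class `osprey_result`: list with `best_position`,
#'   `best_value`, `history` (best-so-far per iteration, non-increasing),
#'   `evaluations`, `variant`, `options`, `seed`.
#' @examples
#' f <- get_benchmark("sphere", 2)
#' res <- osprey_optimize(
#'   function(x) benchmark_evaluate(f, x),
#'   search_space(f$lower, f$upper, f$dimension),
#'   osprey_options("mop", pop_size = 10, iterations = 25), seed = 1
#' )
#' res$best_value
#' @export
osprey_optimize <- function(objective, space, options = osprey_options(),
                            seed = NULL) {
  stopifnot(inherits(space, "search_space"), inherits(options, "osprey_options"))
  if (!is.null(seed)) set.seed(seed)
  n <- options$pop_size
  m <- space$dimension
  t_max <- options$iterations
  mop <- options$variant == "mop"

  pop <- initialize_population(objective, space, n)
  Y <- pop$Y
  fitness <- pop$fitness
  evals <- n

  if (mop) {
    # Per-(member, coordinate) chaos streams: states jittered around chaos_p0
    # (kept inside (0.05, 0.95)), then burned in synchronously.
    P <- matrix(options$chaos_p0, n, m) +
      matrix(stats::runif(n * m, -0.2, 0.2), n, m)
    P <- pmin(pmax(P, 0.05), 0.95)
    for (b in seq_len(options$chaos_burn_in)) P <- .chaos_step(P, options$chaos_a)
  }

  # Mutation scale: random, decreasing over the run, and normalized by
  # 1/sqrt(m) so the expected relative perturbation of a candidate does not
  # grow with the dimension (the evolution-strategy step-size convention);
  # without it the acceptance probability of mutated candidates collapses
  # for large parameter vectors.
  k_scale <- 1 / sqrt(m)

  history <- numeric(t_max)
  for (t in seq_len(t_max)) {
    if (mop) {
      P <- .chaos_step(P, options$chaos_a)
      R1 <- P
    } else {
      R1 <- matrix(stats::runif(n * m), n, m)
    }
    for (i in seq_len(n)) {
      # Phase 1: exploration toward a randomly chosen fish.
      fs <- fish_set(fitness, i)
      sa <- Y[if (length(fs) == 1) fs else sample(fs, 1), ]
      I <- sample(1:2, m, replace = TRUE)
      cand <- .phase1_candidate(Y[i, ], sa, R1[i, ], I)
      if (mop && options$mutation) {
        cand <- gaussian_mutation(cand, k_scale * stats::runif(1) * (1 - t / t_max))
      }
      cand <- clip_to_bounds(cand, space)
      v <- .checked_objective(objective, cand)
      evals <- evals + 1
      if (v < fitness[i]) {
        Y[i, ] <- cand
        fitness[i] <- v
      }
    }
    R2 <- matrix(stats::runif(n * m), n, m)
    for (i in seq_len(n)) {
      # Phase 2: local exploitation with 1/t envelope.
      cand <- .phase2_candidate(Y[i, ], R2[i, ], t, space)
      if (mop && options$mutation) {
        cand <- gaussian_mutation(cand, k_scale * stats::runif(1) * (1 - t / t_max))
      }
      cand <- clip_to_bounds(cand, space)
      v <- .checked_objective(objective, cand)
      evals <- evals + 1
      if (v < fitness[i]) {
        Y[i, ] <- cand
        fitness[i] <- v
      }
    }
    history[t] <- min(fitness)
  }

  best <- which.min(fitness)
  structure(
    list(
      best_position = Y[best, ],
      best_value = fitness[best],
      history = history,
      evaluations = evals,
      variant = options$variant,
      options = options,
      seed = seed
    ),
    class = "osprey_result"
  )
}

#' @export
print.osprey_result <- function(x, ...) {
  cat(sprintf(
    "<osprey_result> variant %s, %d iterations, %d evaluations\n  best value: %g\n",
    x$variant, length(x$history), x$evaluations, x$best_value
  ))
  invisible(x)
}

#' Tidy the convergence history of an optimizer run
#'
#' @param x An `osprey_result`.
#' @param ... Unused.
#' @return Tibble with columns `iteration` and `best_value` (best-so-far).
#' @importFrom generics tidy
#' @export
tidy.osprey_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history), best_value = x$history)
}

#' One-row summary of an optimizer run
#'
#' @param x An `osprey_result`.
#' @param ... Unused.
#' @return One-row tibble: `variant`, `pop_size`, `iterations`,
#'   `evaluations`, `best_value`.
#' @importFrom generics glance
#' @export
glance.osprey_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    pop_size = x$options$pop_size,
    iterations = x$options$iterations,
    evaluations = x$evaluations,
    best_value = x$best_value
  )
}

#' Convergence plot of an optimizer run
#'
#' Best-so-far objective value per iteration, on a log10 y axis when all
#' values are positive.
#'
#' @param object An `osprey_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.osprey_result <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$best_value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best objective value",
                  title = sprintf("Osprey optimizer (%s) convergence", object$variant))
  if (all(d$best_value > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
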