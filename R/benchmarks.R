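#' Classical benchmark test functions
#'
#' The ten box-constrained test functions used to validate the osprey
#' optimizer: five unimodal (Sphere, Schwefel 2.22, Schwefel 1.2,
#' Schwefel 2.21, Rosenbrock) and five multimodal (Ackley, Griewank,
#' Alpine 1, Alpine 2, Trid). Each function is a pure mapping from a real
#' vector to a scalar, with per-coordinate bounds.
#'
#' All functions except Trid attain their global minimum value 0 at a known
#' position (the origin for all but Rosenbrock, whose optimum is the all-ones
#' vector). Trid's minimum is not 0, so its `optimum_value` is `NA`.
#'
#' @param name Function name, e.g. `"sphere"`, `"ackley"`, or the short id
#'   `"F1"` .. `"F10"`. Case-insensitive; see [benchmark_names()].
#' @param dimension Problem dimension `n` (>= 2). Default 10.
#' @return An object of class `benchmark_fn`: a list with elements `name`,
#'   `id`, `fn`, `lower`, `upper`, `dimension`, `optimum_value`,
#'   `optimum_position` and `modality`.
#' @examples
#' f <- get_benchmark("sphere", 2)
#' benchmark_evaluate(f, c(3, 4)) # 25
#' @export
get_benchmark <- function(name, dimension = 10) {
  stopifnot(is.numeric(dimension), length(dimension) == 1, dimension >= 2)
  dimension <- as.integer(dimension)
  key <- .benchmark_key(name)
  entry <- .benchmark_registry[[key]]
  structure(
    list(
      name = key,
      id = entry$id,
      fn = entry$fn,
      lower = entry$lower,
      upper = entry$upper,
      dimension = dimension,
      optimum_value = entry$optimum_value,
      optimum_position = rep(entry$optimum_coord, dimension),
      modality = entry$modality
    ),
    class = "benchmark_fn"
  )
}

#' @export
print.benchmark_fn <- function(x, ...) {
  cat(sprintf(
    "<benchmark_fn> %s (%s, %s), dimension %d, bounds [%g, %g]\n",
    x$name, x$id, x$modality, x$dimension, x$lower, x$upper
  ))
  invisible(x)
}

#' Evaluate a benchmark function
#'
#' @param f A `benchmark_fn` from [get_benchmark()].
#' @param x Numeric vector of length `f$dimension`.
#' @return Scalar function value.
#' @export
benchmark_evaluate <- function(f, x) {
  stopifnot(inherits(f, "benchmark_fn"))
  if (!is.numeric(x) || length(x) != f$dimension) {
    stop("`x` must be a numeric vector of length ", f$dimension,
         " (got length ", length(x), ")")
  }
  f$fn(as.numeric(x))
}

#' Names of the available benchmark functions
#'
#' @return Character vector of the ten registered function names, in
#'   F1..F10 order.
#' @export
benchmark_names <- function() {
  as.character(.benchmark_order)
}

#' Summary table of the benchmark registry
#'
#' @return A tibble with one row per function: `id`, `name`, `lower`,
#'   `upper`, `modality`, `optimum_value`.
#' @export
benchmark_table <- function() {
  field <- function(what, proto) {
    unname(vapply(.benchmark_order,
                  function(n) .benchmark_registry[[n]][[what]], proto))
  }
  tibble::tibble(
    id = field("id", character(1)),
    name = benchmark_names(),
    lower = field("lower", numeric(1)),
    upper = field("upper", numeric(1)),
    modality = field("modality", character(1)),
    optimum_value = field("optimum_value", numeric(1))
  )
}

.benchmark_order <- c(
  "sphere", "schwefel222", "schwefel12", "schwefel221", "rosenbrock",
  "ackley", "griewank", "alpine1", "alpine2", "trid"
)

.benchmark_key <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  key <- tolower(gsub("[ ._-]", "", name))
  aliases <- c(
    f1 = "sphere", f2 = "schwefel222", f3 = "schwefel12", f4 = "schwefel221",
    f5 = "rosenbrock", f6 = "ackley", f7 = "griewank", f8 = "alpine1",
    f9 = "alpine2", f10 = "trid",
    sphere = "sphere", schwefel222 = "schwefel222", schwefel12 = "schwefel12",
    schwefel221 = "schwefel221", rosenbrock = "rosenbrock", ackley = "ackley",
    griewank = "griewank", alpine1 = "alpine1", alpine2 = "alpine2",
    trid = "trid"
  )
  if (!key %in% names(aliases)) {
    stop("no such benchmark: '", name, "'")
  }
  unname(aliases[key])
}

# Registry: bounds as printed; Ackley in its standard (mean-based) form so the
# minimum at the origin is exactly 0; Griewank with the +1 constant for the
# same reason; Alpine 2 with |x| under the root so it is defined on the whole
# symmetric domain and minimal (0) at the origin; Trid cross-term from i = 2.
.benchmark_registry <- list(
  sphere = list(
    id = "F1", lower = -100, upper = 100, modality = "unimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) sum(x^2)
  ),
  schwefel222 = list(
    id = "F2", lower = -10, upper = 10, modality = "unimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) sum(abs(x)) + prod(abs(x))
  ),
  schwefel12 = list(
    id = "F3", lower = -100, upper = 100, modality = "unimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) sum(cumsum(x)^2)
  ),
  schwefel221 = list(
    id = "F4", lower = -100, upper = 100, modality = "unimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) max(abs(x))
  ),
  rosenbrock = list(
    id = "F5", lower = -30, upper = 30, modality = "unimodal",
    optimum_value = 0, optimum_coord = 1,
    fn = function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
    }
  ),
  ackley = list(
    id = "F6", lower = -32, upper = 32, modality = "multimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) {
      -20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))) +
        20 + exp(1)
    }
  ),
  griewank = list(
    id = "F7", lower = -600, upper = 600, modality = "multimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) {
      sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
    }
  ),
  alpine1 = list(
    id = "F8", lower = -10, upper = 10, modality = "multimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) sum(abs(x * sin(x) + 0.1 * x))
  ),
  alpine2 = list(
    id = "F9", lower = -10, upper = 10, modality = "multimodal",
    optimum_value = 0, optimum_coord = 0,
    fn = function(x) prod(abs(sin(x) * sqrt(abs(x))))
  ),
  trid = list(
    id = "F10", lower = -100, upper = 100, modality = "multimodal",
    optimum_value = NA_real_, optimum_coord = NA_real_,
    fn = function(x) {
      n <- length(x)
      sum((x - 1)^2) + sum(x[-1] * x[-n])
    }
  )
)
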