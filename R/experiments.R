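#' Benchmark study of the osprey optimizer variants
#'
#' Runs `runs` independently seeded optimizations of each benchmark function
#' for each variant and summarizes the best-of-run values as AVG and STD
#' (population standard deviation, divisor R). Run seeds are derived
#' deterministically from `base_seed` and shared across variants, so the
#' variants are paired run-by-run.
#'
#' @param functions Benchmark names (see [benchmark_names()]). Default all
#'   ten.
#' @param variants Optimizer variants to run; default `"mop"`.
#' @param runs Repetitions per (function, variant). Default 20.
#' @param iterations Iterations per run. Default 200.
#' @param pop_size Population size. Default 30.
#' @param dimension Benchmark dimension. Default 10.
#' @param base_seed Integer seed for the whole study. Default 1.
#' @return Object of class `benchmark_report`: list with `runs` (tibble:
#'   `function_name`, `variant`, `run`, `seed`, `best_value`,
#'   `evaluations`), `summary` (tibble: `function_name`, `variant`, `avg`,
#'   `std`) and `params`.
#' @export
run_benchmark_study <- function(functions = benchmark_names(),
                                variants = "mop", runs = 20,
                                iterations = 200, pop_size = 30,
                                dimension = 10, base_seed = 1) {
  stopifnot(runs >= 1)
  # Run-level seeds shared by all variants (common random numbers pairing);
  # kept well below 2^31.
  run_seeds <- (as.integer(base_seed) %% 100000L) * 10000L +
    seq_len(runs * length(functions))
  seed_mat <- matrix(run_seeds, nrow = runs)
  grid <- expand.grid(run = seq_len(runs), function_name = functions,
                      variant = variants, stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(run, function_name, variant) {
    f <- get_benchmark(function_name, dimension)
    space <- search_space(f$lower, f$upper, dimension)
    opts <- osprey_options(variant, pop_size = pop_size,
                           iterations = iterations)
    seed <- seed_mat[run, match(function_name, functions)]
    res <- osprey_optimize(function(x) f$fn(x), space, opts, seed = seed)
    tibble::tibble(
      function_name = function_name, variant = variant, run = run,
      seed = seed, best_value = res$best_value,
      evaluations = res$evaluations
    )
  })
  runs_tbl <- dplyr::bind_rows(rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary_tbl <- runs_tbl |>
    dplyr::group_by(.data$function_name, .data$variant) |>
    dplyr::summarise(avg = mean(.data$best_value),
                     std = pop_sd(.data$best_value), .groups = "drop")
  structure(
    list(runs = runs_tbl, summary = summary_tbl,
         params = list(runs = runs, iterations = iterations,
                       pop_size = pop_size, dimension = dimension,
                       base_seed = base_seed)),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> %d runs x %d iterations, N = %d, dimension %d\n",
    x$params$runs, x$params$iterations, x$params$pop_size,
    x$params$dimension
  ))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
tidy.benchmark_report <- function(x, ...) x$summary

#' AVG-by-function plot of a benchmark report
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object (log10 y axis; a small floor keeps zero averages
#'   plottable).
#' @export
autoplot.benchmark_report <- function(object, ...) {
  d <- dplyr::mutate(object$summary,
                     avg_plot = pmax(.data$avg, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$function_name, y = .data$avg_plot,
                                  fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "AVG best value over runs",
                  title = "Benchmark study")
}

#' Write a benchmark report as CSV and JSON
#'
#' Per-run values go to `csv_path`; the AVG/STD summary (with the study
#' parameters and the note that STD is the population formula) to
#' `json_path`.
#'
#' @param report A `benchmark_report`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_benchmark_report <- function(report, csv_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$runs, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(params = report$params, std_formula = "population (divisor R)",
           summary = report$summary),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}

#' Stratified train/test split
#'
#' Splits each class separately, assigning `round(fraction * n_class)`
#' samples to the training set, so the split is stratified, disjoint and
#' exhaustive.
#'
#' @param data Labeled tibble with a `label` column.
#' @param fraction Training fraction in (0, 1). Default 0.8.
#' @param seed Optional integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, fraction = 0.8, seed = NULL) {
  stopifnot(is.data.frame(data), "label" %in% names(data),
            fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  lab <- as.factor(data$label)
  train_idx <- integer(0)
  for (cls in levels(lab)) {
    idx <- which(lab == cls)
    if (length(idx) < 2) {
      stop("class '", cls, "' has fewer than 2 samples; cannot split")
    }
    n_train <- round(fraction * length(idx))
    if (n_train == 0 || n_train == length(idx)) {
      stop("fraction ", fraction, " leaves class '", cls,
           "' with an empty train or test part")
    }
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE])
}

#' Stratified fold assignment
#'
#' Within each class, samples are shuffled (seeded) and dealt round-robin to
#' the `k` folds, so the folds partition the data and per-fold class
#' proportions stay within one sample of the global proportions.
#'
#' @param data Labeled tibble with a `label` column.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids (1..k), one per row of `data`.
#' @export
make_folds <- function(data, k, seed = NULL) {
  stopifnot(is.data.frame(data), "label" %in% names(data), k >= 2)
  if (!is.null(seed)) set.seed(seed)
  lab <- as.factor(data$label)
  fold <- integer(nrow(data))
  for (cls in levels(lab)) {
    idx <- which(lab == cls)
    if (length(idx) < k) {
      stop("class '", cls, "' has fewer samples (", length(idx),
           ") than folds (", k, ")")
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Trains on k-1 folds and evaluates every metric of [metric_report()] on
#' the held-out fold.
#'
#' @param data Labeled image tibble.
#' @param k Folds; the harness supports the usual 2, 3 and 5.
#' @param trainer Function `function(train_data) -> model`, where the model
#'   has a [predict()] method accepting `type = "class"` and `type =
#'   "prob"` (positive-class score). E.g. [train_area_classifier], or a
#'   wrapper around [train_capsnet()].
#' @param seed Optional integer seed (controls the fold assignment and is
#'   also passed through `set.seed` before each training call).
#' @param positive Positive class for the metrics; default the last level.
#' @return Object of class `cv_results`: list with `folds` (one metric row
#'   per fold) and `summary` (mean of each metric).
#' @export
cross_validate <- function(data, k, trainer, seed = NULL, positive = NULL) {
  stopifnot(k %in% c(2, 3, 5), is.function(trainer))
  fold <- make_folds(data, k, seed = seed)
  rows <- lapply(seq_len(k), function(fk) {
    train <- data[fold != fk, , drop = FALSE]
    test <- data[fold == fk, , drop = FALSE]
    model <- trainer(train)
    pred <- predict(model, test, type = "class")
    score <- tryCatch(predict(model, test, type = "prob"),
                      error = function(e) NULL)
    dplyr::mutate(
      metric_report(test$label, pred, scores = score, positive = positive),
      fold = fk, n_test = nrow(test), .before = 1
    )
  })
  folds_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- folds_tbl |>
    dplyr::summarise(dplyr::across(
      c("precision", "recall", "accuracy", "specificity", "f1", "f_beta",
        "kappa", "auc"), mean))
  structure(list(folds = folds_tbl, summary = summary_tbl, k = k),
            class = "cv_results")
}

#' @export
print.cv_results <- function(x, ...) {
  cat(sprintf("<cv_results> %d-fold cross-validation\n", x$k))
  print(x$folds, n = Inf)
  cat("means:\n")
  print(x$summary)
  invisible(x)
}

#' Budget-matched random-search baseline for the capsule network
#'
#' Draws parameter vectors uniformly inside the search box and keeps the one
#' with the lowest full-batch margin loss, spending the same number of
#' objective evaluations as an optimizer run with the given population size
#' and iteration count (`pop_size * (1 + 2 * iterations)`).
#'
#' @inheritParams train_capsnet
#' @param pop_size,iterations Budget reference; the total evaluation count
#'   matches an osprey run with these settings.
#' @return A `capsnet_model` whose `result` is an `osprey_result`-shaped
#'   record of the random search.
#' @export
random_search_capsnet <- function(data, arch = capsnet_architecture(),
                                  pop_size = 30, iterations = 100,
                                  bound = 1, m_plus = 0.9, m_minus = 0.1,
                                  lambda = 0.5, seed = NULL) {
  stopifnot(inherits(arch, "capsnet_arch"))
  if (!is.null(seed)) set.seed(seed)
  prep <- .prepare_training_data(data, arch)
  budget <- pop_size * (1 + 2 * iterations)
  best_v <- Inf
  best_p <- NULL
  history <- numeric(0)
  for (e in seq_len(budget)) {
    p <- stats::runif(arch$n_params, -abs(bound), abs(bound))
    v <- capsnet_fitness(p, prep$images, prep$labels, arch, m_plus, m_minus,
                         lambda)
    if (v < best_v) {
      best_v <- v
      best_p <- p
    }
    history[e] <- best_v
  }
  result <- structure(
    list(best_position = best_p, best_value = best_v, history = history,
         evaluations = budget, variant = "random_search",
         options = NULL, seed = seed),
    class = "osprey_result"
  )
  structure(
    list(params = best_p, arch = arch, classes = prep$classes,
         result = result, loss = best_v, m_plus = m_plus,
         m_minus = m_minus, lambda = lambda),
    class = "capsnet_model"
  )
}

.model_accuracy <- function(model, data) {
  pred <- predict(model, data, type = "class")
  100 * mean(as.character(pred) == as.character(data$label))
}

#' Ablation study of the trained capsule network
#'
#' Compares four configurations over a list of seeds, each seed giving a
#' fresh stratified train/test split of `data`:
#' * `capsnet` — budget-matched random-search baseline (no osprey
#'   optimizer),
#' * `capsnet_sp` — the same random-search model evaluated on test images
#'   corrupted by salt-and-pepper noise,
#' * `capsnet_ooa` — trained by the plain osprey optimizer,
#' * `capsnet_mop` — trained by the modified variant.
#'
#' @param data Labeled image tibble (both classes present).
#' @param seeds Integer seeds; one split + training round per seed.
#' @param noise_density Salt-and-pepper density for the `capsnet_sp` row.
#'   Default 0.05.
#' @param arch A [capsnet_architecture()].
#' @param pop_size,iterations Optimizer settings (and random-search budget
#'   reference).
#' @param split_fraction Training fraction per seed. Default 0.8.
#' @return Object of class `ablation_results`: list with `runs` (per seed
#'   and model: test accuracy in percent, training margin loss, wall time)
#'   and `summary` (per model: mean accuracy, mean loss, mean wall time).
#' @export
run_ablation <- function(data, seeds = 1:10, noise_density = 0.05,
                         arch = capsnet_architecture(), pop_size = 20,
                         iterations = 60, split_fraction = 0.8) {
  stopifnot(is.data.frame(data), nlevels(as.factor(data$label)) == 2)
  rows <- purrr::map(seeds, function(sd) {
    split <- split_train_test(data, split_fraction, seed = sd)
    train <- split$train
    test <- split$test
    time_of <- function(expr) {
      t0 <- proc.time()[["elapsed"]]
      value <- force(expr)
      list(value = value, secs = proc.time()[["elapsed"]] - t0)
    }
    rs <- time_of(random_search_capsnet(train, arch, pop_size, iterations,
                                        seed = sd))
    ooa <- time_of(train_capsnet(
      train, arch, osprey_options("ooa", pop_size, iterations), seed = sd))
    mop <- time_of(train_capsnet(
      train, arch, osprey_options("mop", pop_size, iterations), seed = sd))
    # Salt-and-pepper is applied at the network input resolution, so the
    # stated density is the density the model experiences; the accuracy is
    # averaged over independent noise realizations.
    set.seed(sd)
    test_X <- as_capsnet_input(test, arch)
    truth <- as.character(test$label)
    sp_acc <- mean(vapply(1:5, function(rep) {
      Xn <- t(apply(test_X, 1, function(row) {
        as.vector(salt_pepper(matrix(row, arch$input_height,
                                     arch$input_width), noise_density))
      }))
      pred <- predict(rs$value, Xn, type = "class")
      100 * mean(as.character(pred) == truth)
    }, numeric(1)))
    tibble::tibble(
      seed = sd,
      model = c("capsnet_sp", "capsnet", "capsnet_ooa", "capsnet_mop"),
      accuracy = c(sp_acc,
                   .model_accuracy(rs$value, test),
                   .model_accuracy(ooa$value, test),
                   .model_accuracy(mop$value, test)),
      margin_loss = c(rs$value$loss, rs$value$loss, ooa$value$loss,
                      mop$value$loss),
      wall_time = c(rs$secs, rs$secs, ooa$secs, mop$secs)
    )
  })
  runs <- dplyr::bind_rows(rows)
  summary_tbl <- runs |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     mean_margin_loss = mean(.data$margin_loss),
                     mean_wall_time = mean(.data$wall_time),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$model,
                         c("capsnet_sp", "capsnet", "capsnet_ooa",
                           "capsnet_mop")))
  structure(list(runs = runs, summary = summary_tbl,
                 noise_density = noise_density),
            class = "ablation_results")
}

#' @export
print.ablation_results <- function(x, ...) {
  cat(sprintf("<ablation_results> salt-and-pepper density %.3g\n",
              x$noise_density))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ablation_results <- function(x, ...) x$summary

#' Mean-accuracy plot of an ablation study
#'
#' @param object An `ablation_results`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ablation_results <- function(object, ...) {
  d <- dplyr::mutate(object$summary,
                     model = factor(.data$model, levels = .data$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$mean_accuracy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean test accuracy (%)",
                  title = "Ablation study")
}
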