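#' Stratified train/test split
#'
#' Randomly assigns a `train_fraction` share of *each class* to the training
#' subset (rounded to the nearest integer per class) and the remainder to
#' the testing subset. Stratification guarantees every class appears in both
#' subsets, so the per-class average firing rates and the decision rule are
#' always defined; a plain random split can empty a class in small datasets.
#'
#' @param data labeled data frame of patterns.
#' @param train_fraction share of each class assigned to training, in (0, 1).
#'   Default 0.80.
#' @param label name of the label column.
#' @param seed optional integer seed; the same seed reproduces the split
#'   exactly.
#' @return A list with tibbles `train` and `test`; the two are disjoint and
#'   their union is `data`.
#' @export
#' @examples
#' d <- make_gaussian_clusters(n = 150, seed = 1)
#' sp <- stratified_split(d, seed = 1)
#' nrow(sp$train); nrow(sp$test)
stratified_split <- function(data, train_fraction = 0.8, label = "class",
                             seed = NULL) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  ds <- prepare_dataset(data, label)
  data <- tibble::as_tibble(data)
  gen <- function() {
    idx_train <- integer(0)
    for (k in seq_len(ds$K)) {
      members <- which(ds$y == k)
      n_k <- length(members)
      n_train <- floor(train_fraction * n_k + 0.5)
      if (n_train < 1L || n_train > n_k - 1L) {
        stop("class `", ds$labels[k], "` is too small (", n_k,
             " patterns) to appear in both subsets at train_fraction = ",
             train_fraction, call. = FALSE)
      }
      idx_train <- c(idx_train, sample(members, n_train))
    }
    idx_train <- sort(idx_train)
    list(train = data[idx_train, , drop = FALSE],
         test = data[-idx_train, , drop = FALSE])
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' t-distribution confidence interval for a mean
#'
#' `mean(x) +- t_{1-alpha/2, m-1} * s / sqrt(m)` with `s` the sample
#' standard deviation and `m` the number of values.
#'
#' @param values numeric vector with at least 2 values.
#' @param level confidence level. Default 0.95.
#' @return A one-row tibble with columns `mean`, `sd`, `lower`, `upper`,
#'   `level`, `n`.
#' @export
#' @examples
#' t_confidence_interval(c(0.95, 0.97, 0.96, 0.99))
t_confidence_interval <- function(values, level = 0.95) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 2L) {
    stop("need at least 2 values for a confidence interval", call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  mu <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - level) / 2, df = m - 1) * s / sqrt(m)
  tibble::tibble(mean = mu, sd = s, lower = mu - half, upper = mu + half,
                 level = level, n = m)
}

#' Repeated train/test experiment protocol
#'
#' The full evaluation protocol: for each of `repetitions` runs, draw a
#' stratified `train_fraction` split, train the spiking classifier on the
#' training subset, score it on both subsets, and record the optimizer's
#' best-so-far error curve. Per-run seeds are derived deterministically as
#' `seed + run`, so the whole report is exactly reproducible from the base
#' seed. The summary reports, for training and testing classification
#' rates, the mean, the sample standard deviation and the t-distribution
#' confidence interval around the mean.
#'
#' @param data labeled data frame of patterns (or a `planted_dataset`).
#' @param repetitions number of independent runs. Default 30.
#' @param train_fraction share of each class used for training. Default 0.80.
#' @param level confidence level of the t interval. Default 0.95.
#' @param label name of the label column.
#' @param params,config neuron model and simulation settings.
#' @param n_sources,max_cycles,limit,lower,upper ABC settings (see
#'   [train_spiking_classifier()]).
#' @param seed base integer seed. Default 1.
#' @return An object of class `spiking_experiment`: `runs` (tibble with
#'   `run`, `seed`, `train_accuracy`, `test_accuracy`), `curves` (tibble
#'   with `run`, `cycle`, `best_error`), `level` and the settings used.
#' @export
#' @examples
#' pd <- make_planted(classes = 2, features = 3, n = 40, seed = 1)
#' ex <- run_experiment(pd, repetitions = 2, max_cycles = 20, seed = 1)
#' glance(ex)
run_experiment <- function(data, repetitions = 30, train_fraction = 0.8,
                           level = 0.95, label = "class",
                           params = regular_spiking(),
                           config = simulation_config(),
                           n_sources = 40, max_cycles = 1000, limit = 100,
                           lower = -10, upper = 10, seed = 1) {
  if (inherits(data, "planted_dataset")) data <- data$data
  if (repetitions < 1L) stop("`repetitions` must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  runs <- vector("list", repetitions)
  curves <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    seed_r <- seed + r
    sp <- stratified_split(data, train_fraction, label, seed = seed_r)
    fit <- train_spiking_classifier(sp$train, label = label, params = params,
                                    config = config, n_sources = n_sources,
                                    max_cycles = max_cycles, limit = limit,
                                    lower = lower, upper = upper,
                                    seed = seed_r)
    runs[[r]] <- tibble::tibble(
      run = r, seed = seed_r,
      train_accuracy = evaluate_accuracy(fit, sp$train, label),
      test_accuracy = evaluate_accuracy(fit, sp$test, label))
    curves[[r]] <- tibble::tibble(run = r,
                                  cycle = seq_along(fit$abc$history),
                                  best_error = fit$abc$history)
  }
  structure(list(runs = dplyr::bind_rows(runs),
                 curves = dplyr::bind_rows(curves),
                 level = level,
                 settings = list(repetitions = repetitions,
                                 train_fraction = train_fraction,
                                 n_sources = n_sources,
                                 max_cycles = max_cycles, limit = limit,
                                 lower = lower, upper = upper, seed = seed)),
            class = "spiking_experiment")
}

# One summary row per phase (training/testing): mean, sd and t-based CI.
experiment_summary <- function(x) {
  summarize_phase <- function(values, phase) {
    if (length(values) >= 2L) {
      ci <- t_confidence_interval(values, x$level)
      tibble::tibble(phase = phase, mean = ci$mean, sd = ci$sd,
                     ci_lower = ci$lower, ci_upper = ci$upper,
                     level = x$level, n_runs = ci$n)
    } else {
      tibble::tibble(phase = phase, mean = mean(values), sd = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     level = x$level, n_runs = length(values))
    }
  }
  dplyr::bind_rows(summarize_phase(x$runs$train_accuracy, "training"),
                   summarize_phase(x$runs$test_accuracy, "testing"))
}

#' @rdname tidiers
#' @export
tidy.spiking_experiment <- function(x, ...) x$runs

#' @rdname tidiers
#' @export
glance.spiking_experiment <- function(x, ...) {
  s <- experiment_summary(x)
  tibble::tibble(
    n_runs = s$n_runs[1],
    train_mean = s$mean[s$phase == "training"],
    train_sd = s$sd[s$phase == "training"],
    train_ci_lower = s$ci_lower[s$phase == "training"],
    train_ci_upper = s$ci_upper[s$phase == "training"],
    test_mean = s$mean[s$phase == "testing"],
    test_sd = s$sd[s$phase == "testing"],
    test_ci_lower = s$ci_lower[s$phase == "testing"],
    test_ci_upper = s$ci_upper[s$phase == "testing"],
    level = x$level)
}

#' @export
print.spiking_experiment <- function(x, ...) {
  s <- experiment_summary(x)
  fmt <- function(v) formatC(v, digits = 3, format = "f")
  cat("<spiking_experiment>", nrow(x$runs), "runs, train fraction",
      x$settings$train_fraction, "\n")
  for (i in seq_len(nrow(s))) {
    ci <- if (is.na(s$ci_lower[i])) "CI n/a"
          else paste0("CI [", fmt(s$ci_lower[i]), "-", fmt(s$ci_upper[i]), "]")
    pm <- if (is.na(s$sd[i])) "" else paste0(" ± ", fmt(s$sd[i]))
    cat(sprintf("  %-8s cr. %s%s  %s\n", s$phase[i], fmt(s$mean[i]), pm, ci))
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits the per-run accuracies, the per-cycle learning-error curves and the
#' summary table (mean, sd, t-based CI for training and testing
#' classification rates) as CSV files, plus a plain-text summary.
#'
#' @param x a `spiking_experiment`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_experiment_report <- function(x, dir) {
  stopifnot(inherits(x, "spiking_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(x$runs, file.path(dir, "runs.csv"))
  readr::write_csv(x$curves, file.path(dir, "learning_curves.csv"))
  readr::write_csv(experiment_summary(x), file.path(dir, "summary.csv"))
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con)
  print(x)
  sink()
  close(con)
  invisible(dir)
}
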