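#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib spikebee, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Min-max scaling to [0, 1] with stored training ranges; constant features
# map to 0.
minmax_apply <- function(X, scaling) {
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1
  sweep(sweep(X, 2, scaling$min, "-"), 2, rng, "/")
}

# Validate a labeled pattern data frame and unpack it into a feature matrix
# plus 1..K integer labels. Labels are remapped in first-appearance order;
# the mapping is kept so predictions are reported on the original labels.
prepare_dataset <- function(data, label = "class") {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame of patterns", call. = FALSE)
  }
  if (!label %in% names(data)) {
    stop("label column `", label, "` not found in `data`", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` has no patterns", call. = FALSE)
  y_raw <- data[[label]]
  feats <- setdiff(names(data), label)
  if (length(feats) == 0L) stop("`data` has no feature columns", call. = FALSE)
  X <- as.matrix(data[feats])
  if (!is.numeric(X) || !all(is.finite(X))) {
    stop("feature columns must be finite numerics", call. = FALSE)
  }
  labels <- unique(y_raw)
  y <- match(y_raw, labels)
  K <- length(labels)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(X) < K) stop("need at least one pattern per class", call. = FALSE)
  list(X = X, y = y, K = K, labels = labels, features = feats)
}

#' Input current of a pattern
#'
#' The neuron is not stimulated with the pattern directly: each feature is
#' treated as the presynaptic potential of a receptive field and the
#' constant stimulation current is the weighted sum `I = x . w`.
#'
#' @param x numeric feature vector.
#' @param w synaptic weight vector of the same length.
#' @return A single number, the input current.
#' @export
#' @examples
#' input_current(c(1, 2), c(0.5, -1))
input_current <- function(x, w) {
  if (length(x) != length(w)) {
    stop("`x` and `w` must have the same length", call. = FALSE)
  }
  sum(as.numeric(x) * as.numeric(w))
}

#' Firing rate evoked by a pattern
#'
#' Composition of the current transform and the neuron simulation:
#' `firing_rate(simulate_neuron(input_current(x, w)))`.
#'
#' @inheritParams input_current
#' @param params an [izhikevich_params()] object.
#' @param config a [simulation_config()] object.
#' @return Firing rate in spikes/ms, in `[0, 1/dt]`.
#' @export
pattern_firing_rate <- function(x, w, params = regular_spiking(),
                                config = simulation_config()) {
  firing_rate(simulate_neuron(input_current(x, w), params, config))
}

# Rates for all rows of a feature matrix under weights w.
matrix_firing_rates <- function(X, w, params, config) {
  spike_counts(drop(X %*% w), params, config) / config$t_window
}

# AFR_k = mean firing rate over the patterns of class k.
afr_from_rates <- function(rates, y, K) {
  afr <- vapply(seq_len(K), function(k) {
    r <- rates[y == k]
    if (length(r) == 0L) {
      stop("empty class: no patterns with label index ", k, call. = FALSE)
    }
    mean(r)
  }, numeric(1))
  afr
}

#' Per-class average firing rates (AFR)
#'
#' For a weight vector `w`, simulates every pattern and averages the firing
#' rates within each class. These per-class averages are the class
#' prototypes of the decision rule.
#'
#' @param data data frame of patterns with a label column.
#' @param w synaptic weight vector (one weight per feature column).
#' @param params,config neuron model and simulation settings.
#' @param label name of the label column. Default `"class"`.
#' @return A tibble with columns `class` (original label), `n` (patterns)
#'   and `afr` (spikes/ms), one row per class in first-appearance order.
#' @export
average_firing_rates <- function(data, w, params = regular_spiking(),
                                 config = simulation_config(),
                                 label = "class") {
  ds <- prepare_dataset(data, label)
  if (length(w) != ncol(ds$X)) {
    stop("`w` must have one weight per feature column", call. = FALSE)
  }
  rates <- matrix_firing_rates(ds$X, w, params, config)
  tibble::tibble(class = ds$labels,
                 n = as.integer(tabulate(ds$y, ds$K)),
                 afr = afr_from_rates(rates, ds$y, ds$K))
}

#' Nearest-AFR decision rule
#'
#' Assigns each firing rate to the class whose average firing rate is
#' closest: `argmin_k |AFR_k - fr|`. Ties are broken towards the smallest
#' class index, so the rule is deterministic.
#'
#' @param rates numeric vector of firing rates.
#' @param afr numeric vector of per-class average firing rates.
#' @return Integer vector of class indices in `1..length(afr)`.
#' @export
#' @examples
#' classify_rate(0.06, afr = c(0.01, 0.05, 0.10))
classify_rate <- function(rates, afr) {
  if (length(afr) == 0L) stop("`afr` must be non-empty", call. = FALSE)
  d <- abs(outer(as.numeric(rates), as.numeric(afr), "-"))
  max.col(-d, ties.method = "first")
}

# Shared core of performance(): rates -> in-sample AFR -> decisions.
performance_impl <- function(X, y, K, w, params, config) {
  rates <- matrix_firing_rates(X, w, params, config)
  afr <- afr_from_rates(rates, y, K)
  pred <- classify_rate(rates, afr)
  mean(pred == y)
}

#' Classification performance of a weight vector
#'
#' Computes the per-class average firing rates on `data` itself under `w`,
#' classifies every pattern of `data` by the nearest-AFR rule, and returns
#' the fraction correctly classified. This in-sample score is the quantity
#' the training phase maximizes.
#'
#' @inheritParams average_firing_rates
#' @return Accuracy in `[0, 1]`.
#' @export
classification_performance <- function(data, w, params = regular_spiking(),
                                       config = simulation_config(),
                                       label = "class") {
  ds <- prepare_dataset(data, label)
  if (length(w) != ncol(ds$X)) {
    stop("`w` must have one weight per feature column", call. = FALSE)
  }
  performance_impl(ds$X, ds$y, ds$K, w, params, config)
}

#' Training objective: classification error
#'
#' `1 - classification_performance()`; the quantity the bee colony
#' minimizes over the weight box.
#'
#' @inheritParams classification_performance
#' @return Error rate in `[0, 1]`.
#' @export
classification_fitness <- function(data, w, params = regular_spiking(),
                                   config = simulation_config(),
                                   label = "class") {
  1 - classification_performance(data, w, params, config, label)
}

#' Train a single spiking neuron as a pattern classifier
#'
#' Optimizes the synaptic weight vector with the artificial bee colony
#' algorithm so that patterns of the same class evoke similar firing rates
#' and different classes evoke discriminable rates. The objective is the
#' in-sample classification error of the nearest-AFR rule. After training,
#' the per-class average firing rates computed on the training data under
#' the best weights are frozen into the model and used to classify new
#' patterns.
#'
#' @param data data frame of training patterns with a label column.
#' @param label name of the label column. Default `"class"`.
#' @param params,config neuron model and simulation settings; defaults are
#'   the regular-spiking set with `dt = 1` ms and `T = 1000` ms.
#' @param n_sources,max_cycles,limit,lower,upper ABC settings (see
#'   [abc_config()]); defaults `SN = 40`, `MCN = 1000`, `limit = 100`,
#'   weight bounds `[-10, 10]`.
#' @param normalize if `TRUE`, min-max scale each feature to `[0, 1]` using
#'   the training ranges (stored in the model and re-applied at prediction
#'   time). Off by default: the reference protocol applies no feature
#'   scaling.
#' @param seed optional integer seed for an exactly reproducible run.
#'
#' @return An object of class `spiking_classifier` with elements `w` (best
#'   weight vector), `afr` (tibble of per-class average firing rates),
#'   `training_accuracy`, `labels`, `features`, `params`, `config`,
#'   `abc` (the full [abc_optimize()] result) and `seed`.
#' @export
#' @examples
#' d <- make_planted(classes = 2, features = 3, n = 20, seed = 1)
#' fit <- train_spiking_classifier(d$data, max_cycles = 20, seed = 1)
#' fit$training_accuracy
train_spiking_classifier <- function(data, label = "class",
                                     params = regular_spiking(),
                                     config = simulation_config(),
                                     n_sources = 40, max_cycles = 1000,
                                     limit = 100, lower = -10, upper = 10,
                                     normalize = FALSE, seed = NULL) {
  ds <- prepare_dataset(data, label)
  scaling <- NULL
  if (isTRUE(normalize)) {
    scaling <- list(min = apply(ds$X, 2, min), max = apply(ds$X, 2, max))
    ds$X <- minmax_apply(ds$X, scaling)
  }
  objective <- local({
    X <- ds$X; y <- ds$y; K <- ds$K
    function(w) 1 - performance_impl(X, y, K, w, params, config)
  })
  cfg <- abc_config(dim = ncol(ds$X), lower = lower, upper = upper,
                    n_sources = n_sources, max_cycles = max_cycles,
                    limit = limit, seed = seed)
  res <- abc_optimize(objective, cfg)
  rates <- matrix_firing_rates(ds$X, res$best_x, params, config)
  afr <- afr_from_rates(rates, ds$y, ds$K)
  structure(list(w = stats::setNames(res$best_x, ds$features),
                 scaling = scaling,
                 afr = tibble::tibble(class = ds$labels,
                                      n = as.integer(tabulate(ds$y, ds$K)),
                                      afr = afr),
                 training_accuracy = 1 - res$best_f,
                 labels = ds$labels, features = ds$features,
                 params = params, config = config, abc = res, seed = seed),
            class = "spiking_classifier")
}

#' @export
print.spiking_classifier <- function(x, ...) {
  cat("<spiking_classifier>", length(x$w), "synapses,",
      nrow(x$afr), "classes\n")
  cat("  training accuracy:", format(x$training_accuracy, digits = 4), "\n")
  cat("  AFR (spikes/ms):",
      paste(format(x$afr$afr, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes (or firing rates) for new patterns
#'
#' Each pattern is converted to an input current with the trained weights,
#' the neuron is simulated, and the firing rate is compared against the
#' model's frozen per-class average firing rates; the nearest one decides
#' the class.
#'
#' @param object a `spiking_classifier`.
#' @param newdata data frame of patterns; must contain the training feature
#'   columns (a label column, if present, is ignored).
#' @param type `"class"` for predicted labels (on the original label
#'   scale), `"rate"` for the evoked firing rates.
#' @param ... unused.
#' @return A vector of length `nrow(newdata)`.
#' @export
predict.spiking_classifier <- function(object, newdata,
                                       type = c("class", "rate"), ...) {
  type <- match.arg(type)
  if (!is.data.frame(newdata)) {
    stop("`newdata` must be a data frame", call. = FALSE)
  }
  if (nrow(newdata) == 0L) {
    stop("`newdata` is empty: nothing to classify", call. = FALSE)
  }
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("`newdata` lacks feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[object$features])
  if (!is.numeric(X) || !all(is.finite(X))) {
    stop("feature columns must be finite numerics", call. = FALSE)
  }
  if (!is.null(object$scaling)) X <- minmax_apply(X, object$scaling)
  rates <- matrix_firing_rates(X, object$w, object$params, object$config)
  if (type == "rate") return(rates)
  object$labels[classify_rate(rates, object$afr$afr)]
}

#' Accuracy of a trained model on a labeled dataset
#'
#' Classifies every pattern of `data` against the model's frozen training
#' AFR and returns the fraction of correct decisions. Used for the testing
#' phase on held-out patterns; on the training set itself it reproduces the
#' training performance.
#'
#' @param model a `spiking_classifier`.
#' @param data labeled data frame.
#' @param label name of the label column.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, data, label = "class") {
  stopifnot(inherits(model, "spiking_classifier"))
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("`data` must be a non-empty data frame", call. = FALSE)
  }
  if (!label %in% names(data)) {
    stop("label column `", label, "` not found", call. = FALSE)
  }
  pred <- predict(model, data, type = "class")
  mean(pred == data[[label]])
}

#' @rdname tidiers
#' @export
tidy.spiking_classifier <- function(x, ...) {
  tibble::tibble(feature = x$features, weight = unname(x$w))
}

#' @rdname tidiers
#' @export
glance.spiking_classifier <- function(x, ...) {
  tibble::tibble(training_accuracy = x$training_accuracy,
                 training_error = 1 - x$training_accuracy,
                 n_classes = nrow(x$afr), n_features = length(x$w),
                 cycles = x$abc$cycles_run, n_evals = x$abc$n_evals)
}

#' @rdname tidiers
#' @param data data frame of patterns to augment with `.rate` and `.pred`.
#' @export
augment.spiking_classifier <- function(x, data, ...) {
  out <- tibble::as_tibble(data)
  out$.rate <- predict(x, data, type = "rate")
  out$.pred <- predict(x, data, type = "class")
  out
}

#' Save / load a trained classifier as flat text
#'
#' Serializes a `spiking_classifier` as a plain key-value text file
#' (weights, per-class AFR, neuron parameters, simulation settings, label
#' mapping), so a trained model can be reloaded and applied without any
#' binary artifacts.
#'
#' @param model a `spiking_classifier`.
#' @param path file path.
#' @return `write_spiking_classifier()` returns `path` invisibly;
#'   `read_spiking_classifier()` returns the reconstructed model (without
#'   the optimizer trace, which is not serialized).
#' @export
write_spiking_classifier <- function(model, path) {
  stopifnot(inherits(model, "spiking_classifier"))
  num <- function(x) paste(format(x, digits = 17), collapse = ",")
  lines <- c(
    "# spikebee spiking_classifier v1",
    paste0("features: ", paste(model$features, collapse = ",")),
    paste0("weights: ", num(unname(model$w))),
    paste0("class_labels: ", paste(model$labels, collapse = ",")),
    paste0("afr: ", num(model$afr$afr)),
    paste0("afr_n: ", paste(model$afr$n, collapse = ",")),
    paste0("params: ", num(unlist(model$params))),
    paste0("param_names: ", paste(names(model$params), collapse = ",")),
    paste0("dt: ", num(model$config$dt)),
    paste0("t_window: ", num(model$config$t_window)),
    paste0("v0: ", if (is.null(model$config$v0)) "rest"
           else num(model$config$v0)),
    paste0("u0: ", num(model$config$u0)),
    paste0("training_accuracy: ", num(model$training_accuracy)),
    paste0("scaling_min: ", if (is.null(model$scaling)) "none"
           else num(model$scaling$min)),
    paste0("scaling_max: ", if (is.null(model$scaling)) "none"
           else num(model$scaling$max)),
    paste0("seed: ", if (is.null(model$seed)) "none" else model$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spiking_classifier
#' @export
read_spiking_classifier <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  split_num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1L]])
  split_chr <- function(key) strsplit(vals[[key]], ",")[[1L]]
  pars <- stats::setNames(as.list(split_num("params")),
                          split_chr("param_names"))
  params <- do.call(izhikevich_params, pars)
  config <- simulation_config(
    dt = as.numeric(vals[["dt"]]), t_window = as.numeric(vals[["t_window"]]),
    v0 = if (vals[["v0"]] == "rest") NULL else as.numeric(vals[["v0"]]),
    u0 = as.numeric(vals[["u0"]]))
  feats <- split_chr("features")
  labels <- utils::type.convert(split_chr("class_labels"), as.is = TRUE)
  scaling <- if (vals[["scaling_min"]] == "none") NULL
             else list(min = stats::setNames(split_num("scaling_min"), feats),
                       max = stats::setNames(split_num("scaling_max"), feats))
  structure(list(w = stats::setNames(split_num("weights"), feats),
                 scaling = scaling,
                 afr = tibble::tibble(class = labels,
                                      n = as.integer(split_num("afr_n")),
                                      afr = split_num("afr")),
                 training_accuracy = as.numeric(vals[["training_accuracy"]]),
                 labels = labels, features = feats,
                 params = params, config = config, abc = NULL,
                 seed = if (vals[["seed"]] == "none") NULL
                        else as.integer(vals[["seed"]])),
            class = "spiking_classifier")
}
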