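# Class means at the vertices of a regular simplex with the requested
# mutual distance, embedded in n-dimensional feature space. Rows of the
# centered identity are pairwise sqrt(2) apart and lie in the zero-sum
# subspace; an orthonormal basis of that subspace gives K x (K-1)
# coordinates with the same pairwise distances, which are then scaled and
# zero-padded to n dimensions. Requires K <= n + 1.
simplex_means <- function(K, n, separation) {
  if (separation == 0) return(matrix(0, nrow = K, ncol = n))
  if (K > n + 1L) {
    stop("cannot place ", K, " equidistant class means in ", n,
         " dimensions (need K <= n + 1)", call. = FALSE)
  }
  M <- diag(K) - 1 / K
  Q <- qr.Q(qr(t(M)))[, seq_len(K - 1L), drop = FALSE]
  coords <- (M %*% Q) * (separation / sqrt(2))
  cbind(coords, matrix(0, nrow = K, ncol = n - (K - 1L)))
}

# Balanced class sizes summing to n (within +-1 across classes).
balanced_sizes <- function(n, K) {
  base <- n %/% K
  base + (seq_len(K) <= n %% K)
}

#' Gaussian-cluster dataset generator
#'
#' Emulates the shape of UCI-style benchmark problems: `K` isotropic
#' Gaussian clusters whose means sit at mutual distance `separation` in
#' feature space, with balanced class sizes (within one pattern). Useful for
#' exercising the full pipeline with controllable difficulty —
#' `separation = 0` makes all classes identically distributed (the hardest
#' case), while `spread` near 0 gives point clusters.
#'
#' @param classes number of classes `K` (at least 2).
#' @param features number of feature columns `n`. Equidistant mean placement
#'   requires `classes <= features + 1`.
#' @param n total number of patterns (at least `2 * classes`).
#' @param separation Euclidean distance between every pair of class means.
#' @param spread within-class standard deviation (per coordinate).
#' @param seed optional integer seed; fixing it makes the dataset (and any
#'   CSV written from it) byte-identical across calls.
#'
#' @return A tibble with numeric columns `x1..xn` and an integer `class`
#'   column with labels `1..K`.
#' @export
#' @examples
#' make_gaussian_clusters(classes = 3, features = 4, n = 150, seed = 1)
make_gaussian_clusters <- function(classes = 3, features = 4, n = 150,
                                   separation = 3, spread = 1, seed = NULL) {
  K <- as.integer(classes)
  nf <- as.integer(features)
  p <- as.integer(n)
  if (K < 2L) stop("`classes` must be at least 2", call. = FALSE)
  if (nf < 1L) stop("`features` must be at least 1", call. = FALSE)
  if (p < 2L * K) stop("`n` must be at least 2 * classes", call. = FALSE)
  if (spread <= 0) stop("`spread` must be positive", call. = FALSE)
  if (separation < 0) stop("`separation` must be non-negative", call. = FALSE)
  gen <- function() {
    means <- simplex_means(K, nf, separation)
    sizes <- balanced_sizes(p, K)
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(stats::rnorm(sizes[k] * nf, sd = spread),
             nrow = sizes[k], ncol = nf) +
        matrix(means[k, ], nrow = sizes[k], ncol = nf, byrow = TRUE)
    }))
    colnames(X) <- paste0("x", seq_len(nf))
    out <- tibble::as_tibble(X)
    out$class <- rep.int(seq_len(K), sizes)
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Planted-weights dataset generator
#'
#' Constructs a dataset that is separable by the spiking-neuron classifier
#' *by construction*: a known weight vector `w_star` maps every class-`k`
#' pattern to an input current near a class-specific level, so under
#' `w_star` the classes produce well-separated firing rates. Each pattern
#' is built as the component along `w_star` that realizes its target current
#' exactly, plus Gaussian noise in the orthogonal complement (which cannot
#' change the current).
#'
#' The default current levels are evenly spaced on `[60, 140]` pA, inside
#' the regular-spiking regime's region of increasing rate-current response;
#' `jitter` perturbs each pattern's current uniformly within its level
#' (default 2 pA, small against the default 40 pA level gaps).
#'
#' @param classes,features,n as in [make_gaussian_clusters()].
#' @param w_star planted weight vector of length `features`; `NULL` draws a
#'   random direction scaled to norm 5 (within the training bounds).
#' @param current_levels length-`classes` vector of target input currents,
#'   pairwise separated by more than `2 * jitter`.
#' @param jitter half-width of the uniform within-class current noise (pA).
#' @param spread standard deviation of the orthogonal-complement noise.
#' @param seed optional integer seed.
#'
#' @return An object of class `planted_dataset`: a list with `data` (tibble
#'   as in [make_gaussian_clusters()]), `w_star`, `current_levels`,
#'   `jitter`, `spread`.
#' @export
#' @examples
#' pd <- make_planted(classes = 3, features = 4, n = 150, seed = 1)
#' classification_performance(pd$data, pd$w_star)
make_planted <- function(classes = 3, features = 4, n = 150, w_star = NULL,
                         current_levels = NULL, jitter = 2, spread = 1,
                         seed = NULL) {
  K <- as.integer(classes)
  nf <- as.integer(features)
  p <- as.integer(n)
  if (K < 2L) stop("`classes` must be at least 2", call. = FALSE)
  if (nf < 1L) stop("`features` must be at least 1", call. = FALSE)
  if (p < 2L * K) stop("`n` must be at least 2 * classes", call. = FALSE)
  if (jitter < 0) stop("`jitter` must be non-negative", call. = FALSE)
  if (is.null(current_levels)) {
    current_levels <- seq(60, 140, length.out = K)
  }
  if (length(current_levels) != K) {
    stop("`current_levels` must have one level per class", call. = FALSE)
  }
  gaps <- abs(diff(sort(current_levels)))
  if (any(gaps <= 2 * jitter)) {
    stop("`current_levels` must be pairwise separated by more than ",
         "2 * jitter", call. = FALSE)
  }
  if (!is.null(w_star)) {
    w_star <- as.numeric(w_star)
    if (length(w_star) != nf || !all(is.finite(w_star)) ||
        sum(w_star^2) == 0) {
      stop("`w_star` must be a finite non-zero vector of length `features`",
           call. = FALSE)
    }
  }
  gen <- function() {
    if (is.null(w_star)) {
      w_star <- stats::rnorm(nf)
      w_star <- 5 * w_star / sqrt(sum(w_star^2))
    }
    wn2 <- sum(w_star^2)
    w_hat <- w_star / sqrt(wn2)
    sizes <- balanced_sizes(p, K)
    rows <- vector("list", K)
    for (k in seq_len(K)) {
      I_k <- current_levels[k] +
        stats::runif(sizes[k], -jitter, jitter)
      Z <- matrix(stats::rnorm(sizes[k] * nf, sd = spread),
                  nrow = sizes[k], ncol = nf)
      Z <- Z - (Z %*% w_hat) %*% t(w_hat)          # orthogonal to w_star
      rows[[k]] <- (I_k / wn2) %*% t(w_star) + Z   # x . w_star = I_k exactly
    }
    X <- do.call(rbind, rows)
    colnames(X) <- paste0("x", seq_len(nf))
    out <- tibble::as_tibble(X)
    out$class <- rep.int(seq_len(K), sizes)
    structure(list(data = out, w_star = w_star,
                   current_levels = current_levels, jitter = jitter,
                   spread = spread),
              class = "planted_dataset")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat("<planted_dataset>", nrow(x$data), "patterns,",
      length(x$current_levels), "classes; current levels",
      paste(x$current_levels, collapse = ", "), "pA (jitter ±", x$jitter,
      ")\n")
  invisible(x)
}

#' Benchmark-shaped dataset presets
#'
#' Shapes (classes x features x patterns) mirroring the benchmark problems
#' commonly used with this method: iris 3x4x150, wine 3x13x178, glass (two
#' most represented classes) 2x9x146, diabetes 2x8x768, liver 2x6x345 and a
#' five-object recognition set 5x7x100. Only the shapes are mirrored — the
#' generated values are synthetic (Gaussian clusters or planted-weights
#' constructions), not the real benchmark data.
#'
#' @return `dataset_presets()` returns a tibble of available shapes.
#' @export
#' @examples
#' dataset_presets()
#' d <- make_preset("iris", kind = "planted", seed = 1)
#' dim(d$data)
dataset_presets <- function() {
  tibble::tibble(
    name = c("iris", "wine", "glass", "diabetes", "liver", "objects"),
    classes = c(3L, 3L, 2L, 2L, 2L, 5L),
    features = c(4L, 13L, 9L, 8L, 6L, 7L),
    n = c(150L, 178L, 146L, 768L, 345L, 100L)
  )
}

#' @rdname dataset_presets
#' @param name one of the preset names of `dataset_presets()`.
#' @param kind `"planted"` (separable by construction; returns a
#'   `planted_dataset`) or `"clusters"` (Gaussian clusters; returns a
#'   tibble).
#' @param seed optional integer seed.
#' @param ... further arguments passed to [make_planted()] or
#'   [make_gaussian_clusters()].
#' @export
make_preset <- function(name, kind = c("planted", "clusters"), seed = NULL,
                        ...) {
  kind <- match.arg(kind)
  presets <- dataset_presets()
  row <- presets[presets$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown preset `", name, "`; see dataset_presets()", call. = FALSE)
  }
  if (kind == "planted") {
    make_planted(classes = row$classes, features = row$features, n = row$n,
                 seed = seed, ...)
  } else {
    make_gaussian_clusters(classes = row$classes, features = row$features,
                           n = row$n, seed = seed, ...)
  }
}

#' Read / write pattern datasets as CSV
#'
#' The CSV dialect shared by the generators and the classifier: one row per
#' pattern, feature columns plus one label column (named `class` by
#' default).
#'
#' @param data data frame of patterns.
#' @param path file path.
#' @param label name of the label column (for reading validation).
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a tibble.
#' @export
write_dataset_csv <- function(data, path) {
  if (inherits(data, "planted_dataset")) data <- data$data
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, label = "class") {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prepare_dataset(data, label)  # validation only
  data
}
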