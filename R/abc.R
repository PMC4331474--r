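#' Artificial bee colony configuration
#'
#' Settings for the box-constrained ABC minimizer. The defaults are the
#' settings used throughout the classifier experiments: `n_sources = 40`,
#' `max_cycles = 1000`, `limit = 100`, bounds `[-10, 10]` per dimension.
#'
#' @param dim dimension of the search space (number of decision variables).
#' @param lower,upper per-dimension bounds; scalars are recycled to `dim`.
#' @param n_sources number of food sources `SN`; equals the number of
#'   employed bees and the number of onlooker bees. At least 2.
#' @param max_cycles maximum cycle number `MCN` (stop criterion). `0` is
#'   allowed and returns the best of the initial population.
#' @param limit abandonment threshold: a source whose trial counter exceeds
#'   `limit` is re-seeded by a scout. `Inf` disables scouting.
#' @param seed optional integer seed; when given, the whole run is driven by
#'   one generator seeded here and is exactly reproducible.
#'
#' @return An object of class `abc_config`.
#' @export
#' @examples
#' abc_config(dim = 10)
abc_config <- function(dim, lower = -10, upper = 10, n_sources = 40,
                       max_cycles = 1000, limit = 100, seed = NULL) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1) {
    stop("`dim` must be a positive integer", call. = FALSE)
  }
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper in every dimension",
         call. = FALSE)
  }
  if (n_sources < 2) stop("`n_sources` must be at least 2", call. = FALSE)
  if (max_cycles < 0) stop("`max_cycles` must be >= 0", call. = FALSE)
  if (limit < 0) stop("`limit` must be >= 0", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(dim = dim, lower = lower, upper = upper,
                 n_sources = as.integer(n_sources),
                 max_cycles = as.integer(max_cycles), limit = limit,
                 seed = seed),
            class = "abc_config")
}

#' @export
print.abc_config <- function(x, ...) {
  cat("<abc_config> D =", x$dim, "| SN =", x$n_sources, "| MCN =",
      x$max_cycles, "| limit =", x$limit, "| bounds [",
      min(x$lower), ",", max(x$upper), "]\n")
  invisible(x)
}

# Nectar transform: maps a minimized objective value to a positive fitness
# used by the roulette selection. Objectives here are classification errors
# in [0, 1], for which fit = 1/(1 + f); negative objectives map to 1 + |f|.
abc_fitness_transform <- function(f) {
  ifelse(f >= 0, 1 / (1 + f), 1 + abs(f))
}

eval_objective <- function(objective, x) {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stop("objective returned a non-finite value at x = (",
         paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
  }
  as.numeric(f)
}

#' Initialize an ABC population
#'
#' Draws every coordinate uniformly in its bounds,
#' `x_ij = l_j + rand(0,1) * (u_j - l_j)` (the same formula a scout uses),
#' and evaluates the objective on each source.
#'
#' @param objective function mapping a length-`dim` numeric vector to a
#'   single finite number (minimized).
#' @param config an [abc_config()].
#' @return A list with `x` (an `n_sources` x `dim` matrix), `f` (objective
#'   values), `fit` (nectar amounts) and `trial` (all zero).
#' @export
abc_init_population <- function(objective, config) {
  sn <- config$n_sources
  d <- config$dim
  x <- matrix(stats::runif(sn * d), nrow = sn, ncol = d)
  x <- sweep(sweep(x, 2, config$upper - config$lower, "*"), 2,
             config$lower, "+")
  f <- apply(x, 1L, function(row) eval_objective(objective, row))
  list(x = x, f = f, fit = abc_fitness_transform(f),
       trial = integer(sn))
}

#' Candidate food source from a neighbour
#'
#' Perturbs one coordinate of `x_i` towards/away from the same coordinate of
#' another source: `v_j = x_ij + phi * (x_ij - x_kj)`, then clips the
#' perturbed coordinate to its bounds.
#'
#' @param x_i position being exploited.
#' @param x_k a different source's position (caller guarantees `k != i`).
#' @param j index of the single perturbed dimension.
#' @param phi scalar in `[-1, 1]`.
#' @param lower,upper bound vectors.
#' @return The candidate position (same length as `x_i`).
#' @export
#' @examples
#' abc_neighbor(c(2, 0), c(4, 0), j = 1, phi = 0.5,
#'              lower = c(-10, -10), upper = c(10, 10))
abc_neighbor <- function(x_i, x_k, j, phi, lower, upper) {
  v <- x_i
  v[j] <- x_i[j] + phi * (x_i[j] - x_k[j])
  v[j] <- min(max(v[j], lower[j]), upper[j])
  v
}

#' Roulette selection probabilities
#'
#' Fitness-proportional probabilities `p_i = fit_i / sum(fit)` used by the
#' onlooker bees.
#'
#' @param fit vector of positive nectar amounts.
#' @return A probability vector summing to 1.
#' @export
abc_selection_prob <- function(fit) {
  s <- sum(fit)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate selection: total fitness is not positive", call. = FALSE)
  }
  fit / s
}

#' Greedy replacement of a food source
#'
#' A candidate with equal or better nectar (objective value less than or
#' equal to the source's) replaces the source and resets its trial counter;
#' otherwise the source is kept and the counter incremented.
#'
#' @param source list with elements `x`, `f`, `fit`, `trial` (one source).
#' @param candidate candidate position (already within bounds).
#' @param objective the objective function.
#' @return The updated source list.
#' @export
abc_greedy_replace <- function(source, candidate, objective) {
  f_new <- eval_objective(objective, candidate)
  if (f_new <= source$f) {
    list(x = candidate, f = f_new, fit = abc_fitness_transform(f_new),
         trial = 0L)
  } else {
    source$trial <- source$trial + 1L
    source
  }
}

#' Minimize an objective with the artificial bee colony algorithm
#'
#' Classical ABC over a box: each cycle runs an employed phase (every source
#' produces one single-dimension neighbour candidate and is greedily
#' replaced on ties-or-better), an onlooker phase (`SN` roulette-wheel draws
#' proportional to nectar, each exploiting the selected source the same
#' way), and a scout phase (the single source with the largest trial
#' counter, if it exceeds `limit`, is re-drawn uniformly in the box). The
#' best position ever visited is tracked across cycles.
#'
#' Randomness: one generator drives the run. Per bee action the draw order
#' is fixed — dimension `j`, partner `k`, then `phi` — and one uniform draw
#' per onlooker selects the source by cumulative-sum inversion, so a run is
#' exactly reproducible from its seed.
#'
#' @inheritParams abc_init_population
#' @return An object of class `abc_result`: `best_x`, `best_f`, `history`
#'   (best-so-far objective at the end of each cycle, non-increasing),
#'   `cycles_run`, `n_evals`, `n_scouts` and the final `population`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- abc_optimize(sphere, abc_config(dim = 5, max_cycles = 100, seed = 1))
#' res$best_f
abc_optimize <- function(objective, config) {
  stopifnot(inherits(config, "abc_config"))
  run <- function() abc_run_impl(objective, config)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

abc_run_impl <- function(objective, config) {
  sn <- config$n_sources
  d <- config$dim
  lower <- config$lower
  upper <- config$upper
  limit <- config$limit

  pop <- abc_init_population(objective, config)
  n_evals <- sn
  n_scouts <- 0L

  ib <- which.min(pop$f)
  best_x <- pop$x[ib, ]
  best_f <- pop$f[ib]

  # Exploit source i with one neighbour candidate; fixed draw order j, k, phi.
  exploit <- function(i) {
    j <- sample.int(d, 1L)
    k <- sample.int(sn - 1L, 1L)
    if (k >= i) k <- k + 1L
    phi <- stats::runif(1L, -1, 1)
    cand <- abc_neighbor(pop$x[i, ], pop$x[k, ], j, phi, lower, upper)
    f_new <- eval_objective(objective, cand)
    n_evals <<- n_evals + 1L
    if (f_new <= pop$f[i]) {
      pop$x[i, ] <<- cand
      pop$f[i] <<- f_new
      pop$fit[i] <<- abc_fitness_transform(f_new)
      pop$trial[i] <<- 0L
      if (f_new < best_f) {
        best_f <<- f_new
        best_x <<- cand
      }
    } else {
      pop$trial[i] <<- pop$trial[i] + 1L
    }
  }

  history <- numeric(config$max_cycles)
  for (cycle in seq_len(config$max_cycles)) {
    for (i in seq_len(sn)) exploit(i)                       # employed bees
    cum_p <- cumsum(abc_selection_prob(pop$fit))
    for (o in seq_len(sn)) {                                # onlooker bees
      i <- findInterval(stats::runif(1L), cum_p) + 1L
      if (i > sn) i <- sn  # guard the u == 1 edge
      exploit(i)
    }
    im <- which.max(pop$trial)                              # scout bee
    if (pop$trial[im] > limit) {
      xs <- lower + stats::runif(d) * (upper - lower)
      fs <- eval_objective(objective, xs)
      n_evals <- n_evals + 1L
      pop$x[im, ] <- xs
      pop$f[im] <- fs
      pop$fit[im] <- abc_fitness_transform(fs)
      pop$trial[im] <- 0L
      n_scouts <- n_scouts + 1L
      if (fs < best_f) {
        best_f <- fs
        best_x <- xs
      }
    }
    history[cycle] <- best_f
  }

  structure(list(best_x = best_x, best_f = best_f, history = history,
                 cycles_run = config$max_cycles, n_evals = n_evals,
                 n_scouts = n_scouts, population = pop, config = config),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result> best f =", format(x$best_f, digits = 6), "after",
      x$cycles_run, "cycles (", x$n_evals, "evaluations,", x$n_scouts,
      "scout restarts )\n")
  invisible(x)
}

#' Tidiers for spikebee objects
#'
#' [generics::tidy()], [generics::glance()] and [generics::augment()]
#' methods returning tibbles.
#'
#' @param x a spikebee object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.abc_result <- function(x, ...) {
  tibble::tibble(cycle = seq_along(x$history), best_f = x$history)
}

#' @rdname tidiers
#' @export
glance.abc_result <- function(x, ...) {
  tibble::tibble(best_f = x$best_f, cycles = x$cycles_run,
                 n_evals = x$n_evals, n_scouts = x$n_scouts,
                 dim = x$config$dim)
}
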