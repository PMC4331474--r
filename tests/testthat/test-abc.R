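sphere <- function(x) sum(x^2)

test_that("config validation enforces the documented invariants", {
  expect_error(abc_config(dim = 0), "dim")
  expect_error(abc_config(dim = 2, n_sources = 1), "n_sources")
  expect_error(abc_config(dim = 2, lower = 1, upper = 1), "lower < upper")
  cfg <- abc_config(dim = 3)
  expect_identical(cfg$n_sources, 40L)
  expect_identical(cfg$max_cycles, 1000L)
  expect_identical(cfg$limit, 100)
  expect_identical(cfg$lower, rep(-10, 3))
  expect_identical(cfg$upper, rep(10, 3))
})

test_that("initialization fills the box and is seeded-deterministic", {
  cfg <- abc_config(dim = 4, n_sources = 10, lower = c(-1, 0, 2, -5),
                    upper = c(1, 3, 2.5, 5))
  p1 <- withr::with_seed(3, abc_init_population(sphere, cfg))
  p2 <- withr::with_seed(3, abc_init_population(sphere, cfg))
  expect_identical(p1, p2)
  expect_true(all(sweep(p1$x, 2, cfg$lower, ">=")))
  expect_true(all(sweep(p1$x, 2, cfg$upper, "<=")))
  expect_identical(p1$trial, integer(10))
  expect_equal(p1$f, apply(p1$x, 1, sphere))
  bad <- function(x) NaN
  expect_error(withr::with_seed(3, abc_init_population(bad, cfg)),
               "non-finite")
})

test_that("neighbour candidates follow the single-dimension formula", {
  lo <- rep(-10, 2); up <- rep(10, 2)
  # v_j = x_ij + phi (x_ij - x_kj): 2 + 0.5 (2 - 4) = 1
  expect_identical(abc_neighbor(c(2, 7), c(4, -3), j = 1, phi = 0.5, lo, up),
                   c(1, 7))
  # phi = 0 leaves the source untouched
  x <- c(3.5, -2)
  expect_identical(abc_neighbor(x, c(9, 9), j = 2, phi = 0, lo, up), x)
  # out-of-bound raw value 9 + 1 * (9 - (-9)) = 27 clips to the upper bound
  expect_identical(abc_neighbor(c(9, 0), c(-9, 0), j = 1, phi = 1, lo, up),
                   c(10, 0))
  expect_identical(abc_neighbor(c(-9, 0), c(9, 0), j = 1, phi = 1, lo, up),
                   c(-10, 0))
})

test_that("selection probabilities are fitness-proportional and sum to 1", {
  expect_equal(abc_selection_prob(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(abc_selection_prob(rep(7, 5)), rep(1 / 5, 5))
  expect_identical(abc_selection_prob(3), 1)
  for (s in 1:5) {
    fit <- withr::with_seed(s, runif(40, 0.01, 2))
    expect_equal(sum(abc_selection_prob(fit)), 1, tolerance = 1e-12)
  }
  expect_error(abc_selection_prob(c(0, 0)), "degenerate")
})

test_that("greedy replacement implements equal-or-better with trial reset", {
  src <- list(x = c(1, 1), f = 5, fit = 1 / 6, trial = 2L)
  f_of <- function(x) x[1]
  better <- abc_greedy_replace(src, c(3, 0), f_of)
  expect_identical(better$x, c(3, 0))
  expect_identical(better$f, 3)
  expect_identical(better$trial, 0L)
  worse <- abc_greedy_replace(list(x = c(3, 0), f = 3, fit = 0.25,
                                   trial = 2L), c(5, 0), f_of)
  expect_identical(worse$x, c(3, 0))
  expect_identical(worse$trial, 3L)
  tie <- abc_greedy_replace(list(x = c(3, 0), f = 3, fit = 0.25,
                                 trial = 4L), c(3, 9), f_of)
  expect_identical(tie$x, c(3, 9))  # equal nectar replaces
  expect_identical(tie$trial, 0L)
})

test_that("runs are reproducible and the best-so-far history is monotone", {
  cfg <- abc_config(dim = 5, n_sources = 10, max_cycles = 50, seed = 123)
  r1 <- abc_optimize(sphere, cfg)
  r2 <- abc_optimize(sphere, cfg)
  expect_identical(r1[c("best_x", "best_f", "history")],
                   r2[c("best_x", "best_f", "history")])
  for (s in c(1, 2, 99)) {
    cfg$seed <- s
    r <- abc_optimize(sphere, cfg)
    expect_true(all(diff(r$history) <= 0))
    expect_identical(r$best_f, r$history[length(r$history)])
    expect_true(all(sweep(r$population$x, 2, cfg$lower, ">=")))
    expect_true(all(sweep(r$population$x, 2, cfg$upper, "<=")))
  }
})

test_that("scout policy respects the limit parameter", {
  # limit = Inf: no source is ever abandoned
  r_inf <- abc_optimize(sphere, abc_config(dim = 3, n_sources = 6,
                                           max_cycles = 80, limit = Inf,
                                           seed = 5))
  expect_identical(r_inf$n_scouts, 0L)
  # limit = 0: at most one scout restart per cycle
  r0 <- abc_optimize(sphere, abc_config(dim = 3, n_sources = 6,
                                        max_cycles = 80, limit = 0,
                                        seed = 5))
  expect_lte(r0$n_scouts, r0$cycles_run)
  expect_gt(r0$n_scouts, 0L)
})

test_that("degenerate cycle counts behave per contract", {
  # constant objective: best_f equals the constant after one cycle
  r <- abc_optimize(function(x) 4.2,
                    abc_config(dim = 2, n_sources = 4, max_cycles = 1,
                               seed = 1))
  expect_identical(r$best_f, 4.2)
  # zero cycles: best of the initial population, empty history
  r0 <- abc_optimize(sphere, abc_config(dim = 2, n_sources = 4,
                                        max_cycles = 0, seed = 1))
  init <- withr::with_seed(1, abc_init_population(
    sphere, abc_config(dim = 2, n_sources = 4, max_cycles = 0)))
  expect_identical(r0$best_f, min(init$f))
  expect_length(r0$history, 0)
})

test_that("ABC minimizes the sphere function to high precision", {
  r <- abc_optimize(sphere, abc_config(dim = 5, n_sources = 20,
                                       max_cycles = 300, seed = 17))
  expect_lt(r$best_f, 1e-3)
})

test_that("tidiers return the convergence history", {
  r <- abc_optimize(sphere, abc_config(dim = 2, n_sources = 4,
                                       max_cycles = 10, seed = 2))
  td <- tidy(r)
  expect_identical(td$best_f, r$history)
  expect_identical(nrow(td), 10L)
  g <- glance(r)
  expect_identical(g$best_f, r$best_f)
  expect_identical(g$dim, 2L)
})
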