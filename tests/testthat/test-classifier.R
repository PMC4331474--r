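# Short simulation window keeps unit tests cheap; the full 1000 ms window
# is exercised by the neuron and end-to-end tests.
short_cfg <- simulation_config(t_window = 200)

test_that("input current is the dot product of pattern and weights", {
  expect_identical(input_current(c(1, 2), c(0.5, -1)), -1.5)
  expect_identical(input_current(c(3, -7, 2), c(0, 0, 0)), 0)
  e2 <- c(0, 1, 0)
  w <- c(0.3, -1.2, 4)
  expect_identical(input_current(e2, w), w[2])
  expect_error(input_current(c(1, 2), c(1, 2, 3)), "length")
})

test_that("pattern firing rate composes current, simulation and rate", {
  x <- c(2, -1, 3)
  expect_identical(pattern_firing_rate(x, c(0, 0, 0)), 0)
  w <- c(10, 5, 20)
  I <- input_current(x, w)
  expect_identical(pattern_firing_rate(x, w),
                   length(oracle_izhikevich(I)) / 1000)
  expect_true(pattern_firing_rate(x, w) >= 0 &&
              pattern_firing_rate(x, w) <= 1)
})

test_that("average firing rates are per-class means, stable to duplication", {
  d <- tibble::tibble(x1 = c(8, 12, 20), x2 = c(2, 3, 1),
                      class = c(1, 2, 3))
  w <- c(6, 4)
  afr <- average_firing_rates(d, w, config = short_cfg)
  # one pattern per class: AFR is that pattern's own rate
  rates <- spike_counts(as.matrix(d[1:2]) %*% w, config = short_cfg) / 200
  expect_equal(afr$afr, as.numeric(rates))
  # duplicating patterns within a class leaves the class mean unchanged
  d2 <- d[c(1, 1, 1, 2, 3), ]
  afr2 <- average_firing_rates(d2, w, config = short_cfg)
  expect_equal(afr2$afr, afr$afr)
})

test_that("nearest-AFR rule picks the closest prototype, first on ties", {
  expect_identical(classify_rate(0.06, c(0.01, 0.05, 0.10)), 2L)
  expect_identical(classify_rate(0.10, c(0.01, 0.05, 0.10)), 3L)
  # equidistant: smallest class index wins
  expect_identical(classify_rate(0.03, c(0.02, 0.04)), 1L)
  # agrees with exhaustive search on random instances
  withr::with_seed(42, {
    for (i in 1:50) {
      afr <- runif(sample(2:6, 1))
      fr <- runif(1)
      expect_identical(classify_rate(fr, afr), oracle_nearest_afr(fr, afr))
    }
  })
})

test_that("performance and fitness are complementary and bounded", {
  pd <- make_small_planted()
  perf <- classification_performance(pd$data, pd$w_star, config = short_cfg)
  fit <- classification_fitness(pd$data, pd$w_star, config = short_cfg)
  expect_gte(perf, 0); expect_lte(perf, 1)
  expect_identical(fit, 1 - perf)
  # planted weights separate the classes perfectly by construction
  expect_identical(classification_performance(pd$data, pd$w_star), 1)
})

test_that("zero weights collapse all rates and the tie-break takes over", {
  d <- make_gaussian_clusters(classes = 3, features = 4, n = 30, seed = 2)
  afr <- average_firing_rates(d, rep(0, 4), config = short_cfg)
  expect_identical(afr$afr, rep(0, 3))
  # every pattern lands on class 1; performance equals class-1 prevalence
  perf <- classification_performance(d, rep(0, 4), config = short_cfg)
  expect_identical(perf, mean(d$class == d$class[1]))
})

test_that("dataset validation catches the documented error cases", {
  d <- tibble::tibble(x1 = 1:4, class = c(1, 1, 2, 2))
  expect_error(classification_performance(d[0, ], c(1)), "no patterns")
  expect_error(classification_performance(d, c(1), label = "lab"),
               "not found")
  expect_error(
    classification_performance(tibble::tibble(x1 = 1:3, class = c(1, 1, 1)),
                               1), "2 classes")
  expect_error(classification_performance(d, c(1, 2)), "one weight per")
  d_bad <- d; d_bad$x1[2] <- NA
  expect_error(classification_performance(d_bad, 1), "finite")
})

test_that("training recovers a planted solution and is reproducible", {
  pd <- make_planted(classes = 2, features = 3, n = 30, seed = 4)
  fit1 <- train_spiking_classifier(pd$data, config = short_cfg,
                                   n_sources = 20, max_cycles = 60, seed = 4)
  expect_gte(fit1$training_accuracy, 0.95)
  # evaluating the model on its own training set reproduces the accuracy
  expect_identical(evaluate_accuracy(fit1, pd$data), fit1$training_accuracy)
  # per-class AFR ordering matches the planted current ordering
  expect_identical(order(fit1$afr$afr), order(pd$current_levels))
  fit2 <- train_spiking_classifier(pd$data, config = short_cfg,
                                   n_sources = 20, max_cycles = 60, seed = 4)
  expect_identical(fit1$w, fit2$w)
  expect_identical(fit1$afr, fit2$afr)
})

test_that("an inseparable relabelled dataset caps at the majority rate", {
  # one cluster duplicated under two labels: no weights can split it
  base <- make_gaussian_clusters(classes = 2, features = 3, n = 20,
                                 separation = 0, seed = 9)
  fit <- train_spiking_classifier(base, config = short_cfg, n_sources = 10,
                                  max_cycles = 30, seed = 9)
  expect_lte(fit$training_accuracy, 1)
  expect_gte(fit$training_accuracy, 0.5)  # majority always achievable
})

test_that("prediction validates inputs and maps back to original labels", {
  pd <- make_small_planted()
  d <- pd$data
  d$class <- c("low", "high")[d$class]
  fit <- train_spiking_classifier(d, config = short_cfg, n_sources = 10,
                                  max_cycles = 40, seed = 11)
  pred <- predict(fit, d)
  expect_true(all(pred %in% c("low", "high")))
  expect_error(predict(fit, d[0, ]), "empty")
  expect_error(predict(fit, d[, -1]), "lacks feature")
  rates <- predict(fit, d, type = "rate")
  expect_true(all(rates >= 0 & rates <= 1 / fit$config$dt))
  aug <- augment(fit, d)
  expect_identical(aug$.pred, pred)
  expect_identical(aug$.rate, rates)
})

test_that("a trained model round-trips through the flat text format", {
  pd <- make_small_planted()
  fit <- train_spiking_classifier(pd$data, config = short_cfg,
                                  n_sources = 10, max_cycles = 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spiking_classifier(fit, path)
  back <- read_spiking_classifier(path)
  expect_equal(back$w, fit$w)
  expect_equal(back$afr, fit$afr)
  expect_equal(unlist(back$params), unlist(fit$params))
  expect_identical(predict(back, pd$data), predict(fit, pd$data))
})

test_that("optional min-max scaling is learned, applied and serialized", {
  pd <- make_small_planted()
  d <- pd$data
  d$x1 <- d$x1 * 1000  # wildly different feature scale
  fit <- train_spiking_classifier(d, config = short_cfg, n_sources = 10,
                                  max_cycles = 40, normalize = TRUE,
                                  seed = 5)
  expect_equal(unname(fit$scaling$min), apply(as.matrix(d[1:3]), 2, min),
               ignore_attr = TRUE)
  # scaled training data live in [0, 1]; predictions use the same ranges
  expect_identical(evaluate_accuracy(fit, d), fit$training_accuracy)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spiking_classifier(fit, path)
  back <- read_spiking_classifier(path)
  expect_equal(back$scaling, fit$scaling)
  expect_identical(predict(back, d), predict(fit, d))
  # default remains unscaled
  fit0 <- train_spiking_classifier(pd$data, config = short_cfg,
                                   n_sources = 10, max_cycles = 10, seed = 5)
  expect_null(fit0$scaling)
})

test_that("tidiers expose weights and a one-row training summary", {
  pd <- make_small_planted()
  fit <- train_spiking_classifier(pd$data, config = short_cfg,
                                  n_sources = 10, max_cycles = 20, seed = 3)
  td <- tidy(fit)
  expect_identical(td$weight, unname(fit$w))
  expect_identical(td$feature, fit$features)
  g <- glance(fit)
  expect_identical(g$training_accuracy, fit$training_accuracy)
  expect_equal(g$training_error, 1 - fit$training_accuracy)
})
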