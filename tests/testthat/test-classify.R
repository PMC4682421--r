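test_that("vocabulary building merges training peaks within delta", {
  tr <- list(disc_of(c(1000, 1200)), disc_of(1004))
  v <- build_vocabulary(tr, 10)
  expect_equal(v$positions, c(1002, 1200))
  expect_true(all(diff(v$positions) > v$delta))

  # one spectrum whose peaks are all farther apart than delta: unchanged
  one <- disc_of(c(800, 1500, 2200))
  expect_equal(build_vocabulary(list(one), 10)$positions, c(800, 1500, 2200))

  expect_error(build_vocabulary(list(), 10), "empty",
               class = "rdisc_data_error")
})

test_that("vectorization matches peaks to vocabulary slots", {
  v <- build_vocabulary(list(disc_of(c(1002, 1200))), 10)
  hit <- disc_of(c(1002, 1200), c(0.4, 0.9))
  expect_equal(vectorize_peaks(hit, v), c(0.4, 0.9))
  miss <- disc_of(c(600, 2000), c(0.5, 0.5))
  expect_equal(vectorize_peaks(miss, v), c(0, 0))
  near <- disc_of(1003, 0.7)
  expect_equal(vectorize_peaks(near, v), c(0.7, 0))
})

test_that("k-NN predicts by similarity-ranked majority vote", {
  refs <- labeled_dataset(
    list(disc_of(c(1000, 1500), c(0.3, 0.9)),
         disc_of(c(1001, 1501), c(0.31, 0.88)),
         disc_of(c(2000, 2600), c(0.8, 0.2))),
    c("A", "A", "B"), "discrete")
  expect_equal(knn_predict(refs$items[[1]], refs, k = 1), "A")
  expect_equal(knn_predict(refs$items[[3]], refs, k = 1), "B")
  expect_error(knn_predict(refs$items[[1]], refs, k = 4),
               class = "rdisc_config_error")
})

test_that("k-NN separates well-separated synthetic classes", {
  tpls <- default_templates(2, seed = 71)
  sim <- simulate_dataset(tpls, per_class = 8, n_shifts = 1024, seed = 71)
  disc <- discretize_dataset(sim$dataset)
  refs_idx <- c(1:5, 9:13)
  refs <- labeled_dataset(disc$items[refs_idx], disc$labels[refs_idx],
                          "discrete")
  held <- setdiff(seq_along(disc$items), refs_idx)
  pred <- vapply(held, function(i)
    knn_predict(disc$items[[i]], refs, k = 3), character(1))
  expect_equal(mean(pred == disc$labels[held]), 1)
})

test_that("regularized LDA separates and degrades to chance correctly", {
  set.seed(81)
  x <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             matrix(rnorm(100, 10, 0.5), 50, 2))
  y <- rep(c("lo", "hi"), each = 50)
  fit <- lda_fit(x, y, ridge = 1e-6)
  test_x <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
                  matrix(rnorm(40, 10, 0.5), 20, 2))
  expect_equal(lda_predict(fit, test_x), rep(c("lo", "hi"), each = 20))

  expect_error(lda_fit(x, rep("one", 100)), "2 classes",
               class = "rdisc_data_error")

  # identical class distributions: accuracy near 1/2 on a balanced test
  x0 <- matrix(rnorm(400 * 3), 400, 3)
  y0 <- rep(c("a", "b"), each = 200)
  fit0 <- lda_fit(x0[1:200, ], y0[c(1:100, 201:300)], ridge = 1e-3)
  pred0 <- lda_predict(fit0, x0[201:400, ])
  acc0 <- mean(pred0 == y0[c(101:200, 301:400)])
  expect_gt(acc0, 0.3)
  expect_lt(acc0, 0.7)
})

test_that("LDA agrees with an independent reference fit when well-posed", {
  skip_if_not_installed("MASS")
  set.seed(91)
  x <- rbind(matrix(rnorm(120, 0, 1), 60, 2),
             matrix(rnorm(120, 3, 1), 60, 2),
             matrix(rnorm(120, c(0, 6), 1), 60, 2))
  y <- rep(c("a", "b", "c"), each = 60)
  ours <- lda_predict(lda_fit(x, y, ridge = 0), x)
  ref <- as.character(predict(MASS::lda(x, grouping = y,
                                        prior = rep(1 / 3, 3)))$class)
  expect_gt(mean(ours == ref), 0.98)
})

test_that("evaluation is stratified, deterministic, and leak-free", {
  tpls <- default_templates(3, seed = 101)
  sim <- simulate_dataset(tpls, per_class = 6, n_shifts = 512, seed = 101)
  disc <- discretize_dataset(sim$dataset)

  r1 <- evaluate_classification(disc, "knn", repeats = 3, seed = 5)
  r2 <- evaluate_classification(disc, "knn", repeats = 3, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$mean_accuracy, mean(r1$per_repeat_accuracy))
  expect_true(all(r1$per_repeat_accuracy >= 0 & r1$per_repeat_accuracy <= 1))

  # a marker present only outside the training items never enters the
  # vocabulary fitted on the training side
  train_items <- disc$items[1:12]
  test_only <- disc_of(c(3180), 0.9)
  vocab <- build_vocabulary(train_items, 10)
  expect_false(any(abs(vocab$positions - 3180) <= 10))

  one_member <- labeled_dataset(disc$items[1:3], c("a", "a", "b"),
                                "discrete")
  expect_error(evaluate_classification(one_member, "knn"),
               class = "rdisc_data_error")
})

test_that("permuted labels drop accuracy to chance level", {
  tpls <- default_templates(5, seed = 111)
  sim <- simulate_dataset(tpls, per_class = 8, n_shifts = 512, seed = 111)
  disc <- discretize_dataset(sim$dataset)
  set.seed(9)
  shuffled <- labeled_dataset(disc$items, sample(disc$labels), "discrete")
  r <- evaluate_classification(shuffled, "knn", repeats = 5, seed = 9)
  expect_lt(abs(r$mean_accuracy - 0.2), 0.12)
})
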