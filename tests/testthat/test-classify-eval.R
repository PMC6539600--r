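# A ready-made labelled dataset for harness tests (no feature extraction).
toy_dataset <- function(counts = c(60, 60, 60), seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(0:2, function(lv) {
      n <- counts[lv + 1]
      tibble::tibble(
        recording_id = sprintf("R%d_%d", lv, rep(1:3, length.out = n)),
        tremor_level = lv,
        window = seq_len(n),
        contrast = rnorm(n, mean = 10 * lv, sd = 1),
        homogeneity = rnorm(n, mean = 1 / (1 + lv), sd = 0.05)
      )
    })
  })
}

test_that("dataset assembly stacks per-recording windows with inherited labels", {
  coh <- tiny_cohort()
  ds <- assemble_dataset(coh, N = 49) # 200-sample recordings -> 151 windows
  expect_equal(nrow(ds), 6L * 151L)
  expect_setequal(unique(ds$tremor_level), 0:2)
  expect_true(all(table(ds$recording_id) == 151L))

  ds2 <- assemble_dataset(coh, features = c("contrast", "homogeneity"), N = 49)
  expect_identical(names(ds2),
                   c("recording_id", "tremor_level", "window", "contrast",
                     "homogeneity"))

  # a recording too short for one window is skipped, with a warning
  short <- suppressMessages(simulate_cohort(
    cfg = tremor_config(duration = 1, hold_duration = 0.5),
    composition = tibble::tibble(tremor_level = 1L, hand = "right", n = 1L),
    seed = 3))
  mixed <- dplyr::bind_rows(coh, short)
  expect_warning(ds3 <- assemble_dataset(mixed, N = 49), "skipping")
  expect_equal(nrow(ds3), nrow(ds))
})

test_that("undersampling balances classes exactly and reproducibly", {
  ds <- toy_dataset(counts = c(2000, 1800, 1900))
  b <- balance_classes(ds, per_class = 1800, seed = 4)
  expect_equal(nrow(b), 5400L)
  expect_true(all(table(b$tremor_level) == 1800L))

  expect_equal(sort(balance_classes(ds, per_class = 1800, seed = 4)$window),
               sort(balance_classes(ds, per_class = 1800, seed = 4)$window))

  bal <- toy_dataset(counts = c(50, 50, 50))
  b2 <- balance_classes(bal, per_class = "min", seed = 1)
  expect_equal(as.vector(table(b2$tremor_level)), c(50L, 50L, 50L))

  expect_error(balance_classes(ds, per_class = 2000), "1800")
})

test_that("train/test split honours fraction, determinism and grouping", {
  ds <- toy_dataset(counts = c(400, 300, 300)) # 1000 rows
  sp <- split_train_test(ds, 0.7, seed = 2)
  expect_equal(nrow(sp$train), 700L)
  expect_equal(nrow(sp$test), 300L)
  expect_equal(nrow(dplyr::bind_rows(sp)), 1000L)

  sp2 <- split_train_test(ds, 0.7, seed = 2)
  expect_identical(sp$train, sp2$train)

  spr <- split_train_test(ds, 0.7, seed = 5, grouping = "recording")
  expect_length(intersect(unique(spr$train$recording_id),
                          unique(spr$test$recording_id)), 0L)
  expect_gt(nrow(spr$train), 0L)
  expect_gt(nrow(spr$test), 0L)
})

test_that("classifiers memorize, separate and are deterministic", {
  ds <- toy_dataset()
  # 1-NN memorizes its training set
  m1 <- train_classifier(ds, nearest_neighbor(k = 1))
  expect_equal(mean(predict(m1, ds) == as.character(ds$tremor_level)), 1.0)

  # bagged trees separate a linearly separated toy set perfectly
  sp <- split_train_test(ds, 0.7, seed = 1)
  mb <- train_classifier(sp$train, bagged_trees(), seed = 3)
  expect_equal(mean(predict(mb, sp$test) == as.character(sp$test$tremor_level)), 1.0)

  # same spec + seed + data -> identical predictions
  mb2 <- train_classifier(sp$train, bagged_trees(), seed = 3)
  expect_identical(predict(mb, sp$test), predict(mb2, sp$test))

  expect_error(train_classifier(ds, list(name = "svm")), "unknown classifier")
})

test_that("confusion matrices conserve counts", {
  ds <- toy_dataset(counts = c(10, 10, 10))
  m <- train_classifier(ds, nearest_neighbor(k = 1))
  cm <- evaluate(m, ds) # memorized: perfect diagonal
  expect_equal(unname(diag(cm)), c(10L, 10L, 10L))
  expect_equal(sum(cm), 30L)
  expect_equal(unname(rowSums(cm)), c(10L, 10L, 10L))
  td <- tidy(cm)
  expect_equal(sum(td$n), 30L)
})

test_that("per-class metrics match hand-counted values and flag 0/0", {
  cm <- structure(matrix(c(8L, 2L, 0L, 1L, 9L, 0L, 0L, 0L, 10L), 3, 3,
                         byrow = TRUE, dimnames = list(0:2, 0:2)),
                  class = c("confusion_matrix", "matrix"))
  m <- classification_metrics(cm)
  get <- function(metric, cls = NULL) {
    sel <- m$metric == metric
    if (!is.null(cls)) sel <- sel & m$class %in% cls
    unname(m$value[sel])
  }
  expect_equal(get("accuracy"), 27 / 30)
  expect_equal(get("precision", "0"), 8 / 9)
  expect_equal(get("sensitivity", "0"), 8 / 10)
  expect_equal(get("specificity", "0"), 19 / 20)

  # micro-averaged sensitivity equals accuracy when row sums are equal
  expect_equal(mean(get("sensitivity", as.character(0:2))), get("accuracy"))

  # a class absent from the test set has undefined sensitivity
  cm0 <- structure(matrix(c(5L, 0L, 0L, 0L, 5L, 0L, 0L, 0L, 0L), 3, 3,
                          byrow = TRUE, dimnames = list(0:2, 0:2)),
                   class = c("confusion_matrix", "matrix"))
  m0 <- classification_metrics(cm0)
  expect_true(is.nan(m0$value[m0$metric == "sensitivity" & m0$class == "2"]))
})

test_that("repeated evaluation summarizes min/mean/max reproducibly", {
  ds <- toy_dataset(counts = c(80, 60, 70))
  res <- repeat_evaluation(ds, bagged_trees(n_trees = 10), reps = 5, seed = 9)
  expect_equal(nrow(res$per_rep), 5L * 10L) # accuracy + 3 classes x 3 metrics
  expect_true(all(res$summary$min <= res$summary$mean + 1e-12))
  expect_true(all(res$summary$mean <= res$summary$max + 1e-12))
  expect_true(all(res$per_rep$value >= 0 & res$per_rep$value <= 1))

  res2 <- repeat_evaluation(ds, bagged_trees(n_trees = 10), reps = 5, seed = 9)
  expect_identical(res$summary, res2$summary)

  one <- repeat_evaluation(ds, nearest_neighbor(), reps = 1, seed = 1)
  expect_true(all(one$summary$min == one$summary$max))

  g <- glance(res)
  expect_equal(g$reps, 5)
  expect_true(g$accuracy_min <= g$accuracy_mean && g$accuracy_mean <= g$accuracy_max)
  expect_equal(nrow(tidy(res)), nrow(res$per_rep))
})
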