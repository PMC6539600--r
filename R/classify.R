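#' Assemble a labelled window-feature dataset from a cohort
#'
#' Extracts windowed SDH features from every recording (both hands, all
#' levels combined, with no left/right mirroring) and stacks them into one
#' labelled table; each window inherits its recording's tremor level.
#' Recordings too short for a single window are skipped with a warning.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] / [read_cohort()]).
#' @param features Optional character vector of feature names to keep
#'   (e.g. `c("contrast", "homogeneity")`); default all nine.
#' @inheritParams sdh_features
#' @return A tibble with `recording_id`, `window`, `tremor_level` and one
#'   column per (channel x) feature.
#' @export
assemble_dataset <- function(cohort, channels = "palm_pos_x", features = NULL,
                             M = 1, N = 149, stride = 1, bin_width = 0.1,
                             kernel = c("abs", "squared")) {
  kernel <- match.arg(kernel)
  stopifnot(nrow(cohort) > 0)
  if (!is.null(features)) {
    stopifnot(all(features %in% sdh_feature_names))
  }
  parts <- purrr::map(cohort$recording, function(rec) {
    f <- tryCatch(
      sdh_features(rec, channels = channels, M = M, N = N, stride = stride,
                   bin_width = bin_width, kernel = kernel),
      error = function(e) {
        warning("skipping ", recording_id(rec), ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(f)) return(NULL)
    f$start <- NULL
    dplyr::bind_cols(tibble::tibble(recording_id = recording_id(rec),
                                    tremor_level = tremor_level(rec)),
                     f)
  })
  ds <- dplyr::bind_rows(parts)
  if (!is.null(features)) {
    keep <- if (length(channels) == 1) features else
      as.vector(outer(channels, features, paste, sep = "_"))
    ds <- ds[, c("recording_id", "tremor_level", "window", keep)]
  }
  ds
}

# Feature columns of a dataset = everything that is not bookkeeping.
feature_columns <- function(ds) {
  setdiff(names(ds), c("recording_id", "tremor_level", "window", "start"))
}

#' Balance class counts by random undersampling
#'
#' Draws, without replacement, the same number of windows from every tremor
#' level. Deterministic given `seed`.
#'
#' @param ds A feature dataset from [assemble_dataset()].
#' @param per_class Target rows per class, or `"min"` (the size of the
#'   smallest class).
#' @param seed Integer seed.
#' @return The balanced dataset (rows shuffled within class).
#' @export
balance_classes <- function(ds, per_class = "min", seed = 1) {
  counts <- table(ds$tremor_level)
  target <- if (identical(per_class, "min")) min(counts) else as.integer(per_class)
  short <- counts[counts < target]
  if (length(short) > 0) {
    stop("cannot draw ", target, " rows per class; class ",
         paste(names(short), collapse = ", "), " has only ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    ds |>
      dplyr::group_by(.data$tremor_level) |>
      dplyr::slice_sample(n = target) |>
      dplyr::ungroup()
  })
}

#' Split a dataset into train and test sets
#'
#' `grouping = "window"` performs the reference protocol's uniform row-level
#' 70/30 split (sizes within one row of the requested fraction). Because
#' overlapping windows of one recording are highly correlated, this leaks
#' information between sides; `grouping = "recording"` is the leakage-safe
#' alternative that keeps all windows of a recording on one side, at the best
#' achievable fraction.
#'
#' @param ds A feature dataset.
#' @param train_fraction Fraction of rows for training, in (0, 1).
#' @param seed Integer seed.
#' @param grouping `"window"` (default) or `"recording"`.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(ds, train_fraction = 0.7, seed = 1,
                             grouping = c("window", "recording")) {
  grouping <- match.arg(grouping)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(ds)
  withr::with_seed(as.integer(seed), {
    if (grouping == "window") {
      n_train <- round(train_fraction * n)
      if (n_train == 0 || n_train == n) {
        stop("split would leave an empty side", call. = FALSE)
      }
      idx <- sample.int(n, n_train)
      list(train = ds[idx, , drop = FALSE], test = ds[-idx, , drop = FALSE])
    } else {
      ids <- unique(ds$recording_id)
      if (length(ids) < 2) {
        stop("recording-level split needs at least 2 recordings", call. = FALSE)
      }
      ids <- sample(ids)
      sizes <- vapply(ids, function(i) sum(ds$recording_id == i), integer(1))
      cum <- cumsum(sizes)
      k <- which.min(abs(cum[-length(cum)] - train_fraction * n))
      train_ids <- ids[seq_len(k)]
      list(train = ds[ds$recording_id %in% train_ids, , drop = FALSE],
           test = ds[!ds$recording_id %in% train_ids, , drop = FALSE])
    }
  })
}

#' Classifier specifications
#'
#' The evaluation harness is pluggable; two classifiers are built in, the two
#' that led the reference comparison. `bagged_trees()` is an ensemble of
#' decision trees trained on bootstrap replicates of the training set and
#' combined by majority vote (30 unpruned trees by default, bootstrap size =
#' training size, all features considered at every split). `nearest_neighbor()`
#' is k-nearest-neighbour with Euclidean distance; "fine" KNN is read as
#' `k = 1`.
#'
#' @param n_trees Number of bootstrap trees.
#' @param k Number of neighbours.
#' @return A `classifier_spec`.
#' @export
bagged_trees <- function(n_trees = 30) {
  structure(list(name = "bagged_trees", n_trees = n_trees),
            class = "classifier_spec")
}

#' @rdname bagged_trees
#' @export
nearest_neighbor <- function(k = 1) {
  structure(list(name = "knn", k = k), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", x$name,
      if (x$name == "bagged_trees") paste0("(", x$n_trees, " trees)")
      else paste0("(k = ", x$k, ")"), "\n")
  invisible(x)
}

#' Train a classifier on a feature dataset
#'
#' @param train Training dataset (feature columns plus `tremor_level`).
#' @param spec A [bagged_trees()] or [nearest_neighbor()] specification.
#' @param seed Integer seed (bootstrap resampling / tie-breaking).
#' @return A `tremor_model`; use [predict()] to obtain level labels.
#' @export
train_classifier <- function(train, spec, seed = 1) {
  if (!inherits(spec, "classifier_spec")) stop("unknown classifier spec", call. = FALSE)
  feats <- feature_columns(train)
  stopifnot(length(feats) > 0, nrow(train) > 0)
  x <- as.matrix(train[, feats, drop = FALSE])
  y <- factor(train$tremor_level)
  fit <- switch(spec$name,
    bagged_trees = withr::with_seed(as.integer(seed), {
      # bagging = a forest whose trees see every feature at every split
      randomForest::randomForest(x = x, y = y, ntree = spec$n_trees,
                                 mtry = ncol(x))
    }),
    knn = list(x = x, y = y, k = spec$k),
    stop("unknown classifier: ", spec$name, call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, features = feats,
                 classes = levels(y), seed = as.integer(seed)),
            class = "tremor_model")
}

#' @export
predict.tremor_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  # both predictors break ties via the RNG; pin it to the model seed
  pred <- withr::with_seed(object$seed, switch(object$spec$name,
    bagged_trees = stats::predict(object$fit, x),
    knn = class::knn(object$fit$x, x, object$fit$y, k = object$fit$k)
  ))
  factor(as.character(pred), levels = object$classes)
}

#' Confusion matrix of a model on a test set
#'
#' @param model A [train_classifier()] fit.
#' @param test Test dataset with `tremor_level` labels.
#' @return A square integer matrix (rows = true class, columns = predicted),
#'   class `confusion_matrix`; the total equals the number of test rows.
#' @export
evaluate <- function(model, test) {
  # classes the model never saw in training still occupy a (zero-prediction)
  # row, so the matrix total always equals the test size
  classes <- sort(union(model$classes, unique(as.character(test$tremor_level))))
  truth <- factor(as.character(test$tremor_level), levels = classes)
  pred <- factor(as.character(stats::predict(model, test)), levels = classes)
  cm <- unclass(table(true = truth, predicted = pred))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest precision, sensitivity and specificity per class, plus the
#' overall accuracy. Undefined ratios (0/0, e.g. sensitivity of a class
#' absent from the test set) are reported as `NaN`, never silently 0.
#'
#' @param cm A [evaluate()] confusion matrix.
#' @return A tidy tibble with columns `metric`, `class` (`NA` for accuracy)
#'   and `value`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  dplyr::bind_rows(
    tibble::tibble(metric = "accuracy", class = NA_character_,
                   value = unname(sum(tp) / total)),
    tibble::tibble(metric = "precision", class = classes,
                   value = unname(tp / (tp + fp))),
    tibble::tibble(metric = "sensitivity", class = classes,
                   value = unname(tp / (tp + fn))),
    tibble::tibble(metric = "specificity", class = classes,
                   value = unname(tn / (tn + fp)))
  )
}

#' Repeated balance/split/train/evaluate cycles
#'
#' The reference evaluation protocol: for each repetition the dataset is
#' re-balanced by undersampling, split 70/30, a fresh classifier is trained
#' and its confusion-matrix metrics recorded; metrics are then summarized as
#' min/mean/max across repetitions. All per-repetition values are retained
#' for audit. Repetition seeds are derived from `seed`, so the whole summary
#' is reproducible.
#'
#' @param ds A feature dataset.
#' @param spec A classifier specification.
#' @param reps Number of repetitions (the reference protocol uses 30).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Master integer seed.
#' @param per_class Undersampling target, see [balance_classes()].
#' @param grouping Split grouping, see [split_train_test()].
#' @return A `metrics_summary`: list with `per_rep` and `summary` tibbles.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(seed = 1)
#' ds <- assemble_dataset(coh, features = c("contrast", "homogeneity"), N = 149)
#' repeat_evaluation(ds, bagged_trees(), reps = 3, seed = 1)
#' }
#' @export
repeat_evaluation <- function(ds, spec, reps = 30, train_fraction = 0.7,
                              seed = 1, per_class = "min",
                              grouping = c("window", "recording")) {
  grouping <- match.arg(grouping)
  stopifnot(reps >= 1)
  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    rs <- derive_seed(seed, "rep", r)
    b <- balance_classes(ds, per_class = per_class, seed = derive_seed(rs, "balance"))
    sp <- split_train_test(b, train_fraction = train_fraction,
                           seed = derive_seed(rs, "split"), grouping = grouping)
    model <- train_classifier(sp$train, spec, seed = derive_seed(rs, "train"))
    cm <- evaluate(model, sp$test)
    dplyr::mutate(classification_metrics(cm), rep = r, .before = 1)
  })
  summary <- per_rep |>
    dplyr::group_by(.data$metric, .data$class) |>
    dplyr::summarise(min = min(.data$value), mean = mean(.data$value),
                     max = max(.data$value), .groups = "drop")
  structure(list(per_rep = per_rep, summary = summary, spec = spec,
                 params = list(reps = reps, train_fraction = train_fraction,
                               seed = as.integer(seed), per_class = per_class,
                               grouping = grouping)),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary> %s, %d repetition(s), %d%%/%d%% split\n",
              x$spec$name, x$params$reps,
              round(100 * x$params$train_fraction),
              round(100 * (1 - x$params$train_fraction))))
  print(x$summary, n = Inf)
  invisible(x)
}
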