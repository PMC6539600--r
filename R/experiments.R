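#' Default window-size grid
#'
#' The reference sweep evaluates 250 window sizes spanning 3 to 501: the odd
#' integers 3, 5, ..., 501 (the unique uniform grid with that count and
#' range).
#'
#' @return An integer vector of length 250.
#' @examples
#' g <- default_window_grid()
#' length(g); range(g)
#' @export
default_window_grid <- function() seq(3L, 501L, by = 2L)

#' Coordinate-selection experiment
#'
#' Compares classification accuracy of SDH features extracted from each palm
#' coordinate alone - Cp(x), Cp(y), Cp(z) - and from the three jointly,
#' Cp(x, y, z), at a fixed window size (125 in the reference protocol), for
#' every registered classifier. All nine features are used per channel. The
#' per-coordinate mean accuracy across classifiers identifies the coordinate
#' worth keeping (the lateral axis, along which the push task moves).
#'
#' @param cohort A cohort tibble.
#' @param window_size Window size N (default 125).
#' @param classifiers Named list of classifier specs.
#' @param reps Repetitions per cell.
#' @param seed Master seed (per-cell seeds are derived, so any sub-grid
#'   reproduces the full grid's cells).
#' @param grouping Train/test split grouping (see [split_train_test()]).
#'   Defaults to `"recording"` here: with maximally overlapping windows a
#'   row-level split lets any coordinate - even one carrying no tremor at
#'   all - be classified by near-duplicate windows leaking across the split,
#'   which would mask the between-coordinate comparison this experiment is
#'   for.
#' @inheritParams sdh_features
#' @return A `sweep_result` tibble: one row per (coordinate set, classifier)
#'   with min/mean/max accuracy, plus attribute `coordinate_means`.
#' @export
coordinate_selection <- function(cohort, window_size = 125,
                                 classifiers = list(bagged_trees = bagged_trees(),
                                                    knn = nearest_neighbor()),
                                 reps = 3, seed = 1, M = 1, stride = 1,
                                 bin_width = 0.1,
                                 grouping = c("recording", "window")) {
  grouping <- match.arg(grouping)
  sets <- list("Cp(x)" = "palm_pos_x", "Cp(y)" = "palm_pos_y",
               "Cp(z)" = "palm_pos_z", "Cp(x,y,z)" = palm_channels())
  grid <- tidyr::expand_grid(coordinate_set = names(sets),
                             classifier = names(classifiers))
  cells <- purrr::pmap_dfr(grid, function(coordinate_set, classifier) {
    ds <- assemble_dataset(cohort, channels = sets[[coordinate_set]],
                           M = M, N = window_size, stride = stride,
                           bin_width = bin_width)
    res <- repeat_evaluation(ds, classifiers[[classifier]], reps = reps,
                             seed = derive_seed(seed, "coordsel", coordinate_set,
                                                classifier),
                             grouping = grouping)
    acc <- dplyr::filter(res$summary, .data$metric == "accuracy")
    tibble::tibble(coordinate_set = coordinate_set, classifier = classifier,
                   window_size = window_size,
                   min = acc$min, mean = acc$mean, max = acc$max)
  })
  means <- cells |>
    dplyr::group_by(.data$coordinate_set) |>
    dplyr::summarise(mean_accuracy = mean(.data$mean), .groups = "drop")
  new_sweep_result(cells, kind = "coordinate_selection", seed = seed,
                   extra = list(coordinate_means = means))
}

#' Per-feature accuracy sweep
#'
#' Evaluates each texture feature on its own - one single-feature dataset per
#' feature, per window size, per classifier - to identify the features that
#' carry the tremor-severity signal. In the reference analysis contrast and
#' homogeneity emerge on top at large windows.
#'
#' @param cohort A cohort tibble.
#' @param grid Integer vector of window sizes (default [default_window_grid()];
#'   pass a reduced grid for interactive use).
#' @param features Features to sweep (default all nine).
#' @param classifiers Named list of classifier specs.
#' @param reps Repetitions per cell.
#' @param seed Master seed.
#' @param grouping Train/test split grouping; `"recording"` by default so
#'   that the per-feature ranking reflects information that generalizes
#'   across recordings rather than window-overlap leakage (see
#'   [coordinate_selection()]).
#' @inheritParams sdh_features
#' @return A `sweep_result` tibble: one row per (window size, feature,
#'   classifier) with min/mean/max accuracy; attribute `top_features` ranks
#'   features by mean accuracy at the largest window.
#' @export
feature_sweep <- function(cohort, grid = default_window_grid(),
                          features = sdh_feature_names,
                          classifiers = list(bagged_trees = bagged_trees(),
                                             knn = nearest_neighbor()),
                          reps = 3, seed = 1, M = 1, stride = 1,
                          bin_width = 0.1,
                          grouping = c("recording", "window")) {
  grouping <- match.arg(grouping)
  stopifnot(length(grid) > 0)
  cells <- purrr::map_dfr(grid, function(N) {
    ds_all <- assemble_dataset(cohort, M = M, N = N, stride = stride,
                               bin_width = bin_width)
    purrr::map_dfr(features, function(feat) {
      ds <- ds_all[, c("recording_id", "tremor_level", "window", feat)]
      purrr::map_dfr(names(classifiers), function(cl) {
        res <- repeat_evaluation(ds, classifiers[[cl]], reps = reps,
                                 seed = derive_seed(seed, "featsweep", N, feat, cl),
                                 grouping = grouping)
        acc <- dplyr::filter(res$summary, .data$metric == "accuracy")
        tibble::tibble(window_size = N, feature = feat, classifier = cl,
                       min = acc$min, mean = acc$mean, max = acc$max)
      })
    })
  })
  top <- cells |>
    dplyr::filter(.data$window_size == max(.data$window_size)) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_accuracy = mean(.data$mean), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy))
  new_sweep_result(cells, kind = "feature_sweep", seed = seed,
                   extra = list(top_features = top))
}

#' Window-size sweep with the full metric battery
#'
#' The final-stage evaluation: for each window size and each requested
#' feature set, repeated balance/split/train/evaluate cycles with the bagged
#' tree classifier (by default), summarizing accuracy and per-class
#' precision, sensitivity and specificity as min/mean/max across repetitions.
#'
#' @param cohort A cohort tibble.
#' @param feature_sets Named list of feature-name vectors; defaults to
#'   contrast alone, homogeneity alone, and the two combined.
#' @param classifier A classifier spec (default [bagged_trees()]).
#' @param grid Integer window sizes.
#' @param reps Repetitions per cell (the reference protocol uses 30).
#' @param seed Master seed.
#' @inheritParams sdh_features
#' @inheritParams repeat_evaluation
#' @return A `sweep_result` tibble: one row per (window size, feature set,
#'   metric, class) with min/mean/max.
#' @export
window_sweep <- function(cohort,
                         feature_sets = list(contrast = "contrast",
                                             homogeneity = "homogeneity"),
                         classifier = bagged_trees(),
                         grid = c(149L, 299L, 449L), reps = 30, seed = 1,
                         M = 1, stride = 1, bin_width = 0.1,
                         grouping = c("window", "recording")) {
  grouping <- match.arg(grouping)
  stopifnot(length(grid) > 0)
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- vapply(feature_sets, paste, character(1), collapse = "+")
  }
  cells <- purrr::map_dfr(grid, function(N) {
    ds_all <- assemble_dataset(cohort, M = M, N = N, stride = stride,
                               bin_width = bin_width)
    purrr::map_dfr(names(feature_sets), function(fs) {
      ds <- ds_all[, c("recording_id", "tremor_level", "window",
                       feature_sets[[fs]])]
      res <- repeat_evaluation(ds, classifier, reps = reps,
                               seed = derive_seed(seed, "winsweep", N, fs,
                                                  classifier$name),
                               grouping = grouping)
      dplyr::mutate(res$summary, window_size = N, feature_set = fs, .before = 1)
    })
  })
  new_sweep_result(cells, kind = "window_sweep", seed = seed)
}

#' Focal-window report of a window sweep
#'
#' Reshapes a [window_sweep()] result into the reference report layout: one
#' row per (metric, feature set, class), with min/mean/max columns nested
#' under each requested focal window size (149, 299 and 449 - the first
#' three quartiles of the sweep range - in the reference analysis).
#'
#' @param sweep A `sweep_result` from [window_sweep()].
#' @param focal_sizes Window sizes to report.
#' @return A wide tibble with columns `metric`, `feature_set`, `class` and
#'   `ws<N>_min/mean/max` per focal size.
#' @export
focal_window_report <- function(sweep, focal_sizes = c(149L, 299L, 449L)) {
  stopifnot(all(focal_sizes %in% sweep$window_size))
  sweep |>
    dplyr::filter(.data$window_size %in% focal_sizes) |>
    tidyr::pivot_wider(names_from = "window_size",
                       values_from = c("min", "mean", "max"),
                       names_glue = "ws{window_size}_{.value}") |>
    dplyr::arrange(factor(.data$metric, levels = c("accuracy", "precision",
                                                   "sensitivity", "specificity")),
                   .data$feature_set, .data$class)
}

new_sweep_result <- function(cells, kind, seed, extra = list()) {
  out <- tibble::as_tibble(cells)
  class(out) <- c("sweep_result", class(out))
  attr(out, "kind") <- kind
  attr(out, "master_seed") <- as.integer(seed)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s> master seed %d\n", attr(x, "kind"),
              attr(x, "master_seed")))
  NextMethod()
}
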