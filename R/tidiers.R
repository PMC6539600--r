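#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a repeated-evaluation summary
#'
#' `tidy()` returns the per-repetition metric values (columns `rep`,
#' `metric`, `class`, `value`); `glance()` returns a one-row overview of the
#' overall accuracy across repetitions.
#'
#' @param x A `metrics_summary` from [repeat_evaluation()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.metrics_summary <- function(x, ...) x$per_rep

#' @rdname tidy.metrics_summary
#' @export
glance.metrics_summary <- function(x, ...) {
  acc <- dplyr::filter(x$summary, .data$metric == "accuracy")
  tibble::tibble(classifier = x$spec$name, reps = x$params$reps,
                 train_fraction = x$params$train_fraction,
                 accuracy_min = acc$min, accuracy_mean = acc$mean,
                 accuracy_max = acc$max)
}

#' @rdname tidy.metrics_summary
#' @export
tidy.confusion_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(as.table(unclass(x)),
                                         stringsAsFactors = FALSE))
  names(out) <- c("true", "predicted", "n")
  out$n <- as.integer(out$n)
  out
}
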