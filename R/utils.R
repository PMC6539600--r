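#' Derive a reproducible child seed from a master seed
#'
#' Stable string hash (31-multiplier rolling hash over the key components,
#' modulo 2^31 - 2) mixed with the master seed. Used throughout the package
#' so that every cell of an experiment grid, and every repetition within a
#' cell, gets a seed that depends only on the master seed and the cell's
#' identity - never on evaluation order. Evaluating a sub-grid therefore
#' reproduces exactly the corresponding cells of the full grid.
#'
#' @param master Integer master seed.
#' @param ... Key components (coerced to character) identifying the consumer.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)),
               collapse = "|")
  m <- 2147483646 # 2^31 - 2; doubles hold (h * 31 + c) exactly below 2^53
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
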