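#' Quantize a real-valued signal to integer levels
#'
#' Sum-and-difference histograms are defined on discrete levels, so positions
#' (mm) are mapped to integers by scale-and-round:
#' `level = round((x - offset) / bin_width)` with `offset` the signal minimum.
#' The default 0.1 mm bin preserves the tracker's sub-millimetre resolution
#' while keeping histogram supports small. De-quantization
#' (`offset + level * bin_width`) reproduces the input to within
#' `bin_width / 2`.
#'
#' @param x Non-empty finite numeric vector (mm).
#' @param bin_width Quantization step in mm; must be positive.
#' @return A `quantized_signal`: list of `levels` (integer), `offset`,
#'   `bin_width`.
#' @examples
#' quantize(c(0, 2.5, 5), bin_width = 2.5)$levels # 0 1 2
#' @export
quantize <- function(x, bin_width = 0.1) {
  if (length(x) == 0) stop("signal is empty", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a single positive number", call. = FALSE)
  }
  offset <- min(x)
  structure(list(levels = as.integer(round((x - offset) / bin_width)),
                 offset = offset, bin_width = bin_width),
            class = "quantized_signal")
}

#' @rdname quantize
#' @param q A `quantized_signal`.
#' @export
dequantize <- function(q) q$offset + q$levels * q$bin_width

#' Sum and difference vectors at a fixed displacement
#'
#' For a quantized series `V(1..n)` and displacement `M` (samples), pairs
#' each point with its `M`-th predecessor: `VS(l) = V(l) + V(l-M)` and
#' `VD(l) = V(l) - V(l-M)` for `l = M+1 .. n`, giving vectors of length
#' `n - M`. The whole recording's vectors are computed once and windowed
#' afterwards. The displacement is fixed at 1 (the previous sample) in the
#' reference pipeline.
#'
#' @param q A [quantize()]d signal, or an integer vector of levels.
#' @param M Displacement in samples, `1 <= M < length`.
#' @return An `sdh_pair`: list of `sum`, `diff` (integer vectors of length
#'   `n - M`) and `displacement`.
#' @examples
#' p <- sum_diff_vectors(c(1, 2, 4, 2, 1), M = 1)
#' p$sum  # 3 6 6 3
#' p$diff # 1 2 -2 -1
#' @export
sum_diff_vectors <- function(q, M = 1) {
  v <- if (inherits(q, "quantized_signal")) q$levels else as.integer(q)
  n <- length(v)
  if (M < 1 || M >= n) stop("displacement M must satisfy 1 <= M < n", call. = FALSE)
  lead <- v[(M + 1):n]
  lag <- v[1:(n - M)]
  structure(list(sum = lead + lag, diff = lead - lag, displacement = M),
            class = "sdh_pair")
}

# Compact histogram of an integer vector: nonzero-mass values + probabilities.
count_hist <- function(v, n) {
  lo <- min(v)
  counts <- tabulate(v - lo + 1L, nbins = max(v) - lo + 1L)
  nz <- counts > 0L
  list(values = (lo:max(v))[nz], prob = counts[nz] / n)
}

#' Windowed normalized sum/difference histograms
#'
#' The analysis region is a contiguous index window of size `N` slid along
#' the sum/difference vectors in steps of `stride`. Within each window the
#' sum histogram `hS` and difference histogram `hD` count occurrences of each
#' integer value; normalization divides by `N` (the window cardinality), so
#' each histogram's masses sum to 1. The number of windows is
#' `floor((len - N) / stride) + 1`.
#'
#' @param pair An [sum_diff_vectors()] result.
#' @param N Window size (number of sum/difference values per histogram).
#' @param stride Window step in samples (default 1, maximal overlap).
#' @return A list of `sdh_histograms` objects, each with `sum_values`,
#'   `sum_prob`, `diff_values`, `diff_prob`, `window_size` and `start`
#'   (1-based index into the pair).
#' @export
window_histograms <- function(pair, N, stride = 1) {
  len <- length(pair$diff)
  if (N < 1 || N > len) {
    stop("window size N must satisfy 1 <= N <= ", len, call. = FALSE)
  }
  stopifnot(stride >= 1)
  starts <- seq.int(1L, len - N + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + N - 1L)
    hs <- count_hist(pair$sum[idx], N)
    hd <- count_hist(pair$diff[idx], N)
    structure(list(sum_values = hs$values, sum_prob = hs$prob,
                   diff_values = hd$values, diff_prob = hd$prob,
                   window_size = N, start = s),
              class = "sdh_histograms")
  })
}

#' Contrast of a difference histogram
#'
#' The second moment of the normalized difference histogram,
#' `sum_k k^2 * hD(k)`: quantifies the discontinuity of successive
#' displacements of the signal. Non-negative; zero exactly when all
#' difference mass sits at 0 (a constant window).
#'
#' @param h An `sdh_histograms` window.
#' @return A non-negative scalar (squared quantization levels).
#' @export
contrast <- function(h) {
  sum(h$diff_values^2 * h$diff_prob)
}

#' Homogeneity of a difference histogram
#'
#' Inverse-distance-weighted mass of the normalized difference histogram,
#' `sum_k hD(k) / (1 + |k|)` (default) or `sum_k hD(k) / (1 + k^2)`:
#' measures the similarity of successive displacements. Lies in (0, 1] and
#' equals 1 exactly when all mass sits at 0. The magnitude kernel is the
#' default because difference values are signed; the squared kernel is the
#' form used in the classical 2D texture literature.
#'
#' @param h An `sdh_histograms` window.
#' @param kernel `"abs"` for `1/(1+|k|)` or `"squared"` for `1/(1+k^2)`.
#' @return A scalar in (0, 1].
#' @export
homogeneity <- function(h, kernel = c("abs", "squared")) {
  kernel <- match.arg(kernel)
  k <- h$diff_values
  w <- if (kernel == "abs") 1 / (1 + abs(k)) else 1 / (1 + k^2)
  sum(w * h$diff_prob)
}

sdh_feature_names <- c("mean", "variance", "energy", "correlation", "entropy",
                       "contrast", "homogeneity", "cluster_shade",
                       "cluster_prominence")

# Core feature arithmetic on compact histograms; returns a named numeric(9).
features_from_hists <- function(jv, jp, kv, kp, kernel) {
  mu <- 0.5 * sum(jv * jp)
  cj <- jv - 2 * mu
  S <- sum(cj^2 * jp)
  D <- sum(kv^2 * kp)
  w <- if (kernel == "abs") 1 / (1 + abs(kv)) else 1 / (1 + kv^2)
  c(mean = mu,
    variance = 0.5 * (S + D),
    energy = sum(jp^2) * sum(kp^2),
    correlation = 0.5 * (S - D),
    entropy = -(sum(jp * log(jp)) + sum(kp * log(kp))),
    contrast = D,
    homogeneity = sum(w * kp),
    cluster_shade = sum(cj^3 * jp),
    cluster_prominence = sum(cj^4 * jp))
}

#' The nine SDH texture features of one window
#'
#' With `j` ranging over sum-histogram values, `k` over difference-histogram
#' values, and `mu = 1/2 sum_j j*hS(j)`:
#' mean `= mu`;
#' variance `= 1/2 (sum_j (j-2mu)^2 hS + sum_k k^2 hD)`;
#' energy `= (sum_j hS^2)(sum_k hD^2)`;
#' correlation `= 1/2 (sum_j (j-2mu)^2 hS - sum_k k^2 hD)`;
#' entropy `= -sum_j hS log hS - sum_k hD log hD` (natural log, `0 log 0 = 0`);
#' contrast and homogeneity as in [contrast()] and [homogeneity()];
#' cluster shade `= sum_j (j-2mu)^3 hS`;
#' cluster prominence `= sum_j (j-2mu)^4 hS`.
#' These imply `contrast = variance - correlation` identically.
#'
#' @param h An `sdh_histograms` window.
#' @param kernel Homogeneity kernel, see [homogeneity()].
#' @return A one-row tibble with the nine feature columns.
#' @export
texture_features <- function(h, kernel = c("abs", "squared")) {
  kernel <- match.arg(kernel)
  f <- features_from_hists(h$sum_values, h$sum_prob, h$diff_values, h$diff_prob,
                           kernel)
  tibble::as_tibble(as.list(f))
}

# Fast path: per-window features for one channel without materializing
# histogram objects. Returns an n_windows x 9 matrix.
channel_feature_matrix <- function(x, M, N, stride, bin_width, kernel) {
  q <- quantize(x, bin_width)
  pair <- sum_diff_vectors(q, M)
  len <- length(pair$diff)
  if (N > len) {
    stop("recording too short: need at least N + M = ", N + M,
         " samples for one window", call. = FALSE)
  }
  starts <- seq.int(1L, len - N + 1L, by = stride)
  out <- matrix(NA_real_, length(starts), 9,
                dimnames = list(NULL, sdh_feature_names))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + N - 1L)
    hs <- count_hist(pair$sum[idx], N)
    hd <- count_hist(pair$diff[idx], N)
    out[i, ] <- features_from_hists(hs$values, hs$prob, hd$values, hd$prob,
                                    kernel)
  }
  out
}

#' Windowed SDH features of a recording
#'
#' The full extraction pipeline for one recording: extract channel ->
#' quantize -> sum/difference vectors -> sliding normalized histograms ->
#' nine texture features, applied per channel. For a channel set the
#' per-channel features are concatenated column-wise into one row per window
#' (columns `<channel>_<feature>`); for a single channel the bare feature
#' names are used. Row count is `floor((n - M - N) / stride) + 1`.
#'
#' @param rec A [tremor_recording()] (or any data frame with the requested
#'   channels).
#' @param channels Channel name(s); default the palm-centre x position, the
#'   coordinate the tremor analysis selects.
#' @param M Displacement in samples (default 1).
#' @param N Window size in sum/difference samples (default 149).
#' @param stride Window step (default 1).
#' @param bin_width Quantization step in mm (default 0.1).
#' @param kernel Homogeneity kernel (see [homogeneity()]).
#' @return A tibble: `window` (1-based index), `start` (index into the
#'   sum/difference vectors), then feature columns.
#' @examples
#' rec <- simulate_recording(level = 1, hand = "right", seed = 3)
#' f <- sdh_features(rec, N = 149)
#' nrow(f) # 451
#' @export
sdh_features <- function(rec, channels = "palm_pos_x", M = 1, N = 149,
                         stride = 1, bin_width = 0.1,
                         kernel = c("abs", "squared")) {
  kernel <- match.arg(kernel)
  assert_channels(channels)
  mats <- lapply(channels, function(ch) {
    m <- channel_feature_matrix(rec[[ch]], M, N, stride, bin_width, kernel)
    if (length(channels) > 1) colnames(m) <- paste(ch, colnames(m), sep = "_")
    m
  })
  m <- do.call(cbind, mats)
  nw <- nrow(m)
  dplyr::bind_cols(
    tibble::tibble(window = seq_len(nw),
                   start = seq.int(1L, by = as.integer(stride), length.out = nw)),
    tibble::as_tibble(m)
  )
}

#' Write a feature table with a parameter sidecar
#'
#' Writes the feature tibble as CSV and, when the jsonlite package is
#' available, a `<path>.json` sidecar recording the extraction parameters
#' (`M`, `N`, `stride`, `bin_width`, `kernel`, entropy log base).
#'
#' @param features A tibble from [sdh_features()].
#' @param path Output CSV path.
#' @param params Named list of extraction parameters to record.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, params = list()) {
  readr::write_csv(features, path, progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    params$log_base <- params$log_base %||% "natural"
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE)
  }
  message(sprintf("wrote %d feature rows to %s", nrow(features), path))
  invisible(path)
}
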