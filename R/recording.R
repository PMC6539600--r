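#' Construct a tremor recording
#'
#' A recording is one hand's capture: a tibble of samples in the 40-channel
#' schema (see [lmc_channels()]) carrying recording-level metadata as
#' attributes - patient id, hand, clinician-assigned tremor level (MDS-UPDRS
#' 0-2) and the sampling rate. The nominal protocol is 40 samples/s for 15 s,
#' i.e. 600 samples per hand.
#'
#' @param samples A data frame with exactly the 40 schema channels, all
#'   numeric and finite.
#' @param patient_id Opaque patient identifier.
#' @param hand `"left"` or `"right"`.
#' @param tremor_level Integer severity label (0, 1 or 2 after outlier
#'   exclusion; higher levels are storable so that exclusion logic can see
#'   them, but are flagged downstream).
#' @param sample_rate Samples per second; must be positive.
#' @return A `tremor_recording`: a tibble of samples with metadata attributes.
#' @examples
#' rec <- simulate_recording(level = 1, hand = "right", seed = 1)
#' rec
#' n_samples(rec)
#' @export
tremor_recording <- function(samples, patient_id = "unknown",
                             hand = c("right", "left"),
                             tremor_level = NA_integer_,
                             sample_rate = 40) {
  hand <- match.arg(hand)
  samples <- tibble::as_tibble(samples)
  schema <- lmc_channels()
  missing <- setdiff(schema, names(samples))
  extra <- setdiff(names(samples), schema)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("capture schema mismatch",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(samples) == 0) stop("empty recording", call. = FALSE)
  samples <- samples[, schema] # canonical column order
  not_num <- names(samples)[!vapply(samples, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric channel(s): ", paste(not_num, collapse = ", "), call. = FALSE)
  }
  if (!all(vapply(samples, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite values in capture channels", call. = FALSE)
  }
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1, sample_rate > 0)
  structure(samples,
            patient_id = as.character(patient_id),
            hand = hand,
            tremor_level = as.integer(tremor_level),
            sample_rate = as.numeric(sample_rate),
            class = c("tremor_recording", class(tibble::tibble())))
}

#' @rdname tremor_recording
#' @param rec A `tremor_recording`.
#' @export
n_samples <- function(rec) nrow(rec)

#' Recording metadata accessors
#'
#' @param rec A `tremor_recording`.
#' @return The stored metadata field.
#' @export
tremor_level <- function(rec) attr(rec, "tremor_level")

#' @rdname tremor_level
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate")

#' @rdname tremor_level
#' @export
recording_id <- function(rec) {
  paste(attr(rec, "patient_id"), attr(rec, "hand"), sep = "_")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf("<tremor_recording> patient %s, %s hand, level %s, %g sps, %d samples\n",
              attr(x, "patient_id"), attr(x, "hand"),
              attr(x, "tremor_level"), attr(x, "sample_rate"), nrow(x)))
  NextMethod()
}

#' Extract one or more channels from a recording
#'
#' A pure projection: the stored samples are never modified. For a single
#' channel a numeric vector of the recording's length is returned; for a set
#' of channels (e.g. the palm triplet `Cp(x, y, z)`) a numeric matrix with
#' one column per requested channel, in the requested order.
#'
#' @param rec A `tremor_recording`.
#' @param channels One or more channel names from [lmc_channels()].
#' @return A numeric vector (one channel) or matrix (several).
#' @examples
#' rec <- simulate_recording(level = 0, hand = "right", seed = 1)
#' x <- extract_channel(rec, "palm_pos_x")
#' xyz <- extract_channel(rec, palm_channels())
#' dim(xyz)
#' @export
extract_channel <- function(rec, channels) {
  assert_channels(channels)
  if (length(channels) == 1) {
    rec[[channels]]
  } else {
    m <- as.matrix(as.data.frame(rec)[, channels, drop = FALSE])
    dimnames(m) <- list(NULL, channels)
    m
  }
}
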