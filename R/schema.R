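#' The 40-channel leap-motion capture schema
#'
#' Each capture sample holds position (mm) and velocity (mm/s) triplets for
#' the five fingertips and the palm centre, plus the hand-rotation quaternion:
#' 6 parts x 2 quantities x 3 coordinates + 4 quaternion components = 40
#' channels. Channel names are fixed strings; capture files are matched by
#' name, never by column position.
#'
#' @return A character vector of the 40 channel names, in canonical order.
#' @examples
#' lmc_channels()
#' @export
lmc_channels <- function() {
  parts <- c("thumb", "index", "middle", "ring", "little", "palm")
  pv <- as.vector(vapply(
    parts,
    function(p) paste(p, rep(c("pos", "vel"), each = 3), c("x", "y", "z"), sep = "_"),
    character(6)
  ))
  c(pv, paste("hand_rot", c("x", "y", "z", "w"), sep = "_"))
}

#' @rdname lmc_channels
#' @details `lmc_position_channels()` returns the 18 position channels;
#'   `palm_channels()` the palm-centre position triplet `Cp(x, y, z)` that the
#'   tremor analysis tracks.
#' @export
lmc_position_channels <- function() {
  grep("_pos_", lmc_channels(), value = TRUE)
}

#' @rdname lmc_channels
#' @export
palm_channels <- function() {
  paste("palm_pos", c("x", "y", "z"), sep = "_")
}

# Validate that `names` are known channels; error naming offenders.
assert_channels <- function(channels) {
  bad <- setdiff(channels, lmc_channels())
  if (length(bad) > 0) {
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(channels)
}
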