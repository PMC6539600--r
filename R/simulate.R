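#' Tremor-simulation configuration
#'
#' Parameters of the synthetic push-ball recordings. The acquisition protocol
#' is fixed by the study design: 40 samples/s for 15 s (600 samples per hand),
#' with the hand held still in the start position for 10 s before a smooth
#' 5 s push of the on-screen ball along the lateral (x) axis. Tremor is an
#' additive sinusoid in the parkinsonian action-tremor band (4-6 Hz, drawn
#' uniformly per recording) whose amplitude grows with severity level; the
#' default amplitudes put levels 0 and 1 close together (normal physiological
#' motion vs slight tremor) while level 2 is well separated, mirroring the
#' clinical difficulty ordering.
#'
#' @param sample_rate Samples per second (default 40).
#' @param duration Recording length in seconds (default 15).
#' @param hold_duration Still-hold phase before the push, seconds (default 10).
#' @param tremor_freq_range Tremor frequency band in Hz, drawn uniformly per
#'   recording (default 4-6; must be below Nyquist).
#' @param level_amplitudes Oscillation amplitude in mm for levels 0, 1, 2
#'   (default 0.2, 1.5, 4.0; must be strictly increasing).
#' @param task_excursion Lateral distance travelled by the push, mm
#'   (default 100).
#' @param noise_sd Sensor noise standard deviation, mm (default 0.05,
#'   i.e. sub-millimetre tracking accuracy).
#' @return A `tremor_config` list.
#' @export
tremor_config <- function(sample_rate = 40, duration = 15, hold_duration = 10,
                          tremor_freq_range = c(4, 6),
                          level_amplitudes = c(0.2, 1.5, 4.0),
                          task_excursion = 100, noise_sd = 0.05) {
  stopifnot(sample_rate > 0, duration > 0, hold_duration >= 0,
            hold_duration < duration,
            length(tremor_freq_range) == 2,
            tremor_freq_range[1] <= tremor_freq_range[2],
            length(level_amplitudes) == 3, noise_sd >= 0, task_excursion >= 0)
  n <- sample_rate * duration
  if (abs(n - round(n)) > 1e-9) {
    stop("sample_rate x duration must be an integer sample count", call. = FALSE)
  }
  if (any(diff(level_amplitudes) <= 0)) {
    stop("level_amplitudes must be strictly increasing with level", call. = FALSE)
  }
  if (tremor_freq_range[2] >= sample_rate / 2) {
    stop("tremor_freq_range must lie below the Nyquist frequency", call. = FALSE)
  }
  structure(list(sample_rate = sample_rate, duration = duration,
                 hold_duration = hold_duration,
                 tremor_freq_range = tremor_freq_range,
                 level_amplitudes = level_amplitudes,
                 task_excursion = task_excursion, noise_sd = noise_sd),
            class = "tremor_config")
}

# Rigid-hand fingertip offsets from the palm centre, mm (x lateral, y height,
# z toward the user). Only palm channels are analysed downstream.
finger_offsets <- list(
  thumb  = c(-35, -5, 25),
  index  = c(-20, 10, 45),
  middle = c(0, 12, 50),
  ring   = c(18, 10, 45),
  little = c(32, 5, 35)
)

# Noiseless lateral task trajectory: plateau at 0, then a smoothstep ramp to
# +/- task_excursion (sign follows the pushing hand).
task_trajectory <- function(cfg, hand) {
  n <- round(cfg$sample_rate * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  s <- (t - cfg$hold_duration) / (cfg$duration - cfg$hold_duration)
  s <- pmin(pmax(s, 0), 1)
  sign <- if (hand == "right") 1 else -1
  sign * cfg$task_excursion * (3 * s^2 - 2 * s^3)
}

#' Simulate one hand recording with a controlled tremor level
#'
#' The palm-centre x channel carries the signal of interest: the noiseless
#' push-task trajectory plus an additive tremor sinusoid
#' `A_level * sin(2*pi*f*t + phi)` (frequency and phase drawn per recording)
#' plus Gaussian sensor noise. Palm y and z carry only baseline position and
#' sensor noise - the tremor is injected on the lateral axis alone. Fingertip
#' channels are the palm channels plus fixed rigid-hand offsets; velocity
#' channels are the sampled first differences times the sample rate (first
#' sample 0); the hand-rotation quaternion is the unit identity. Deterministic
#' given `(level, hand, cfg, seed)`.
#'
#' @param level Tremor severity 0, 1 or 2.
#' @param hand `"right"` or `"left"` (sets the push direction).
#' @param cfg A [tremor_config()].
#' @param seed Integer seed.
#' @param patient_id Identifier stamped on the recording.
#' @return A [tremor_recording()] of `sample_rate * duration` samples.
#' @examples
#' rec <- simulate_recording(level = 2, hand = "right", seed = 42)
#' n_samples(rec) # 600
#' @export
simulate_recording <- function(level, hand = c("right", "left"),
                               cfg = tremor_config(), seed = 1,
                               patient_id = "sim") {
  hand <- match.arg(hand)
  if (!level %in% 0:2) stop("tremor level must be 0, 1 or 2", call. = FALSE)
  n <- round(cfg$sample_rate * cfg$duration)
  base <- task_trajectory(cfg, hand)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  samples <- withr::with_seed(as.integer(seed), {
    f <- stats::runif(1, cfg$tremor_freq_range[1], cfg$tremor_freq_range[2])
    phi <- stats::runif(1, 0, 2 * pi)
    amp <- cfg$level_amplitudes[level + 1]
    noise <- function() stats::rnorm(n, 0, cfg$noise_sd)
    palm <- list(
      x = base + amp * sin(2 * pi * f * t + phi) + noise(),
      y = 150 + noise(),  # hover height above the sensor
      z = noise()         # depth toward the user
    )
    out <- list()
    for (part in c("thumb", "index", "middle", "ring", "little", "palm")) {
      off <- if (part == "palm") c(0, 0, 0) else finger_offsets[[part]]
      for (i in 1:3) {
        ax <- c("x", "y", "z")[i]
        pos <- palm[[ax]] + off[i]
        out[[paste(part, "pos", ax, sep = "_")]] <- pos
        out[[paste(part, "vel", ax, sep = "_")]] <- c(0, cfg$sample_rate * diff(pos))
      }
    }
    out[["hand_rot_x"]] <- rep(0, n)
    out[["hand_rot_y"]] <- rep(0, n)
    out[["hand_rot_z"]] <- rep(0, n)
    out[["hand_rot_w"]] <- rep(1, n)
    tibble::as_tibble(out)
  })
  tremor_recording(samples, patient_id = patient_id, hand = hand,
                   tremor_level = level, sample_rate = cfg$sample_rate)
}

#' Default cohort composition
#'
#' Per-level/per-hand recording counts of the retained study cohort
#' (levels 0/1/2 contribute 22/14/3 recordings, 39 in total).
#'
#' @return A tibble with columns `tremor_level`, `hand`, `n`.
#' @export
default_composition <- function() {
  m <- apply_exclusions_quietly(reference_cohort_manifest())
  dplyr::count(m, .data$tremor_level, .data$hand, name = "n")
}

apply_exclusions_quietly <- function(x) suppressMessages(apply_exclusions(x))

#' Simulate a full cohort
#'
#' Generates one recording per manifest entry. With the default composition
#' the manifest is the retained study cohort (39 recordings across levels
#' 0/1/2 and both hands, with the published gender split). Per-recording
#' seeds are derived reproducibly from the master seed and the recording's
#' identity, so any subset of the cohort is reproducible independently.
#'
#' @param cfg A [tremor_config()].
#' @param composition Either `NULL` (the default study composition), a named
#'   numeric vector of per-level counts (e.g. `c("0" = 10, "1" = 10, "2" = 10)`,
#'   hands alternating), or a tibble with columns `tremor_level`, `hand`, `n`.
#' @param seed Master integer seed, recorded on the result.
#' @return A cohort tibble (manifest columns plus a `recording` list-column)
#'   with attribute `master_seed`.
#' @examples
#' coh <- simulate_cohort(seed = 7)
#' nrow(coh) # 39
#' @export
simulate_cohort <- function(cfg = tremor_config(), composition = NULL, seed = 1) {
  manifest <- if (is.null(composition)) {
    apply_exclusions_quietly(reference_cohort_manifest())
  } else {
    composition_manifest(composition)
  }
  if (nrow(manifest) == 0) {
    out <- new_cohort(manifest, list())
    attr(out, "master_seed") <- as.integer(seed)
    return(out)
  }
  recs <- purrr::pmap(
    manifest[, c("patient_id", "hand", "tremor_level")],
    function(patient_id, hand, tremor_level) {
      simulate_recording(tremor_level, hand = hand, cfg = cfg,
                         seed = derive_seed(seed, patient_id, hand, tremor_level),
                         patient_id = patient_id)
    }
  )
  out <- new_cohort(manifest, recs)
  attr(out, "master_seed") <- as.integer(seed)
  message(sprintf("simulated cohort of %d recordings (seed %d)", nrow(out),
                  as.integer(seed)))
  out
}

# Expand a composition request into a manifest tibble.
composition_manifest <- function(composition) {
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- tibble::tibble(
      tremor_level = rep(as.integer(names(composition)), composition),
      hand = rep_len(c("right", "left"), sum(composition))
    ) |>
      dplyr::count(.data$tremor_level, .data$hand, name = "n")
  }
  stopifnot(all(c("tremor_level", "hand", "n") %in% names(composition)),
            all(composition$n >= 0))
  rows <- tidyr::uncount(composition, .data$n)
  if (nrow(rows) == 0) {
    return(tibble::tibble(patient_id = character(), gender = character(),
                          hand = character(), tremor_level = integer(),
                          file = character()))
  }
  tibble::tibble(
    patient_id = sprintf("S%03d", seq_len(nrow(rows))),
    gender = NA_character_,
    hand = rows$hand,
    tremor_level = as.integer(rows$tremor_level),
    file = NA_character_
  )
}
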