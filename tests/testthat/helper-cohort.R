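# Small, fast synthetic material for unit tests.

tiny_cfg <- function(...) {
  tremor_config(duration = 5, hold_duration = 3, ...)
}

# A 6-recording cohort (2 per level, one hand each) of 200-sample recordings.
tiny_cohort <- function(seed = 11) {
  suppressMessages(simulate_cohort(
    cfg = tiny_cfg(),
    composition = tibble::tibble(tremor_level = c(0L, 0L, 1L, 1L, 2L, 2L),
                                 hand = rep(c("right", "left"), 3), n = 1L),
    seed = seed
  ))
}
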