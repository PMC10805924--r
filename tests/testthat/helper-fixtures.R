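# Reduced sampler settings used throughout the test suite.
quick_spec <- function(seed, chains = 2, tune = 250, draws = 400, ...) {
  hier_spec(chains = chains, tune = tune, draws = draws, seed = seed, ...)
}

# Hand-built toy choice dataset: one participant, `n_blocks` blocks of
# `n` trials each, all correct, constant RT, choices alternating.
toy_trials <- function(n = 10, n_blocks = 1, rt_ms = 1000) {
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(participant = 1L, block = b, block_type = "main",
               block_start = "star", trial = seq_len(n),
               cycle_pos = seq_len(n),
               phase = rep(c("P1", "T1"), length.out = n),
               n_star = 14L, n_pentagon = 0L, plateau = "star",
               choice = rep(c("star", "pentagon"), length.out = n),
               digit_star = 1L, digit_pentagon = 2L, digit_reported = 1L,
               correct = TRUE, rt_ms = rt_ms,
               stringsAsFactors = FALSE)
  }))
}

# Minimal two-item display for assignment tests.
two_item_display <- function() {
  data.frame(item = 1:2, grid_row = c(0L, 0L), grid_col = c(0L, 1L),
             role = c("target", "distractor"),
             shape = c("star", "pentagon"), variant = c(6L, 174L),
             color = c("blue", "black"), digit = c(1L, 5L),
             x_px = c(100, 300), y_px = c(100, 100),
             stringsAsFactors = FALSE)
}
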