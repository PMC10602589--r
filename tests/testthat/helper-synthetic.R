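# Shared fixtures, built in code at test time.

# Simulate the accumulator over several fresh blocks and score it; returns
# parallel lists of realised blocks and scorings for kernel estimation.
agent_runs <- function(condition, n_blocks, params, seed = 1) {
  blocks <- vector("list", n_blocks)
  scorings <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    blk <- generate_block(condition, seed = seed + i)
    sim <- simulate_ou_block(blk, params, seed = seed + 1000L + i)
    blocks[[i]] <- sim$block
    scorings[[i]] <- score_responses(sim$block, sim$responses)
  }
  list(blocks = blocks, scorings = scorings)
}

# A short handcrafted block: deterministic schedule and piecewise-constant
# coherence set directly, for scoring and regressor arithmetic tests.
handmade_block <- function(coherence_by_interval, interval_len_s,
                           schedule, fs_hz = 100,
                           cfg = task_config()) {
  duration_s <- sum(interval_len_s)
  onsets <- cumsum(c(0, interval_len_s[-length(interval_len_s)]))
  n <- round(duration_s * fs_hz)
  samp <- seq_len(n) - 1L
  iv_of_samp <- findInterval(samp, round(onsets * fs_hz))
  series <- coherence_by_interval[iv_of_samp]
  p_idx <- findInterval(onsets, schedule$onset_s)
  period_of_samp <- findInterval(samp, round(schedule$onset_s * fs_hz))
  structure(list(
    condition = rdk_condition("short", "frequent"),
    cfg = cfg, fs_hz = fs_hz, duration_s = duration_s, n_samples = n,
    coherence = series, period_index = period_of_samp,
    intervals = data.frame(onset_s = onsets, duration_s = interval_len_s,
                           coherence = coherence_by_interval,
                           period_kind = schedule$kind[p_idx],
                           period_mean = ifelse(schedule$kind[p_idx] == "response",
                                                schedule$mean_coherence[p_idx], 0)),
    schedule = schedule, seed = 0L
  ), class = "stimulus_block")
}

# Build a period_schedule data.frame directly.
make_schedule <- function(kind, onset_s, nominal_duration_s, mean_coherence,
                          duration_s = NULL) {
  if (is.null(duration_s)) {
    duration_s <- onset_s[length(onset_s)] + nominal_duration_s[length(onset_s)]
  }
  sched <- data.frame(kind = kind, onset_s = onset_s,
                      nominal_duration_s = nominal_duration_s,
                      mean_coherence = mean_coherence,
                      actual_end_s = pmin(onset_s + nominal_duration_s,
                                          duration_s),
                      stringsAsFactors = FALSE)
  class(sched) <- c("period_schedule", "data.frame")
  attr(sched, "duration_s") <- duration_s
  sched
}
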