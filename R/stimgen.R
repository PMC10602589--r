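#' Task configuration for the continuous random-dot-motion paradigm
#'
#' Bundles the reward rule and noise-process parameters of the continuous
#' motion-detection task. Defaults follow the task as run: +3 points for a
#' correct buttonpress, -3 for an incorrect direction, -1.5 for a missed
#' response period or a false alarm; a press within 0.5 s of a response
#' period's nominal end still counts as correct. The experimenter-controlled
#' noise resamples the coherence on average every 270 ms (exponential
#' inter-sample intervals truncated to 10--1000 ms by rejection), with
#' Gaussian coherence samples of SD 0.5 during baseline and 0.3 during
#' response periods.
#'
#' @param reward_correct Points awarded for a correct response.
#' @param penalty_incorrect Points for an incorrect-direction response
#'   (must be <= 0).
#' @param penalty_miss Points for an unanswered response period (<= 0).
#' @param penalty_false_alarm Points for a press during baseline (<= 0).
#' @param response_tolerance_s Grace window after a response period's nominal
#'   end during which a press is still attributed to it, seconds.
#' @param sd_baseline Coherence SD during baseline periods.
#' @param sd_response Coherence SD during response periods.
#' @param isi_mean_s Mean of the exponential interval-duration distribution,
#'   seconds (before truncation).
#' @param isi_min_s,isi_max_s Truncation bounds on interval durations, seconds.
#' @return An object of class `task_config`.
#' @export
task_config <- function(reward_correct = 3,
                        penalty_incorrect = -3,
                        penalty_miss = -1.5,
                        penalty_false_alarm = -1.5,
                        response_tolerance_s = 0.5,
                        sd_baseline = 0.5,
                        sd_response = 0.3,
                        isi_mean_s = 0.270,
                        isi_min_s = 0.010,
                        isi_max_s = 1.000) {
  stopifnot(reward_correct >= 0,
            penalty_incorrect <= 0, penalty_miss <= 0,
            penalty_false_alarm <= 0,
            response_tolerance_s >= 0,
            sd_baseline >= 0, sd_response >= 0,
            isi_min_s > 0, isi_min_s < isi_mean_s, isi_mean_s < isi_max_s)
  structure(list(reward_correct = reward_correct,
                 penalty_incorrect = penalty_incorrect,
                 penalty_miss = penalty_miss,
                 penalty_false_alarm = penalty_false_alarm,
                 response_tolerance_s = response_tolerance_s,
                 sd_baseline = sd_baseline,
                 sd_response = sd_response,
                 isi_mean_s = isi_mean_s,
                 isi_min_s = isi_min_s,
                 isi_max_s = isi_max_s),
            class = "task_config")
}

#' Task environment condition
#'
#' The task crosses response-period length with response-period frequency in
#' a 2 x 2 design: LONG (5 s) vs SHORT (3 s) response periods, and RARE
#' (baseline durations uniform on 5--40 s) vs FREQUENT (3--8 s) scheduling.
#'
#' @param length_class `"long"` or `"short"`.
#' @param frequency_class `"rare"` or `"frequent"`.
#' @return An object of class `rdk_condition` with fields `length_class`,
#'   `frequency_class`, `response_period_s` and `baseline_range_s`.
#' @export
#' @examples
#' rdk_condition("long", "rare")
rdk_condition <- function(length_class = c("long", "short"),
                          frequency_class = c("rare", "frequent")) {
  length_class <- match.arg(length_class)
  frequency_class <- match.arg(frequency_class)
  structure(list(
    length_class = length_class,
    frequency_class = frequency_class,
    response_period_s = if (length_class == "long") 5.0 else 3.0,
    baseline_range_s = if (frequency_class == "rare") c(5, 40) else c(3, 8)
  ), class = "rdk_condition")
}

#' All four task conditions
#'
#' @return A named list of the four `rdk_condition` objects
#'   (`long_rare`, `long_frequent`, `short_rare`, `short_frequent`).
#' @export
all_conditions <- function() {
  out <- list()
  for (l in c("long", "short")) {
    for (f in c("rare", "frequent")) {
      out[[paste(l, f, sep = "_")]] <- rdk_condition(l, f)
    }
  }
  out
}

#' @export
print.rdk_condition <- function(x, ...) {
  cat(sprintf("<rdk_condition> %s/%s: response periods %.0f s, baselines U[%g, %g] s\n",
              toupper(x$length_class), toupper(x$frequency_class),
              x$response_period_s, x$baseline_range_s[1], x$baseline_range_s[2]))
  invisible(x)
}

# Deterministic sub-seed derivation so that schedule, interval and coherence
# draws come from independent reproducible streams (kept below 2^31).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 * 32749 + k * 104729) %% 2147483647)
}

#' Sample noise-interval durations
#'
#' Draws the durations of the piecewise-constant coherence intervals from an
#' exponential distribution (mean `isi_mean_s`) truncated to
#' `[isi_min_s, isi_max_s]` by rejection resampling (out-of-bounds draws are
#' redrawn, preserving the exponential shape within the bounds; durations are
#' never clipped to the bounds). Durations tile `total_duration_s`; the final
#' interval is clipped so the tiling is exact.
#'
#' @param total_duration_s Total duration to tile, seconds (> 0).
#' @param cfg A [task_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return Numeric vector of interval durations in seconds, summing to
#'   `total_duration_s`.
#' @export
sample_noise_intervals <- function(total_duration_s, cfg = task_config(),
                                   seed = NULL) {
  if (!is.numeric(total_duration_s) || length(total_duration_s) != 1 ||
      !is.finite(total_duration_s) || total_duration_s <= 0) {
    stop("`total_duration_s` must be a single positive number")
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- numeric(0)
  total <- 0
  while (total < total_duration_s) {
    n <- max(32L, ceiling((total_duration_s - total) / cfg$isi_mean_s * 1.5))
    d <- stats::rexp(n, rate = 1 / cfg$isi_mean_s)
    d <- d[d >= cfg$isi_min_s & d <= cfg$isi_max_s]
    draws <- c(draws, d)
    total <- total + sum(d)
  }
  cs <- cumsum(draws)
  k <- which(cs >= total_duration_s)[1]
  durations <- draws[seq_len(k)]
  durations[k] <- durations[k] - (cs[k] - total_duration_s)
  durations
}

#' Schedule baseline and response periods for one block
#'
#' Alternates baseline and response periods until the block is filled.
#' Baseline durations are uniform on the condition's baseline range; response
#' periods have the condition's nominal duration and a mean coherence drawn
#' uniformly from {-0.5, -0.4, -0.3, +0.3, +0.4, +0.5}. The final period is
#' truncated at the block end; a response period is kept only if at least one
#' sample (10 ms) of it fits.
#'
#' @param condition An [rdk_condition()].
#' @param duration_s Block duration, seconds.
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `period_schedule` with columns `kind`
#'   (`"baseline"`/`"response"`), `onset_s`, `nominal_duration_s`,
#'   `mean_coherence` and `actual_end_s`.
#' @export
schedule_periods <- function(condition, duration_s = 300, seed = NULL) {
  stopifnot(inherits(condition, "rdk_condition"))
  min_needed <- condition$baseline_range_s[1] + 0.010
  if (duration_s < min_needed) {
    stop("`duration_s` too short: need at least one baseline and one response period")
  }
  if (!is.null(seed)) set.seed(seed)
  means_set <- c(-0.5, -0.4, -0.3, 0.3, 0.4, 0.5)
  kind <- character(0); onset <- numeric(0)
  nominal <- numeric(0); mu <- numeric(0)
  t <- 0
  next_kind <- "baseline"
  while (t < duration_s) {
    if (next_kind == "baseline") {
      d <- stats::runif(1, condition$baseline_range_s[1],
                        condition$baseline_range_s[2])
      m <- 0
    } else {
      d <- condition$response_period_s
      m <- means_set[sample.int(6L, 1L)]
    }
    kind <- c(kind, next_kind); onset <- c(onset, t)
    nominal <- c(nominal, d); mu <- c(mu, m)
    t <- t + d
    next_kind <- if (next_kind == "baseline") "response" else "baseline"
  }
  # drop a trailing response period with less than one sample inside the block
  keep <- !(kind == "response" & (duration_s - onset) < 0.010)
  sched <- data.frame(kind = kind[keep], onset_s = onset[keep],
                      nominal_duration_s = nominal[keep],
                      mean_coherence = mu[keep],
                      actual_end_s = pmin(onset[keep] + nominal[keep],
                                          duration_s),
                      stringsAsFactors = FALSE)
  attr(sched, "condition") <- condition
  attr(sched, "duration_s") <- duration_s
  class(sched) <- c("period_schedule", "data.frame")
  sched
}

#' Generate one continuous stimulus block
#'
#' Produces a 5-minute (by default) coherence stream at 100 Hz: the period
#' schedule is drawn first, then interval durations, then one Gaussian
#' coherence sample per interval with mean and SD given by the period label
#' at the interval's onset (mean 0 / SD `sd_baseline` in baseline; period
#' mean / SD `sd_response` in response periods). Samples exceeding full
#' coherence are set to +1 or -1. The root `seed` is split deterministically
#' into independent sub-streams for the schedule, the interval durations and
#' the coherence draws, so identical `(condition, cfg, seed)` give
#' bit-identical blocks.
#'
#' @param condition An [rdk_condition()].
#' @param cfg A [task_config()].
#' @param seed Integer root seed.
#' @param duration_s Block duration, seconds.
#' @param fs_hz Sampling rate of the materialised per-sample series, Hz.
#' @return An object of class `stimulus_block` with fields `condition`,
#'   `cfg`, `fs_hz`, `duration_s`, `n_samples`, `coherence` (per-sample
#'   series), `period_index` (per-sample row index into `schedule`),
#'   `intervals` (one row per noise interval), `schedule` and `seed`.
#' @export
#' @examples
#' blk <- generate_block(rdk_condition("short", "frequent"), seed = 1)
#' blk
generate_block <- function(condition, cfg = task_config(), seed,
                           duration_s = 300, fs_hz = 100) {
  stopifnot(inherits(condition, "rdk_condition"), inherits(cfg, "task_config"))
  sched <- schedule_periods(condition, duration_s, seed = sub_seed(seed, 1L))
  durations <- sample_noise_intervals(duration_s, cfg, seed = sub_seed(seed, 2L))
  onsets <- cumsum(c(0, durations[-length(durations)]))

  # period label at each interval's (unquantised) onset
  p_idx <- findInterval(onsets, sched$onset_s)
  is_resp <- sched$kind[p_idx] == "response"
  mu <- ifelse(is_resp, sched$mean_coherence[p_idx], 0)
  sdv <- ifelse(is_resp, cfg$sd_response, cfg$sd_baseline)

  set.seed(sub_seed(seed, 3L))
  coh <- stats::rnorm(length(onsets), mean = mu, sd = sdv)
  coh <- pmin(pmax(coh, -1), 1)

  n <- round(duration_s * fs_hz)
  # materialise on the sample grid; interval onsets rounded to nearest sample
  start_samp <- round(onsets * fs_hz)            # 0-based sample of each onset
  samp <- seq_len(n) - 1L
  iv_of_samp <- findInterval(samp, start_samp)
  series <- coh[iv_of_samp]
  period_start_samp <- round(sched$onset_s * fs_hz)
  period_of_samp <- findInterval(samp, period_start_samp)

  structure(list(
    condition = condition,
    cfg = cfg,
    fs_hz = fs_hz,
    duration_s = duration_s,
    n_samples = n,
    coherence = series,
    period_index = period_of_samp,
    intervals = data.frame(onset_s = onsets, duration_s = durations,
                           coherence = coh,
                           period_kind = sched$kind[p_idx],
                           period_mean = mu),
    schedule = sched,
    seed = seed
  ), class = "stimulus_block")
}

#' @export
print.stimulus_block <- function(x, ...) {
  nresp <- sum(x$schedule$kind == "response")
  cat(sprintf(
    "<stimulus_block> %s/%s, %.0f s @ %g Hz (seed %d)\n  %d noise intervals, %d response periods, coherence in [%.2f, %.2f]\n",
    toupper(x$condition$length_class), toupper(x$condition$frequency_class),
    x$duration_s, x$fs_hz, x$seed, nrow(x$intervals), nresp,
    min(x$coherence), max(x$coherence)))
  invisible(x)
}

normalise_direction <- function(direction) {
  if (is.character(direction)) {
    d <- ifelse(tolower(direction) %in% c("right", "r"), 1,
                ifelse(tolower(direction) %in% c("left", "l"), -1, NA))
  } else {
    d <- sign(direction)
  }
  if (anyNA(d) || any(d == 0)) {
    stop("`direction` must be 'left'/'right' or non-zero numeric sign")
  }
  d
}

#' Score buttonpresses against a stimulus block
#'
#' Applies the task's reward rule. A press during a response period (or
#' within the tolerance window after its nominal end, if no earlier press
#' claimed the period) is scored correct when its direction matches the sign
#' of the period's mean coherence, incorrect otherwise; correct and incorrect
#' presses terminate the period immediately (its `actual_end_s` becomes the
#' press time, and the remaining scheduled time counts as baseline). All
#' other presses are false alarms. Unclaimed response periods count as
#' misses. Only the first press can claim a period; later presses during its
#' original extent fall in the post-termination baseline.
#'
#' @param block A [generate_block()] result.
#' @param responses A `data.frame` with columns `time_s` (seconds from block
#'   start, sorted increasing) and `direction` (`"left"`/`"right"` or signed
#'   numeric). May have zero rows.
#' @param cfg A [task_config()]; defaults to the block's own.
#' @return An object of class `scored_block`: a list with `scored` (one row
#'   per press: `time_s`, `direction`, `outcome`, `points`, `period_index`,
#'   `rt_s`), `misses`, `total_points`, the updated `schedule`,
#'   `baseline_time_s` (time scoreable as baseline, including
#'   post-termination remainders) and per-outcome counts.
#' @export
score_responses <- function(block, responses, cfg = block$cfg) {
  stopifnot(inherits(block, "stimulus_block"))
  if (is.null(responses) || nrow(responses) == 0) {
    responses <- data.frame(time_s = numeric(0), direction = numeric(0))
  }
  if (is.unsorted(responses$time_s)) {
    stop("`responses` must be sorted by `time_s`")
  }
  if (any(responses$time_s < 0 | responses$time_s >= block$duration_s)) {
    stop("press times must lie within [0, block duration)")
  }
  dir <- if (nrow(responses)) normalise_direction(responses$direction) else numeric(0)

  sched <- block$schedule
  claimed <- rep(FALSE, nrow(sched))
  nominal_end <- pmin(sched$onset_s + sched$nominal_duration_s, block$duration_s)
  actual_end <- nominal_end
  tol <- cfg$response_tolerance_s

  np <- nrow(responses)
  outcome <- character(np); points <- numeric(np)
  period_index <- rep(NA_integer_, np); rt <- rep(NA_real_, np)

  for (i in seq_len(np)) {
    t <- responses$time_s[i]
    inside <- which(sched$kind == "response" & !claimed &
                      sched$onset_s <= t & t < actual_end)
    if (!length(inside)) {
      # tolerance window after an unclaimed period's nominal end
      inside <- which(sched$kind == "response" & !claimed &
                        t >= nominal_end & t < nominal_end + tol)
    }
    if (length(inside)) {
      j <- inside[1]
      claimed[j] <- TRUE
      if (t < actual_end[j]) actual_end[j] <- t  # terminate early
      if (dir[i] == sign(sched$mean_coherence[j])) {
        outcome[i] <- "correct"; points[i] <- cfg$reward_correct
      } else {
        outcome[i] <- "incorrect"; points[i] <- cfg$penalty_incorrect
      }
      period_index[i] <- j
      rt[i] <- t - sched$onset_s[j]
    } else {
      outcome[i] <- "false_alarm"; points[i] <- cfg$penalty_false_alarm
    }
  }

  resp_rows <- sched$kind == "response"
  misses <- sum(resp_rows & !claimed)
  sched$actual_end_s <- actual_end
  n_correct <- sum(outcome == "correct")
  n_incorrect <- sum(outcome == "incorrect")
  n_fa <- sum(outcome == "false_alarm")
  total_points <- n_correct * cfg$reward_correct +
    n_incorrect * cfg$penalty_incorrect +
    n_fa * cfg$penalty_false_alarm +
    misses * cfg$penalty_miss
  baseline_time <- block$duration_s -
    sum(actual_end[resp_rows] - sched$onset_s[resp_rows])

  structure(list(
    scored = data.frame(time_s = responses$time_s, direction = dir,
                        outcome = outcome, points = points,
                        period_index = period_index, rt_s = rt,
                        stringsAsFactors = FALSE),
    misses = misses,
    total_points = total_points,
    schedule = sched,
    baseline_time_s = baseline_time,
    n_correct = n_correct, n_incorrect = n_incorrect,
    n_false_alarm = n_fa
  ), class = "scored_block")
}

#' @export
print.scored_block <- function(x, ...) {
  cat(sprintf(
    "<scored_block> %d correct, %d incorrect, %d false alarms, %d misses -> %.1f points\n",
    x$n_correct, x$n_incorrect, x$n_false_alarm, x$misses, x$total_points))
  invisible(x)
}

#' Write a stimulus block's interval table to delimited text
#'
#' One row per noise interval: `onset_s`, `duration_s`, `coherence`,
#' `period_kind`, `period_mean`. Condition, seed and sampling rate are stored
#' in `#`-prefixed header lines.
#'
#' @param block A [generate_block()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block_tsv <- function(block, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition: %s_%s", block$condition$length_class,
                     block$condition$frequency_class), con)
  writeLines(sprintf("# seed: %d  fs_hz: %g  duration_s: %g",
                     block$seed, block$fs_hz, block$duration_s), con)
  utils::write.table(block$intervals, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
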