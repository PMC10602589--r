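test_that("interval durations respect the truncation bounds and tile exactly", {
  cfg <- task_config()
  d <- sample_noise_intervals(300, cfg, seed = 7)
  expect_true(all(d[-length(d)] >= cfg$isi_min_s - 1e-12))
  expect_true(all(d <= cfg$isi_max_s + 1e-12))
  expect_equal(sum(d), 300)

  # degenerate tiling: a single clipped interval
  expect_equal(sample_noise_intervals(0.005, cfg, seed = 1), 0.005)
  expect_error(sample_noise_intervals(0, cfg), "positive")
})

test_that("truncated-exponential mean matches a numerical-integration oracle", {
  cfg <- task_config()
  # oracle: moments of the rejection-truncated density by numerical integration
  f <- function(t) stats::dexp(t, rate = 1 / cfg$isi_mean_s)
  Z <- stats::integrate(f, cfg$isi_min_s, cfg$isi_max_s)$value
  m1 <- stats::integrate(function(t) t * f(t), cfg$isi_min_s, cfg$isi_max_s)$value / Z
  m2 <- stats::integrate(function(t) t^2 * f(t), cfg$isi_min_s, cfg$isi_max_s)$value / Z
  sd_tr <- sqrt(m2 - m1^2)

  d <- sample_noise_intervals(1e5 * m1, cfg, seed = 11)
  d <- d[-length(d)]                     # drop the clipped tail
  se <- sd_tr / sqrt(length(d))
  expect_lt(abs(mean(d) - m1), 3 * se)
})

test_that("schedules alternate, stay in range, and match a renewal oracle", {
  cond <- rdk_condition("short", "frequent")
  sched <- schedule_periods(cond, 300, seed = 3)
  expect_true(all(rle(sched$kind)$lengths == 1))     # strict alternation
  expect_equal(sched$kind[1], "baseline")
  resp <- sched[sched$kind == "response", ]
  base <- sched[sched$kind == "baseline", ]
  expect_true(all(resp$nominal_duration_s == 3.0))
  expect_true(all(base$nominal_duration_s >= 3 & base$nominal_duration_s <= 8))
  expect_true(all(abs(resp$mean_coherence) %in% c(0.3, 0.4, 0.5)))
  # periods tile the block
  expect_equal(sched$onset_s[-1], (sched$onset_s + sched$nominal_duration_s)[-nrow(sched)])

  # minimal block still contains both period kinds
  s50 <- schedule_periods(rdk_condition("long", "rare"), 50, seed = 5)
  expect_true(all(c("baseline", "response") %in% s50$kind))
  expect_error(schedule_periods(rdk_condition("long", "rare"), 2), "short")

  # mean response-period count vs an independent renewal-process simulation
  cond_r <- rdk_condition("long", "rare")
  counts <- vapply(1:200, function(s) {
    sum(schedule_periods(cond_r, 300, seed = s)$kind == "response")
  }, numeric(1))
  set.seed(991)
  oracle_counts <- vapply(1:2000, function(i) {
    t <- 0; k <- 0
    repeat {
      t <- t + stats::runif(1, 5, 40)        # baseline
      if (t >= 300) break
      k <- k + 1                             # response period starts
      t <- t + 5
      if (t >= 300) break
    }
    k
  }, numeric(1))
  se <- sqrt(stats::var(counts) / 200 + stats::var(oracle_counts) / 2000)
  expect_lt(abs(mean(counts) - mean(oracle_counts)), 3 * se)
})

test_that("blocks are bounded, piecewise constant, dense in jumps, deterministic", {
  cond <- rdk_condition("long", "rare")
  blk <- generate_block(cond, seed = 21)
  expect_equal(blk$n_samples, 30000)
  expect_true(all(blk$coherence >= -1 & blk$coherence <= 1))

  # piecewise constancy: changes only at materialised interval boundaries
  changes <- which(diff(blk$coherence) != 0)
  starts0 <- round(blk$intervals$onset_s * blk$fs_hz)   # 0-based
  expect_true(all(changes %in% starts0))

  # every sample carries exactly one period label
  expect_true(all(blk$period_index >= 1 &
                    blk$period_index <= nrow(blk$schedule)))

  # determinism: identical inputs give bit-identical blocks
  blk2 <- generate_block(cond, seed = 21)
  expect_identical(blk$coherence, blk2$coherence)
  expect_identical(blk$intervals, blk2$intervals)

  # zero-variance baseline noise: every baseline-labelled interval (the
  # label is chosen at interval onset) carries exactly zero coherence
  cfg0 <- task_config(sd_baseline = 0)
  b0 <- generate_block(rdk_condition("short", "frequent"), cfg0, seed = 5)
  base_iv <- b0$intervals$period_kind == "baseline"
  expect_true(any(base_iv) && all(b0$intervals$coherence[base_iv] == 0))

  # jump density: >1000 intervals in at least 95 of 100 seeded blocks
  n_iv <- vapply(1:100, function(s) {
    length(sample_noise_intervals(300, task_config(), seed = s))
  }, numeric(1))
  expect_gte(mean(n_iv > 1000), 0.95)
})

test_that("noise statistics during baseline are identical across conditions", {
  # with a fixed seed, only the schedule stream differs between conditions:
  # interval durations and the coherence draws for all-baseline stretches
  # come from the same sub-streams
  b_rare <- generate_block(rdk_condition("short", "rare"), seed = 42)
  b_freq <- generate_block(rdk_condition("short", "frequent"), seed = 42)
  expect_identical(b_rare$intervals$duration_s, b_freq$intervals$duration_s)
})

test_that("scoring follows the reward rule, tolerance window and termination", {
  cfg <- task_config()
  sched <- make_schedule(
    kind = c("baseline", "response", "baseline", "response", "baseline"),
    onset_s = c(0, 5, 8, 14, 19),
    nominal_duration_s = c(5, 3, 6, 5, 6),
    mean_coherence = c(0, 0.4, 0, -0.3, 0),
    duration_s = 25)
  blk <- handmade_block(rep(0.1, 5), rep(5, 5), sched)

  # press 0.4 s after the first period's nominal end, matching direction
  res <- score_responses(blk, data.frame(time_s = 8.4, direction = "right"))
  expect_equal(res$scored$outcome, "correct")
  expect_equal(res$scored$points, 3)
  expect_equal(res$misses, 1)

  # no presses: every response period is a miss
  res0 <- score_responses(blk, NULL)
  expect_equal(res0$misses, 2)
  expect_equal(res0$total_points, -3)

  # wrong direction inside a period terminates it
  res1 <- score_responses(blk, data.frame(time_s = c(6, 7, 15),
                                          direction = c("left", "left", "left")))
  expect_equal(res1$scored$outcome, c("incorrect", "false_alarm", "correct"))
  expect_equal(res1$schedule$actual_end_s[2], 6)
  expect_equal(res1$total_points, -3 - 1.5 + 3)
  expect_equal(res1$scored$rt_s[3], 1)

  expect_error(score_responses(blk, data.frame(time_s = c(7, 6),
                                               direction = c("left", "left"))),
               "sorted")
})

test_that("scoring agrees with a brute-force oracle and conserves points", {
  # independent oracle: interval-membership scoring written from scratch
  oracle_score <- function(sched, times, dirs, dur, cfg) {
    claimed <- rep(FALSE, nrow(sched))
    a_end <- pmin(sched$onset_s + sched$nominal_duration_s, dur)
    nom_end <- a_end
    out <- character(length(times))
    for (i in seq_along(times)) {
      t <- times[i]; hit <- NA
      for (j in seq_len(nrow(sched))) {
        if (sched$kind[j] != "response" || claimed[j]) next
        if ((sched$onset_s[j] <= t && t < a_end[j]) ||
            (t >= nom_end[j] && t < nom_end[j] + cfg$response_tolerance_s)) {
          hit <- j; break
        }
      }
      if (is.na(hit)) {
        out[i] <- "false_alarm"
      } else {
        claimed[hit] <- TRUE
        if (t < a_end[hit]) a_end[hit] <- t
        out[i] <- if (dirs[i] == sign(sched$mean_coherence[hit]))
          "correct" else "incorrect"
      }
    }
    list(outcomes = out,
         misses = sum(sched$kind == "response" & !claimed))
  }

  cfg <- task_config()
  blk <- generate_block(rdk_condition("short", "frequent"), seed = 8)
  set.seed(52)
  for (rep in 1:50) {
    k <- sample(0:12, 1)
    times <- sort(stats::runif(k, 0, blk$duration_s - 1e-6))
    dirs <- sample(c(-1, 1), k, replace = TRUE)
    res <- score_responses(blk, data.frame(time_s = times, direction = dirs))
    orc <- oracle_score(blk$schedule, times, dirs, blk$duration_s, cfg)
    expect_identical(res$scored$outcome, orc$outcomes)
    expect_identical(res$misses, orc$misses)
    # conservation identity
    expect_equal(res$total_points,
                 3 * res$n_correct - 3 * res$n_incorrect -
                   1.5 * (res$n_false_alarm + res$misses))
  }
})
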