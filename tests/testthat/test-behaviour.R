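all_baseline_block <- function(coh, interval_len_s, duration_s = NULL,
                               cfg = task_config()) {
  if (is.null(duration_s)) duration_s <- sum(interval_len_s)
  sched <- make_schedule("baseline", 0, duration_s, 0, duration_s)
  handmade_block(coh, interval_len_s, sched, cfg = cfg)
}

test_that("detection summary matches trivial cases and a recount oracle", {
  # perfect detection: every response period answered correctly in window
  sched <- make_schedule(
    kind = c("baseline", "response", "baseline", "response", "baseline"),
    onset_s = c(0, 5, 8, 14, 17),
    nominal_duration_s = c(5, 3, 6, 3, 5),
    mean_coherence = c(0, 0.4, 0, -0.4, 0), duration_s = 22)
  blk <- handmade_block(rep(0, 5), c(5, 3, 6, 3, 5), sched)
  sc <- score_responses(blk, data.frame(time_s = c(6, 15),
                                        direction = c("right", "left")))
  ds <- detection_summary(list(blk), list(sc))
  cell <- ds$by_coherence[ds$by_coherence$coherence == 0.4, ]
  expect_equal(cell$detection_rate, 1)
  expect_equal(cell$median_rt_s, 1)
  # no periods at other coherences: flagged absent, not zero
  expect_true(all(is.na(
    ds$by_coherence$detection_rate[ds$by_coherence$coherence != 0.4])))

  # zero presses anywhere: false-alarm rate is exactly 0
  sc0 <- score_responses(blk, NULL)
  ds0 <- detection_summary(list(blk), list(sc0))
  expect_equal(ds0$false_alarms$false_alarm_rate, 0)

  # random outcomes vs an independent recount over the scored tables
  runs <- agent_runs(rdk_condition("short", "frequent"), 3,
                     ou_params(-0.002, 60), seed = 31)
  ds1 <- detection_summary(runs$blocks, runs$scorings,
                           runs = seq_along(runs$blocks))
  for (lev in c(0.3, 0.4, 0.5)) {
    rates <- vapply(seq_along(runs$blocks), function(i) {
      sch <- runs$scorings[[i]]$schedule
      rp <- which(sch$kind == "response" &
                    abs(abs(sch$mean_coherence) - lev) < 1e-9)
      if (!length(rp)) return(NA_real_)
      hit <- runs$scorings[[i]]$scored
      mean(rp %in% hit$period_index[hit$outcome == "correct"])
    }, numeric(1))
    got <- ds1$by_coherence$detection_rate[ds1$by_coherence$coherence == lev]
    expect_equal(got, mean(rates, na.rm = TRUE))
  }
  n_fa <- sum(vapply(runs$scorings, function(s) s$n_false_alarm, numeric(1)))
  t_bl <- sum(vapply(runs$scorings, function(s) s$baseline_time_s, numeric(1)))
  expect_equal(ds1$false_alarms$false_alarm_rate, n_fa / t_bl)
})

test_that("integration kernels reproduce constant, sign-flip and slicing cases", {
  cfg <- task_config()
  blk <- all_baseline_block(c(0.4, 0.4), c(6, 4))
  sc <- score_responses(blk, data.frame(time_s = 7, direction = "right"))
  k <- compute_integration_kernel(list(blk), list(sc), "false_alarm")
  expect_equal(length(k$lags_s), 501)
  expect_true(all(k$mean_evidence == 0.4))

  # leftward press preceded by -0.4: sign flip makes the kernel +0.4
  blkL <- all_baseline_block(c(-0.4, -0.4), c(6, 4))
  scL <- score_responses(blkL, data.frame(time_s = 7, direction = "left"))
  kL <- compute_integration_kernel(list(blkL), list(scL), "false_alarm")
  expect_true(all(kL$mean_evidence == 0.4))

  # single press on an arbitrary stream equals the direct 501-sample slice
  blk2 <- generate_block(rdk_condition("short", "rare"), seed = 77)
  base <- blk2$schedule[blk2$schedule$kind == "baseline" &
                          blk2$schedule$onset_s > 6, ]
  t_press <- base$onset_s[1] + base$nominal_duration_s[1] / 2
  sc2 <- score_responses(blk2, data.frame(time_s = t_press, direction = "left"))
  stopifnot(sc2$scored$outcome[1] == "false_alarm")
  k2 <- compute_integration_kernel(list(blk2), list(sc2), "false_alarm")
  idx <- floor(t_press * 100) + 1
  expect_equal(k2$mean_evidence, -blk2$coherence[(idx - 500):idx])

  # presses earlier than the window are excluded; none eligible -> error
  sc3 <- score_responses(blk2, data.frame(time_s = 2, direction = "left"))
  expect_error(compute_integration_kernel(list(blk2), list(sc3), "false_alarm"),
               "no eligible")
})

test_that("kernel averaging is linear and sign-equivariant", {
  blk <- generate_block(rdk_condition("short", "rare"), seed = 5)
  # pick press times in the middle of long baseline periods, past the window
  base <- blk$schedule[blk$schedule$kind == "baseline", ]
  base <- base[base$onset_s > 6 & base$nominal_duration_s > 2, ]
  times <- sort(base$onset_s[1:3] + base$nominal_duration_s[1:3] / 2)
  dirs <- c("right", "left", "right")
  sc_all <- score_responses(blk, data.frame(time_s = times, direction = dirs))
  fa <- which(sc_all$scored$outcome == "false_alarm")
  stopifnot(length(fa) >= 2)
  k_all <- compute_integration_kernel(list(blk), list(sc_all), "false_alarm")

  per_event <- lapply(fa, function(i) {
    sci <- sc_all
    sci$scored <- sci$scored[i, , drop = FALSE]
    compute_integration_kernel(list(blk), list(sci), "false_alarm")$mean_evidence
  })
  expect_equal(k_all$mean_evidence, Reduce(`+`, per_event) / length(per_event))

  # flipping all coherences and all press directions leaves the kernel fixed
  blk_f <- blk
  blk_f$coherence <- -blk$coherence
  blk_f$intervals$coherence <- -blk$intervals$coherence
  blk_f$schedule$mean_coherence <- -blk$schedule$mean_coherence
  dirs_f <- ifelse(dirs == "right", "left", "right")
  sc_f <- score_responses(blk_f, data.frame(time_s = times, direction = dirs_f))
  k_f <- compute_integration_kernel(list(blk_f), list(sc_f), "false_alarm")
  expect_equal(k_f$mean_evidence, k_all$mean_evidence)
})

test_that("exponential fit recovers noiseless parameters and flags degeneracy", {
  dt <- 0.01
  tt <- seq(5, 0, by = -dt)                 # seconds before the peak
  k <- 0.5 * exp(-tt / 1.0)
  fit <- fit_exponential_kernel(k, dt_s = dt)
  expect_lt(abs(fit$A - 0.5) / 0.5, 0.02)   # regularisation-induced bias only
  expect_lt(abs(fit$tau_s - 1.0), 0.02)
  expect_gt(fit$r_squared, 0.99)
  expect_false(fit$degenerate)

  # constant kernel: tau diverges, flagged, no R^2 above 1
  fitc <- fit_exponential_kernel(rep(0.3, 501), dt_s = dt)
  expect_true(fitc$degenerate)
  expect_false(isTRUE(fitc$r_squared > 1))

  expect_error(fit_exponential_kernel(c(0.1, NA, 0.3)), "non-finite")
})

test_that("fit matches a dense grid-search oracle on noisy synthetic kernels", {
  dt <- 0.01
  nl <- 501
  reg <- 0.01
  set.seed(404)
  rel_err <- numeric(25)
  for (i in 1:25) {
    A0 <- stats::runif(1, 0.2, 0.6)
    tau0 <- stats::runif(1, 0.3, 2)
    tt_full <- seq((nl - 1) * dt, 0, by = -dt)
    k <- A0 * exp(-tt_full / tau0) + stats::rnorm(nl, 0, 0.02)
    fit <- fit_exponential_kernel(k, dt_s = dt)

    # oracle: dense 2-D grid over (A, tau) of the same penalised objective,
    # using the same peak/fitted-range rule
    peak <- max(which(k == max(k)))
    kf <- k[seq_len(peak)]
    tt <- (peak - seq_len(peak)) * dt
    A_grid <- seq(0.05, 0.9, by = 0.005)
    tau_grid <- seq(0.05, 3, by = 0.01)
    best <- c(Inf, NA, NA)
    for (tau in tau_grid) {
      e <- exp(-tt / tau)
      s1 <- sum(kf * e); s2 <- sum(e^2)
      obj <- sum(kf^2) - 2 * A_grid * s1 + A_grid^2 * s2 +
        reg * (A_grid^2 + tau^2)
      j <- which.min(obj)
      if (obj[j] < best[1]) best <- c(obj[j], A_grid[j], tau)
    }
    # the optimiser must do at least as well as the best grid node, and
    # land within a few cells of it (the objective is flat near the optimum)
    obj_fit <- sum((kf - fit$A * exp(-tt / fit$tau_s))^2) +
      reg * (fit$A^2 + fit$tau_s^2)
    expect_lte(obj_fit, best[1] + 1e-9)
    expect_lt(abs(fit$A - best[2]), 3 * 0.005)
    expect_lt(abs(fit$tau_s - best[3]), 3 * 0.01)
    rel_err[i] <- abs(fit$tau_s - tau0) / tau0
  }
  expect_lt(stats::median(rel_err), 0.10)
})
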