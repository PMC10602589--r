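#' Summarise detection behaviour across scored blocks
#'
#' Computes, for each condition and absolute mean-coherence level (0.3, 0.4,
#' 0.5), the correct detection rate (proportion of response periods answered
#' correctly, computed per run and then averaged over runs) and the median
#' reaction time of correct responses; and, per condition, the false-alarm
#' rate in events per second of baseline. Reaction times in LONG conditions
#' that exceed 3.5 s are excluded so that LONG and SHORT are comparable.
#'
#' @param blocks List of [generate_block()] results.
#' @param scorings Parallel list of [score_responses()] results.
#' @param runs Optional integer vector assigning each block to a run
#'   (defaults to a single run).
#' @param rt_cutoff_s Reaction-time exclusion threshold applied in LONG
#'   conditions.
#' @return An object of class `detection_summary`: list with `by_coherence`
#'   (condition x |coherence| table; cells with no response periods are `NA`)
#'   and `false_alarms` (per-condition rates).
#' @export
detection_summary <- function(blocks, scorings, runs = NULL,
                              rt_cutoff_s = 3.5) {
  stopifnot(length(blocks) >= 1, length(blocks) == length(scorings))
  if (is.null(runs)) runs <- rep(1L, length(blocks))
  stopifnot(length(runs) == length(blocks))

  per_period <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    blk <- blocks[[i]]; sc <- scorings[[i]]
    sched <- sc$schedule
    rp <- which(sched$kind == "response")
    if (!length(rp)) return(NULL)
    correct_idx <- sc$scored$period_index[sc$scored$outcome == "correct"]
    rt_by_period <- rep(NA_real_, nrow(sched))
    rt_by_period[sc$scored$period_index[sc$scored$outcome == "correct"]] <-
      sc$scored$rt_s[sc$scored$outcome == "correct"]
    data.frame(
      condition = paste(blk$condition$length_class,
                        blk$condition$frequency_class, sep = "_"),
      length_class = blk$condition$length_class,
      run = runs[i],
      coherence = abs(sched$mean_coherence[rp]),
      detected = rp %in% correct_idx,
      rt_s = rt_by_period[rp]
    )
  }))
  if (is.null(per_period)) stop("no response periods in any block")

  long_excl <- per_period$length_class == "long" &
    !is.na(per_period$rt_s) & per_period$rt_s > rt_cutoff_s
  rt_keep <- per_period$detected & !is.na(per_period$rt_s) & !long_excl

  grid <- expand.grid(condition = unique(per_period$condition),
                      coherence = c(0.3, 0.4, 0.5),
                      stringsAsFactors = FALSE)
  by_coh <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- per_period$condition == grid$condition[g] &
      abs(per_period$coherence - grid$coherence[g]) < 1e-9
    if (!any(sel)) {
      return(data.frame(condition = grid$condition[g],
                        coherence = grid$coherence[g],
                        detection_rate = NA_real_, median_rt_s = NA_real_,
                        n_periods = 0L))
    }
    # per-run rates, then average over runs
    rates <- tapply(per_period$detected[sel], per_period$run[sel], mean)
    rts <- per_period$rt_s[sel & rt_keep]
    data.frame(condition = grid$condition[g], coherence = grid$coherence[g],
               detection_rate = mean(rates),
               median_rt_s = if (length(rts)) stats::median(rts) else NA_real_,
               n_periods = sum(sel))
  }))

  fa <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    blk <- blocks[[i]]; sc <- scorings[[i]]
    data.frame(condition = paste(blk$condition$length_class,
                                 blk$condition$frequency_class, sep = "_"),
               n_fa = sc$n_false_alarm,
               baseline_time_s = sc$baseline_time_s)
  }))
  fa_rate <- do.call(rbind, lapply(split(fa, fa$condition), function(d) {
    data.frame(condition = d$condition[1], n_fa = sum(d$n_fa),
               baseline_time_s = sum(d$baseline_time_s),
               false_alarm_rate = sum(d$n_fa) / sum(d$baseline_time_s))
  }))
  rownames(fa_rate) <- NULL

  structure(list(by_coherence = by_coh, false_alarms = fa_rate,
                 rt_cutoff_s = rt_cutoff_s),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("<detection_summary>\n")
  print(x$by_coherence, row.names = FALSE)
  cat("\nFalse alarms:\n")
  print(x$false_alarms, row.names = FALSE)
  invisible(x)
}

#' Reverse-correlation integration kernel
#'
#' Averages the signed coherence stream over the `window_s` seconds
#' preceding each buttonpress of the requested class, sign-flipping the
#' stream for leftward presses so left and right responses average together.
#' Presses earlier than `window_s` into a block are excluded (no padding);
#' correct-class kernels additionally exclude LONG-condition responses with
#' reaction times above 3.5 s.
#'
#' @param blocks List of [generate_block()] results.
#' @param scorings Parallel list of [score_responses()] results.
#' @param event_class `"false_alarm"` or `"correct"`.
#' @param window_s Kernel window length, seconds.
#' @param rt_cutoff_s Reaction-time exclusion for LONG-condition correct
#'   responses.
#' @return An object of class `integration_kernel` with `lags_s` (from
#'   `-window_s` to 0 at the sample step; 501 points at defaults),
#'   `mean_evidence`, `n_events` and `event_class`.
#' @export
compute_integration_kernel <- function(blocks, scorings,
                                       event_class = c("false_alarm", "correct"),
                                       window_s = 5.0, rt_cutoff_s = 3.5) {
  event_class <- match.arg(event_class)
  stopifnot(length(blocks) == length(scorings), length(blocks) >= 1)
  fs <- blocks[[1]]$fs_hz
  nlag <- round(window_s * fs) + 1L

  acc <- numeric(nlag)
  n_events <- 0L
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]; sc <- scorings[[i]]
    ev <- sc$scored[sc$scored$outcome == event_class, , drop = FALSE]
    if (event_class == "correct" && blk$condition$length_class == "long") {
      ev <- ev[ev$rt_s <= rt_cutoff_s, , drop = FALSE]
    }
    ev <- ev[ev$time_s >= window_s, , drop = FALSE]
    if (!nrow(ev)) next
    for (j in seq_len(nrow(ev))) {
      idx <- floor(ev$time_s[j] * fs) + 1L       # sample containing the press
      slice <- blk$coherence[(idx - nlag + 1L):idx]
      acc <- acc + ev$direction[j] * slice
      n_events <- n_events + 1L
    }
  }
  if (n_events == 0L) {
    stop("no eligible ", event_class, " events for kernel estimation")
  }
  structure(list(lags_s = seq(-window_s, 0, by = 1 / fs),
                 mean_evidence = acc / n_events,
                 n_events = n_events,
                 event_class = event_class,
                 window_s = window_s, fs_hz = fs),
            class = "integration_kernel")
}

#' @export
print.integration_kernel <- function(x, ...) {
  cat(sprintf("<integration_kernel> %s, %d events, peak %.3f at lag %.2f s\n",
              x$event_class, x$n_events, max(x$mean_evidence),
              x$lags_s[which.max(x$mean_evidence)]))
  invisible(x)
}

#' Fit a regularised exponential decay to an integration kernel
#'
#' Locates the kernel peak (global argmax; ties broken toward the lag
#' closest to the response), fixes t = 0 there, and fits
#' `k(t) = A * exp(-t / tau)` to all lags up to and including the peak by
#' Nelder-Mead minimisation of the least-squares cost plus an L2 penalty
#' `reg_lambda * (A^2 + tau^2)`. Positivity of both parameters is enforced
#' by optimising on the log scale. `R^2 = 1 - RSS/TSS` is computed on the
#' fitted range without the penalty.
#'
#' @param kernel An [compute_integration_kernel()] result, or a numeric
#'   vector of kernel heights on a uniform lag grid.
#' @param reg_lambda L2 penalty weight on `A` and `tau`.
#' @param dt_s Lag step, seconds (taken from the kernel object when given).
#' @param tau_init Initial decay constant for the optimiser, seconds.
#' @return An object of class `exponential_fit`: `A`, `tau_s`, `r_squared`,
#'   `peak_lag_s`, `reg_lambda`, `converged` and `degenerate` (flagged when
#'   the optimiser failed, the kernel was constant, or `tau` diverged).
#' @export
fit_exponential_kernel <- function(kernel, reg_lambda = 0.01, dt_s = NULL,
                                   tau_init = 1.0) {
  if (inherits(kernel, "integration_kernel")) {
    k <- kernel$mean_evidence
    dt_s <- 1 / kernel$fs_hz
    lags <- kernel$lags_s
  } else {
    k <- as.numeric(kernel)
    if (is.null(dt_s)) dt_s <- 0.01
    lags <- seq(-(length(k) - 1), 0) * dt_s
  }
  if (!all(is.finite(k))) stop("kernel contains non-finite values")
  if (length(k) < 3) stop("kernel too short to fit")

  kmax <- max(k)
  peak <- max(which(k == kmax))           # tie-break toward the response
  kfit <- k[seq_len(peak)]
  tt <- (peak - seq_len(peak)) * dt_s     # seconds before the peak

  a0 <- max(kmax, 1e-3)
  obj <- function(p) {
    A <- exp(p[1]); tau <- exp(p[2])
    pred <- A * exp(-tt / tau)
    sum((kfit - pred)^2) + reg_lambda * (A^2 + tau^2)
  }
  opt <- stats::optim(c(log(a0), log(tau_init)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 5000))
  A <- exp(opt$par[1]); tau <- exp(opt$par[2])

  pred <- A * exp(-tt / tau)
  rss <- sum((kfit - pred)^2)
  tss <- sum((kfit - mean(kfit))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  degenerate <- opt$convergence != 0 || tss == 0 ||
    tau > 10 * (length(k) * dt_s)

  structure(list(A = A, tau_s = tau, r_squared = r2,
                 peak_lag_s = lags[peak], reg_lambda = reg_lambda,
                 n_fit_points = peak,
                 converged = opt$convergence == 0,
                 degenerate = degenerate),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "<exponential_fit> A = %.3f, tau = %.3f s, R^2 = %s%s\n",
    x$A, x$tau_s,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Write kernels and fits to delimited text
#'
#' @param kernel An [compute_integration_kernel()] result.
#' @param fit Optional [fit_exponential_kernel()] result for the same kernel.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(kernel, path, fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# event_class: %s  n_events: %d", kernel$event_class,
                     kernel$n_events), con)
  if (!is.null(fit)) {
    writeLines(sprintf("# fit: A=%.6g tau_s=%.6g r_squared=%.6g",
                       fit$A, fit$tau_s, fit$r_squared), con)
  }
  utils::write.table(
    data.frame(lag_s = kernel$lags_s, mean_evidence = kernel$mean_evidence),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
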