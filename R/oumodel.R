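#' Ornstein-Uhlenbeck accumulator parameters
#'
#' The leaky accumulator updates once per stimulus sample (10 ms):
#' `X[t] = (1 + lambda) * X[t-1] + g * M[t] + eps[t]`, with `M[t]` the signed
#' momentary coherence and `eps[t] ~ N(0, sigma^2)`. A response is emitted
#' whenever `|X| >= theta`, after which `X` resets to 0. `lambda` and `sigma`
#' are therefore per-10-ms quantities. With `lambda = 0` the update reduces
#' to drift-diffusion (perfect) accumulation.
#'
#' The default `noise_sigma` of 2 per step reflects internal (sensory)
#' noise well above the per-sample evidence, which is what makes detection
#' of a 30--50% coherence shift genuinely hard over seconds of integration:
#' with much smaller values the reward-optimal agent detects essentially
#' every response period without false alarms, unlike observed behaviour.
#'
#' @param leak_lambda Leak per step, in `[-1, 0]` (0 = no leak).
#' @param threshold_theta Decision threshold (> 0), accumulator units.
#' @param gain_g Gain on the momentary evidence (held constant in sweeps).
#' @param noise_sigma Per-step accumulator noise SD (>= 0).
#' @param dt_s Integration step, seconds; must match the stimulus grid.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(leak_lambda = -0.002, threshold_theta = 75,
                      gain_g = 1, noise_sigma = 2, dt_s = 0.010) {
  stopifnot(leak_lambda >= -1, leak_lambda <= 0,
            threshold_theta > 0, noise_sigma >= 0, dt_s > 0)
  structure(list(leak_lambda = leak_lambda,
                 threshold_theta = threshold_theta,
                 gain_g = gain_g, noise_sigma = noise_sigma, dt_s = dt_s),
            class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf(
    "<ou_params> lambda = %g, theta = %g, g = %g, sigma = %g, dt = %g s\n",
    x$leak_lambda, x$threshold_theta, x$gain_g, x$noise_sigma, x$dt_s))
  invisible(x)
}

#' Simulate the leaky accumulator on a stimulus block
#'
#' Runs the accumulator sample by sample over the block's coherence stream.
#' In closed-loop mode (the default, matching the task), a press that claims
#' a running response period terminates it: the remaining samples up to the
#' period's nominal end are re-drawn from the baseline noise distribution,
#' so the agent -- like a human participant -- sees the stimulus return to
#' baseline after responding. Scheduled period boundaries are left in place,
#' so the emitted presses can be scored against the realised block with
#' [score_responses()].
#'
#' @param block A [generate_block()] result.
#' @param params An [ou_params()]; `dt_s` must equal `1 / block$fs_hz`.
#' @param seed Optional integer seed for the accumulator noise and the
#'   baseline re-draws.
#' @param closed_loop Terminate claimed response periods and return the
#'   stimulus to baseline (default `TRUE`).
#' @param keep_trajectory Return the per-sample accumulator series.
#' @return An object of class `ou_sim`: `responses` (`time_s`, `direction`),
#'   `block` (the realised block, coherence possibly re-drawn after
#'   terminations), `params`, `seed`, and optionally `trajectory`.
#' @export
simulate_ou_block <- function(block, params, seed = NULL,
                              closed_loop = TRUE, keep_trajectory = FALSE) {
  stopifnot(inherits(block, "stimulus_block"), inherits(params, "ou_params"))
  if (abs(params$dt_s - 1 / block$fs_hz) > 1e-9) {
    stop("`params$dt_s` does not match the block's sample grid")
  }
  if (!is.null(seed)) set.seed(seed)

  sched <- block$schedule
  samp0 <- seq_len(block$n_samples) - 1L
  iv_of_samp <- findInterval(samp0, round(block$intervals$onset_s * block$fs_hz))
  nominal_end <- pmin(sched$onset_s + sched$nominal_duration_s, block$duration_s)

  res <- ou_simulate_cpp(block$coherence, as.integer(iv_of_samp),
                         sched$onset_s, nominal_end,
                         sched$kind == "response",
                         params$leak_lambda, params$threshold_theta,
                         params$gain_g, params$noise_sigma, params$dt_s,
                         block$cfg$response_tolerance_s,
                         block$cfg$sd_baseline,
                         closed_loop, keep_trajectory)

  realised <- block
  realised$coherence <- res$coherence

  structure(list(
    responses = data.frame(time_s = res$resp_time,
                           direction = as.numeric(res$resp_dir)),
    response_samples = res$resp_sample,
    block = realised,
    params = params,
    seed = seed,
    trajectory = if (keep_trajectory) res$trajectory else NULL
  ), class = "ou_sim")
}

#' @export
print.ou_sim <- function(x, ...) {
  cat(sprintf("<ou_sim> %d responses (lambda = %g, theta = %g)\n",
              nrow(x$responses), x$params$leak_lambda,
              x$params$threshold_theta))
  invisible(x)
}

#' Default grids for the reward-landscape search
#'
#' Log-spaced leak magnitudes spanning integration timescales of roughly
#' 0.5--20 s (plus the diffusion limit `lambda = 0`), and log-spaced
#' thresholds spanning the scale of evidence accumulated over a response
#' period. On these axes the reward landscape has an interior optimum with
#' the leak--threshold trade-off ridge.
#'
#' @return Numeric axis vector.
#' @export
default_lambda_grid <- function() {
  -c(rev(10^seq(log10(5e-4), log10(0.02), length.out = 11)), 0)
}

#' @rdname default_lambda_grid
#' @export
default_theta_grid <- function() {
  exp(seq(log(30), log(400), length.out = 12))
}

#' Reward landscape of the accumulator over (leak, threshold)
#'
#' For every cell of the `(lambda, theta)` grid, simulates the accumulator
#' on each stream, scores the emitted presses with the task reward rule
#' ([score_responses()] is the single scoring path), and records the mean
#' total points per block. Gain and noise are held constant across the grid.
#'
#' @param streams List of [generate_block()] results.
#' @param lambda_grid,theta_grid Numeric axis vectors (lambda in `[-1, 0]`,
#'   theta > 0).
#' @param params_base An [ou_params()] supplying `gain_g`, `noise_sigma`
#'   and `dt_s`.
#' @param seed Integer; per-(cell, stream) seeds are derived from it.
#' @param top_fraction Fraction of cells marked as the top-performing region.
#' @return An object of class `ou_grid`: `points` (lambda x theta matrix of
#'   mean points), `per_stream_points` (3-d array), `top_decile_mask`,
#'   `argmax` (overall `(lambda, theta)`), and `per_stream_argmax`.
#' @export
grid_search_ou <- function(streams, lambda_grid = default_lambda_grid(),
                           theta_grid = default_theta_grid(),
                           params_base = ou_params(), seed = 1,
                           top_fraction = 0.10) {
  stopifnot(length(streams) >= 1, length(lambda_grid) >= 1,
            length(theta_grid) >= 1)
  nl <- length(lambda_grid); nt <- length(theta_grid)
  ns <- length(streams)
  pts <- array(NA_real_, c(nl, nt, ns))
  cell <- 0L
  for (a in seq_len(nl)) {
    for (b in seq_len(nt)) {
      cell <- cell + 1L
      par <- ou_params(leak_lambda = lambda_grid[a],
                       threshold_theta = theta_grid[b],
                       gain_g = params_base$gain_g,
                       noise_sigma = params_base$noise_sigma,
                       dt_s = params_base$dt_s)
      for (i in seq_len(ns)) {
        sim <- simulate_ou_block(streams[[i]], par,
                                 seed = sub_seed(seed, cell * 1000L + i))
        sc <- score_responses(sim$block, sim$responses)
        pts[a, b, i] <- sc$total_points
      }
    }
  }
  mean_pts <- apply(pts, c(1, 2), mean)
  ncells <- nl * nt
  k <- max(1L, round(top_fraction * ncells))
  cutoff <- sort(mean_pts, decreasing = TRUE)[k]
  mask <- mean_pts >= cutoff
  am <- which(mean_pts == max(mean_pts), arr.ind = TRUE)[1, ]
  per_stream <- do.call(rbind, lapply(seq_len(ns), function(i) {
    m <- matrix(pts[, , i], nl, nt)
    w <- which(m == max(m), arr.ind = TRUE)
    data.frame(stream = i, lambda_star = lambda_grid[w[1, 1]],
               theta_star = theta_grid[w[1, 2]],
               points = max(m))
  }))

  structure(list(lambda_grid = lambda_grid, theta_grid = theta_grid,
                 points = mean_pts, per_stream_points = pts,
                 top_decile_mask = mask,
                 argmax = c(lambda = lambda_grid[am[1]],
                            theta = theta_grid[am[2]]),
                 per_stream_argmax = per_stream,
                 params_base = params_base, seed = seed),
            class = "ou_grid")
}

#' @export
print.ou_grid <- function(x, ...) {
  cat(sprintf(
    "<ou_grid> %d x %d cells, %d streams; best mean points %.1f at lambda = %g, theta = %g\n",
    length(x$lambda_grid), length(x$theta_grid),
    dim(x$per_stream_points)[3], max(x$points),
    x$argmax["lambda"], x$argmax["theta"]))
  invisible(x)
}

#' Model integration kernels across a parameter sweep
#'
#' Varies the threshold at fixed leak, or the leak at fixed threshold,
#' simulating the accumulator on the supplied streams; collects the model's
#' false alarms (presses during baseline), builds their reverse-correlation
#' kernel with [compute_integration_kernel()], and fits
#' [fit_exponential_kernel()]. Settings that produce fewer than `min_events`
#' false alarms are flagged as under-sampled (their fits, if any, should not
#' be interpreted).
#'
#' @param streams List of [generate_block()] results.
#' @param vary `"theta"` or `"lambda"` -- which parameter the sweep varies.
#' @param values Numeric vector of values for the varied parameter.
#' @param params_base An [ou_params()] supplying the fixed parameters.
#' @param seed Integer root seed.
#' @param min_events Minimum false-alarm count for a usable kernel.
#' @return A `data.frame` with one row per setting: `lambda`, `theta`,
#'   `n_false_alarms`, `A`, `tau_s`, `r_squared`, `undersampled`.
#' @export
model_kernel_sweep <- function(streams, vary = c("theta", "lambda"), values,
                               params_base = ou_params(), seed = 1,
                               min_events = 50) {
  vary <- match.arg(vary)
  stopifnot(length(values) >= 1, length(streams) >= 1)
  out <- vector("list", length(values))
  for (v in seq_along(values)) {
    par <- params_base
    if (vary == "theta") par$threshold_theta <- values[v]
    else par$leak_lambda <- values[v]
    blocks <- vector("list", length(streams))
    scorings <- vector("list", length(streams))
    for (i in seq_along(streams)) {
      sim <- simulate_ou_block(streams[[i]], par,
                               seed = sub_seed(seed, v * 1000L + i))
      blocks[[i]] <- sim$block
      scorings[[i]] <- score_responses(sim$block, sim$responses)
    }
    n_fa <- sum(vapply(scorings, function(s) s$n_false_alarm, numeric(1)))
    undersampled <- n_fa < min_events
    A <- tau <- r2 <- NA_real_
    if (n_fa >= 1) {
      kern <- tryCatch(
        compute_integration_kernel(blocks, scorings, "false_alarm"),
        error = function(e) NULL)
      if (!is.null(kern)) {
        fit <- fit_exponential_kernel(kern)
        A <- fit$A; tau <- fit$tau_s; r2 <- fit$r_squared
      }
    }
    out[[v]] <- data.frame(lambda = par$leak_lambda,
                           theta = par$threshold_theta,
                           n_false_alarms = n_fa, A = A, tau_s = tau,
                           r_squared = r2, undersampled = undersampled)
  }
  do.call(rbind, out)
}

#' Write a reward landscape to delimited text
#'
#' One row per grid cell: `lambda`, `theta`, `mean_points`, `in_top_decile`.
#'
#' @param grid An [grid_search_ou()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(grid, path) {
  d <- expand.grid(lambda = grid$lambda_grid, theta = grid$theta_grid)
  d$mean_points <- as.vector(grid$points)
  d$in_top_decile <- as.vector(grid$top_decile_mask)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
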