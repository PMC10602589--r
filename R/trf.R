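#' Default deconvolution regressor specification
#'
#' The 11-regressor model of the continuous task: sticks at every jump of
#' the piecewise-constant noise (`jump_event`) with parametric modulators
#' for the new absolute coherence (`jump_level`) and the absolute change
#' (`jump_abs_delta`); the continuous absolute and signed momentary evidence;
#' response-period onset sticks and their absolute-coherence modulator; and
#' correct / false-alarm buttonpress sticks, each with a signed
#' (+1 right / -1 left) twin. Evidence-derived regressors are estimated from
#' baseline periods only. Lag windows give, at 100 Hz, 251 / 301 / 851
#' columns per regressor after time expansion.
#'
#' @return A `data.frame` with columns `name`, `kind`, `pre_ms`, `post_ms`,
#'   `baseline_only` and `n_lags` (at 100 Hz).
#' @export
default_regressor_specs <- function() {
  d <- data.frame(
    name = c("jump_event", "jump_level", "jump_abs_delta",
             "cont_abs_evidence", "cont_signed_evidence",
             "bp_correct", "bp_correct_signed",
             "bp_false_alarm", "bp_false_alarm_signed",
             "resp_period_onset", "resp_period_coherence"),
    kind = c("stick", "stick_modulated", "stick_modulated",
             "continuous", "continuous",
             "stick", "stick_modulated", "stick", "stick_modulated",
             "stick", "stick_modulated"),
    pre_ms = c(1000, 1000, 1500, 1500, 1500,
               5000, 5000, 5000, 5000, 500, 500),
    post_ms = c(1500, 1500, 1500, 1500, 1500,
                3500, 3500, 3500, 3500, 8000, 8000),
    baseline_only = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  d$n_lags <- (d$pre_ms + d$post_ms) / 10 + 1
  d
}

#' Extract per-regressor event and continuous series from a block
#'
#' Builds the un-expanded regressor streams on the block's sample grid.
#' `jump_event` is 1 at each noise-interval onset; `jump_level` carries the
#' new absolute coherence and `jump_abs_delta` the absolute change from the
#' previous interval (the first interval is referenced against 0).
#' `cont_abs_evidence` / `cont_signed_evidence` track the momentary
#' coherence at every sample. Response-period onsets and scored
#' buttonpresses become sticks (with signed twins for presses). Regressors
#' marked `baseline_only` in the specification table are zeroed outside
#' baseline samples
#' (samples after an early termination count as baseline).
#'
#' @param block A [generate_block()] result.
#' @param scored Optional [score_responses()] result for the same block;
#'   without it the buttonpress series are all zero and the scheduled
#'   period ends are used for the baseline mask.
#' @param specs Regressor specification, see [default_regressor_specs()].
#' @param apply_baseline_mask Zero the `baseline_only` regressors outside
#'   baseline samples (the estimation rule; default `TRUE`). Set `FALSE` to
#'   inspect the raw event series.
#' @return An object of class `regressor_streams`: named list of numeric
#'   vectors (one per regressor) with attributes `baseline_mask`, `fs_hz`
#'   and `n_samples`.
#' @export
extract_regressor_streams <- function(block, scored = NULL,
                                      specs = default_regressor_specs(),
                                      apply_baseline_mask = TRUE) {
  stopifnot(inherits(block, "stimulus_block"))
  n <- block$n_samples
  fs <- block$fs_hz
  iv <- block$intervals

  jump_samp <- round(iv$onset_s * fs) + 1L   # 1-based sample of each jump
  keep <- jump_samp >= 1L & jump_samp <= n
  jump_samp <- jump_samp[keep]
  lvl <- abs(iv$coherence)[keep]
  delta <- abs(iv$coherence - c(0, iv$coherence[-nrow(iv)]))[keep]

  z <- numeric(n)
  streams <- list()
  streams$jump_event <- z; streams$jump_event[jump_samp] <- 1
  streams$jump_level <- z; streams$jump_level[jump_samp] <- lvl
  streams$jump_abs_delta <- z; streams$jump_abs_delta[jump_samp] <- delta
  streams$cont_abs_evidence <- abs(block$coherence)
  streams$cont_signed_evidence <- block$coherence

  sched <- if (!is.null(scored)) scored$schedule else block$schedule
  rp <- which(sched$kind == "response")
  onset_samp <- round(sched$onset_s[rp] * fs) + 1L
  ok <- onset_samp >= 1L & onset_samp <= n
  streams$resp_period_onset <- z
  streams$resp_period_onset[onset_samp[ok]] <- 1
  streams$resp_period_coherence <- z
  streams$resp_period_coherence[onset_samp[ok]] <-
    abs(sched$mean_coherence[rp][ok])

  streams$bp_correct <- z; streams$bp_correct_signed <- z
  streams$bp_false_alarm <- z; streams$bp_false_alarm_signed <- z
  if (!is.null(scored) && nrow(scored$scored)) {
    ev <- scored$scored
    ps <- floor(ev$time_s * fs) + 1L
    ps <- pmin(ps, n)
    cor_i <- ev$outcome == "correct"
    fa_i <- ev$outcome == "false_alarm"
    streams$bp_correct[ps[cor_i]] <- 1
    streams$bp_correct_signed[ps[cor_i]] <- ev$direction[cor_i]
    streams$bp_false_alarm[ps[fa_i]] <- 1
    streams$bp_false_alarm_signed[ps[fa_i]] <- ev$direction[fa_i]
  }

  # baseline mask: scheduled baseline samples plus post-termination remainders
  t_samp <- (seq_len(n) - 1) / fs
  pk <- sched$kind[block$period_index]
  mask <- pk == "baseline"
  for (j in rp) {
    sel <- block$period_index == j & t_samp >= sched$actual_end_s[j]
    mask[sel] <- TRUE
  }
  if (apply_baseline_mask) {
    for (nm in specs$name[specs$baseline_only]) {
      if (!is.null(streams[[nm]])) streams[[nm]][!mask] <- 0
    }
  }

  streams <- streams[specs$name]
  attr(streams, "baseline_mask") <- mask
  attr(streams, "fs_hz") <- fs
  attr(streams, "n_samples") <- n
  class(streams) <- "regressor_streams"
  streams
}

#' Time-expand regressor streams into a deconvolutional design matrix
#'
#' Each regressor is replicated ("staircased") at every lag from `-pre_ms`
#' to `+post_ms` in 10 ms steps: the column at lag `l >= 0` models activity
#' `l` ms after the event, so its value at row `s` is the regressor value at
#' sample `s - l` (zero-padded at the block edges; negative lags model
#' anticipatory activity). Columns are stored sparsely.
#'
#' @param streams A [extract_regressor_streams()] result, or a named list of
#'   equal-length numeric vectors.
#' @param specs Regressor specification rows matching `names(streams)`.
#' @param fs_hz Sampling rate, Hz.
#' @return An object of class `design_matrix`: `X` (a sparse
#'   `Matrix::dgCMatrix`, rows = samples), `column_index` (`regressor`,
#'   `lag_ms` per column), `specs`, `fs_hz` and `valid_rows`.
#' @export
build_design_matrix <- function(streams, specs = default_regressor_specs(),
                                fs_hz = NULL) {
  if (is.null(fs_hz)) fs_hz <- attr(streams, "fs_hz")
  if (is.null(fs_hz)) fs_hz <- 100
  nm <- names(streams)
  specs <- specs[match(nm, specs$name), , drop = FALSE]
  if (anyNA(specs$name)) stop("every stream needs a matching spec row")
  n <- length(streams[[1]])
  stopifnot(all(vapply(streams, length, integer(1)) == n))

  step_ms <- 1000 / fs_hz
  if (any(specs$pre_ms %% step_ms != 0 | specs$post_ms %% step_ms != 0)) {
    stop("lag windows must be multiples of the sample step")
  }

  ii <- list(); jj <- list(); xx <- list()
  col_reg <- character(0); col_lag <- numeric(0)
  col0 <- 0L
  for (r in seq_along(nm)) {
    x <- streams[[r]]
    nz <- which(x != 0)
    lags <- seq(-specs$pre_ms[r] / step_ms, specs$post_ms[r] / step_ms)
    for (k in seq_along(lags)) {
      rows <- nz + lags[k]
      okr <- rows >= 1L & rows <= n
      if (any(okr)) {
        ii[[length(ii) + 1L]] <- rows[okr]
        jj[[length(jj) + 1L]] <- rep.int(col0 + k, sum(okr))
        xx[[length(xx) + 1L]] <- x[nz[okr]]
      }
    }
    col_reg <- c(col_reg, rep(nm[r], length(lags)))
    col_lag <- c(col_lag, lags * step_ms)
    col0 <- col0 + length(lags)
  }
  X <- Matrix::sparseMatrix(
    i = if (length(ii)) unlist(ii) else integer(0),
    j = if (length(jj)) unlist(jj) else integer(0),
    x = if (length(xx)) unlist(xx) else numeric(0),
    dims = c(n, col0))
  structure(list(X = X,
                 column_index = data.frame(regressor = col_reg,
                                           lag_ms = col_lag,
                                           stringsAsFactors = FALSE),
                 specs = specs, fs_hz = fs_hz,
                 valid_rows = rep(TRUE, n)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d samples x %d columns (%d regressors), %.1f%% nonzero\n",
              nrow(x$X), ncol(x$X), nrow(x$specs),
              100 * Matrix::nnzero(x$X) / prod(dim(x$X))))
  invisible(x)
}

#' Estimate temporal response functions by ordinary least squares
#'
#' Per channel, solves `beta = pinv(X) %*% Y` on the valid rows. The normal
#' equations are solved by Cholesky when the design has full column rank;
#' otherwise the minimum-norm solution is returned via an eigendecomposition
#' pseudoinverse, with a warning recorded in the metadata.
#'
#' @param dm A [build_design_matrix()] result.
#' @param Y Numeric matrix (samples x channels) or vector of continuous
#'   recordings aligned with the design rows.
#' @param valid_rows Logical mask of rows to keep (artifact exclusion);
#'   defaults to the design's own mask.
#' @param channel_labels Optional channel names.
#' @return An object of class `trf_set`: `betas` (columns x channels),
#'   `column_index`, `specs`, `fs_hz`, `channel_labels`, `n_valid_rows` and
#'   `rank_deficient`.
#' @export
fit_trf <- function(dm, Y, valid_rows = NULL, channel_labels = NULL) {
  stopifnot(inherits(dm, "design_matrix"))
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(dm$X)) stop("rows of the design and `Y` must align")
  if (is.null(valid_rows)) valid_rows <- dm$valid_rows
  stopifnot(length(valid_rows) == nrow(dm$X))
  if (is.null(channel_labels)) {
    channel_labels <- colnames(Y)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(Y)))
    }
  }

  Xv <- dm$X[valid_rows, , drop = FALSE]
  Yv <- Y[valid_rows, , drop = FALSE]
  p <- ncol(Xv)
  rank_deficient <- nrow(Xv) < p
  XtX <- as.matrix(Matrix::crossprod(Xv))
  XtY <- as.matrix(Matrix::crossprod(Xv, Yv))

  betas <- NULL
  if (!rank_deficient) {
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (!is.null(ch)) {
      betas <- backsolve(ch, forwardsolve(t(ch), XtY))
    } else {
      rank_deficient <- TRUE
    }
  }
  if (is.null(betas)) {
    # minimum-norm solution through the pseudoinverse of X'X
    eg <- eigen(XtX, symmetric = TRUE)
    tol <- max(eg$values) * p * .Machine$double.eps
    pos <- eg$values > tol
    betas <- eg$vectors[, pos, drop = FALSE] %*%
      ((t(eg$vectors[, pos, drop = FALSE]) %*% XtY) / eg$values[pos])
    warning("design is rank deficient; returning the minimum-norm solution")
  }
  dimnames(betas) <- list(NULL, channel_labels)

  structure(list(betas = betas, column_index = dm$column_index,
                 specs = dm$specs, fs_hz = dm$fs_hz,
                 channel_labels = channel_labels,
                 n_valid_rows = sum(valid_rows),
                 rank_deficient = rank_deficient),
            class = "trf_set")
}

#' @export
print.trf_set <- function(x, ...) {
  cat(sprintf("<trf_set> %d regressors x %d channels (%d valid rows%s)\n",
              nrow(x$specs), length(x$channel_labels), x$n_valid_rows,
              if (x$rank_deficient) ", rank deficient" else ""))
  invisible(x)
}

#' Extract one regressor's TRF curve from a fitted set
#'
#' @param trf A [fit_trf()] result.
#' @param regressor Regressor name.
#' @param channel Channel label or index.
#' @return A `data.frame` with `lag_ms` and `beta`.
#' @export
trf_curve <- function(trf, regressor, channel = 1) {
  stopifnot(inherits(trf, "trf_set"))
  sel <- trf$column_index$regressor == regressor
  if (!any(sel)) stop("unknown regressor: ", regressor)
  data.frame(lag_ms = trf$column_index$lag_ms[sel],
             beta = trf$betas[sel, channel])
}

#' Ground-truth configuration for synthetic continuous EEG
#'
#' @param truth Named list of ground-truth TRF curves; each element must
#'   have one value per lag of the matching regressor spec.
#' @param specs Regressor specification the curves refer to.
#' @param noise `"white"` or `"ar1"`.
#' @param noise_sd Marginal noise SD per channel.
#' @param ar_coef AR(1) coefficient (used when `noise = "ar1"`).
#' @param n_channels Number of channels to synthesise.
#' @param spatial_weights Optional regressors x channels weight matrix
#'   (defaults to all ones).
#' @return An object of class `synthetic_eeg_config`.
#' @export
synthetic_eeg_config <- function(truth, specs = default_regressor_specs(),
                                 noise = c("ar1", "white"), noise_sd = 1,
                                 ar_coef = 0.9, n_channels = 1,
                                 spatial_weights = NULL) {
  noise <- match.arg(noise)
  stopifnot(is.list(truth), length(names(truth)) == length(truth),
            noise_sd >= 0, abs(ar_coef) < 1, n_channels >= 1)
  for (nm in names(truth)) {
    r <- match(nm, specs$name)
    if (is.na(r)) stop("truth curve for unknown regressor: ", nm)
    if (length(truth[[nm]]) != specs$n_lags[r]) {
      stop(sprintf("truth curve for %s must have %d lags", nm, specs$n_lags[r]))
    }
  }
  if (is.null(spatial_weights)) {
    spatial_weights <- matrix(1, length(truth), n_channels,
                              dimnames = list(names(truth), NULL))
  }
  stopifnot(nrow(spatial_weights) == length(truth),
            ncol(spatial_weights) == n_channels)
  structure(list(truth = truth, specs = specs, noise = noise,
                 noise_sd = noise_sd, ar_coef = ar_coef,
                 n_channels = n_channels,
                 spatial_weights = spatial_weights),
            class = "synthetic_eeg_config")
}

#' A triphasic TRF curve on a regressor's lag grid
#'
#' Three Gaussian lobes of alternating sign, ending on a negative lobe --
#' the shape of the centroparietal response to continuous absolute evidence.
#' Zero at negative (anticipatory) lags.
#'
#' @param pre_ms,post_ms Lag window of the target regressor.
#' @param centers_ms Lobe centres, ms post-event.
#' @param amplitudes Lobe amplitudes (signs alternate, final negative).
#' @param sd_ms Lobe width (Gaussian SD), ms.
#' @param fs_hz Sampling rate, Hz.
#' @return Numeric vector with one value per lag.
#' @export
triphasic_curve <- function(pre_ms = 1500, post_ms = 1500,
                            centers_ms = c(120, 300, 550),
                            amplitudes = c(-0.5, 1, -0.8),
                            sd_ms = 60, fs_hz = 100) {
  lag_ms <- seq(-pre_ms, post_ms, by = 1000 / fs_hz)
  y <- numeric(length(lag_ms))
  for (k in seq_along(centers_ms)) {
    y <- y + amplitudes[k] * exp(-(lag_ms - centers_ms[k])^2 / (2 * sd_ms^2))
  }
  y[lag_ms < 0] <- 0
  y
}

#' Synthesise continuous multichannel EEG with known TRFs
#'
#' Convolves each regressor stream with its ground-truth curve (direct
#' summation over lags, matching the design matrix's lag convention),
#' weights it onto channels, and adds white or AR(1) noise. The exact
#' stacked coefficient vector is returned so recovery can be checked against
#' [fit_trf()].
#'
#' @param streams A [extract_regressor_streams()] result (or named list of
#'   series) containing every regressor named in `cfg$truth`.
#' @param cfg A [synthetic_eeg_config()].
#' @param seed Optional integer seed for the noise.
#' @return A list with `Y` (samples x channels), `beta_true` (stacked in
#'   design-column order for `cfg$truth`'s regressors), `truth` and `cfg`.
#' @export
simulate_eeg <- function(streams, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_eeg_config"))
  if (!is.null(seed)) set.seed(seed)
  nm <- names(cfg$truth)
  missing_r <- setdiff(nm, names(streams))
  if (length(missing_r)) stop("streams missing: ", paste(missing_r, collapse = ", "))
  n <- length(streams[[nm[1]]])
  fs <- attr(streams, "fs_hz"); if (is.null(fs)) fs <- 100
  step_ms <- 1000 / fs

  signal <- matrix(0, n, cfg$n_channels)
  for (r in seq_along(nm)) {
    srow <- match(nm[r], cfg$specs$name)
    lags <- seq(-cfg$specs$pre_ms[srow] / step_ms,
                cfg$specs$post_ms[srow] / step_ms)
    x <- streams[[nm[r]]]
    contrib <- numeric(n)
    curve <- cfg$truth[[r]]
    for (k in seq_along(lags)) {
      if (curve[k] == 0) next
      l <- lags[k]
      src <- seq_len(n) - l
      okr <- src >= 1L & src <= n
      contrib[okr] <- contrib[okr] + curve[k] * x[src[okr]]
    }
    signal <- signal + outer(contrib, cfg$spatial_weights[r, ])
  }

  noise <- matrix(0, n, cfg$n_channels)
  if (cfg$noise_sd > 0) {
    for (ch in seq_len(cfg$n_channels)) {
      if (cfg$noise == "white") {
        noise[, ch] <- stats::rnorm(n, 0, cfg$noise_sd)
      } else {
        innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_coef^2)
        noise[, ch] <- as.numeric(stats::filter(
          stats::rnorm(n, 0, innov_sd), cfg$ar_coef,
          method = "recursive"))
      }
    }
  }
  list(Y = signal + noise, beta_true = unlist(cfg$truth, use.names = FALSE),
       truth = cfg$truth, cfg = cfg)
}

#' Pairwise collinearity of the evidence regressors
#'
#' Squared sample correlations between the un-expanded series of
#' `jump_event`, `jump_level`, `jump_abs_delta` and `cont_abs_evidence`,
#' restricted to baseline samples. Pairs of stick-type regressors are
#' compared at the event level (their values on the union of event samples);
#' pairs involving the continuous regressor are compared sample by sample
#' over the baseline. Zero-variance comparisons are returned as `NA` and
#' flagged.
#'
#' @param streams A [extract_regressor_streams()] result.
#' @param regressors Regressor names to cross (defaults to the four
#'   evidence regressors).
#' @return A symmetric matrix of squared correlations with unit diagonal;
#'   attribute `"undefined"` marks flagged entries.
#' @export
regressor_collinearity <- function(streams,
                                   regressors = c("jump_event", "jump_level",
                                                  "jump_abs_delta",
                                                  "cont_abs_evidence")) {
  mask <- attr(streams, "baseline_mask")
  if (is.null(mask)) mask <- rep(TRUE, length(streams[[1]]))
  specs <- default_regressor_specs()
  kind <- specs$kind[match(regressors, specs$name)]
  kind[is.na(kind)] <- "continuous"
  is_stick <- kind %in% c("stick", "stick_modulated")

  m <- length(regressors)
  R2 <- matrix(NA_real_, m, m, dimnames = list(regressors, regressors))
  undef <- matrix(FALSE, m, m, dimnames = list(regressors, regressors))
  diag(R2) <- 1
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      xa <- streams[[regressors[a]]][mask]
      xb <- streams[[regressors[b]]][mask]
      if (is_stick[a] && is_stick[b]) {
        ev <- which(xa != 0 | xb != 0)
        xa <- xa[ev]; xb <- xb[ev]
      }
      if (length(xa) < 3 || stats::sd(xa) == 0 || stats::sd(xb) == 0) {
        undef[a, b] <- undef[b, a] <- TRUE
      } else {
        R2[a, b] <- R2[b, a] <- stats::cor(xa, xb)^2
      }
    }
  }
  attr(R2, "undefined") <- undef
  R2
}

#' Write a fitted TRF set to delimited text
#'
#' One row per (regressor, lag, channel): `regressor`, `lag_ms`, `channel`,
#' `beta`.
#'
#' @param trf A [fit_trf()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trf_tsv <- function(trf, path) {
  d <- do.call(rbind, lapply(seq_along(trf$channel_labels), function(ch) {
    data.frame(regressor = trf$column_index$regressor,
               lag_ms = trf$column_index$lag_ms,
               channel = trf$channel_labels[ch],
               beta = trf$betas[, ch])
  }))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
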