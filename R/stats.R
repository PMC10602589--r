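#' Gaussian temporal smoothing of a beta timecourse
#'
#' Convolves a curve with a unit-area Gaussian kernel of the stated full
#' width at half maximum (SD = FWHM / (2 * sqrt(2 * ln 2)) samples), using
#' reflective edge handling so constant curves pass through unchanged.
#'
#' @param x Numeric vector (a single subject's lag or time curve).
#' @param fwhm_ms Kernel FWHM, ms (> 0).
#' @param fs_hz Sampling rate, Hz.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_timecourse <- function(x, fwhm_ms = 75, fs_hz = 100) {
  stopifnot(fwhm_ms > 0, fs_hz > 0)
  sd_samp <- fwhm_ms / 1000 * fs_hz / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sd_samp))
  kern <- stats::dnorm(seq(-half, half), sd = sd_samp)
  kern <- kern / sum(kern)
  n <- length(x)
  # reflective padding about the first and last samples
  xp <- c(x[pmin(seq(half + 1, 2), n)], x, x[pmax(seq(n - 1, n - half), 1)])
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

find_clusters <- function(tvals, threshold) {
  supra <- abs(tvals) > threshold
  if (!any(supra)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(k) {
               sum(tvals[starts[k]:ends[k]])
             }, numeric(1)))
}

paired_t_course <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(pmax(colSums(d^2) / n - m^2, 0) * n / (n - 1))
  tv <- m / (s / sqrt(n))
  tv[is.nan(tv)] <- 0          # 0/0: no difference, no evidence
  tv                           # +-Inf (constant non-zero difference) kept
}

#' Paired cluster-based permutation test on channel-averaged curves
#'
#' Computes a per-timepoint paired t statistic across subjects, forms
#' clusters from contiguous runs with `|t|` above the cluster-forming
#' threshold, and scores each by its summed t (mass). The null distribution
#' of the maximal absolute cluster mass is built by randomly sign-flipping
#' each subject's difference curve (full enumeration when `2^n` does not
#' exceed `n_perm`); the observed labelling is included in the null, so
#' p-values are bounded below by `1 / (n_perm + 1)`.
#'
#' @param cond_a,cond_b Numeric matrices, subjects x timepoints, aligned on
#'   the analysis window.
#' @param times_ms Optional timepoint labels (defaults to 10 ms steps
#'   from 0).
#' @param threshold_t Cluster-forming threshold on `|t|`.
#' @param n_perm Number of Monte Carlo permutations.
#' @param alpha Two-tailed significance level for clusters.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `cluster_result`: `clusters` (`start_ms`,
#'   `end_ms`, `mass`, `p_value`, `significant`), `threshold_t`,
#'   `n_permutations`, `alpha`, `tail` and the observed `t_course`.
#' @export
paired_cluster_permutation <- function(cond_a, cond_b, times_ms = NULL,
                                       threshold_t = 2.07, n_perm = 1000,
                                       alpha = 0.05, seed = NULL) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  stopifnot(all(dim(cond_a) == dim(cond_b)))
  n <- nrow(cond_a)
  if (n < 2) stop("need at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  nt <- ncol(cond_a)
  if (is.null(times_ms)) times_ms <- seq(0, by = 10, length.out = nt)
  if (!is.null(seed)) set.seed(seed)

  d <- cond_a - cond_b
  tobs <- paired_t_course(d)
  cl <- find_clusters(tobs, threshold_t)

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    n_eff <- nrow(signs)
  } else {
    signs <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    n_eff <- n_perm
  }

  # t-courses for all sign patterns at once: means from S %*% d, second
  # moments are flip-invariant
  m <- (signs %*% d) / n
  q <- matrix(colSums(d^2) / n, n_eff, nt, byrow = TRUE)
  s <- sqrt(pmax(q - m^2, 0) * n / (n - 1))
  tperm <- m / (s / sqrt(n))
  tperm[is.nan(tperm)] <- 0

  null_max <- vapply(seq_len(n_eff), function(p) {
    cp <- find_clusters(tperm[p, ], threshold_t)
    if (nrow(cp)) max(abs(cp$mass)) else 0
  }, numeric(1))

  if (nrow(cl)) {
    if (exhaustive) {
      pvals <- vapply(cl$mass,
                      function(ms) mean(null_max >= abs(ms)), numeric(1))
    } else {
      pvals <- vapply(cl$mass, function(ms) {
        (1 + sum(null_max >= abs(ms))) / (n_eff + 1)
      }, numeric(1))
    }
  } else {
    pvals <- numeric(0)
  }

  structure(list(
    clusters = data.frame(start_ms = times_ms[cl$start],
                          end_ms = times_ms[cl$end],
                          mass = cl$mass, p_value = pvals,
                          significant = pvals < alpha),
    threshold_t = threshold_t, n_permutations = n_eff,
    exhaustive = exhaustive, alpha = alpha, tail = "two-sided",
    t_course = tobs, times_ms = times_ms,
    null_max = null_max
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> |t| > %.2f, %d permutations%s\n",
              x$threshold_t, x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' Across-subject correlation between beta curves and a behavioural measure
#'
#' Spearman rank correlation, at each timepoint, between subjects' (already
#' smoothed) beta values and a per-subject behavioural quantity such as the
#' integration-kernel decay constant tau. The window summary correlates the
#' window-averaged betas with the behavioural values. Ties are handled by
#' average ranks; timepoints where either variable is constant across
#' subjects are returned as `NA` and flagged.
#'
#' @param beta_curves Numeric matrix, subjects x timepoints.
#' @param behav_values Numeric vector, one value per subject.
#' @param times_ms Timepoint labels, ms.
#' @param window_ms Two-element window for the summary correlation, ms.
#' @return An object of class `correlation_timecourse`: `times_ms`, `rho`,
#'   `window_ms`, `window_mean_rho`, `n_subjects` and `undefined` (logical
#'   per timepoint).
#' @export
across_subject_correlation <- function(beta_curves, behav_values,
                                       times_ms = NULL,
                                       window_ms = c(420, 750)) {
  beta_curves <- as.matrix(beta_curves)
  n <- nrow(beta_curves)
  if (n < 5) stop("need at least 5 subjects")
  stopifnot(length(behav_values) == n)
  nt <- ncol(beta_curves)
  if (is.null(times_ms)) times_ms <- seq(0, by = 10, length.out = nt)

  behav_const <- stats::sd(behav_values) == 0
  rho <- rep(NA_real_, nt)
  undefined <- rep(FALSE, nt)
  for (j in seq_len(nt)) {
    if (behav_const || stats::sd(beta_curves[, j]) == 0) {
      undefined[j] <- TRUE
    } else {
      rho[j] <- stats::cor(beta_curves[, j], behav_values,
                           method = "spearman")
    }
  }

  win <- times_ms >= window_ms[1] & times_ms <= window_ms[2]
  window_mean_rho <- NA_real_
  if (any(win) && !behav_const) {
    wavg <- rowMeans(beta_curves[, win, drop = FALSE])
    if (stats::sd(wavg) > 0) {
      window_mean_rho <- stats::cor(wavg, behav_values, method = "spearman")
    }
  }

  structure(list(times_ms = times_ms, rho = rho, window_ms = window_ms,
                 window_mean_rho = window_mean_rho, n_subjects = n,
                 undefined = undefined),
            class = "correlation_timecourse")
}

#' @export
print.correlation_timecourse <- function(x, ...) {
  cat(sprintf(
    "<correlation_timecourse> %d subjects; window %g-%g ms rho = %s\n",
    x$n_subjects, x$window_ms[1], x$window_ms[2],
    ifelse(is.na(x$window_mean_rho), "NA",
           sprintf("%.3f", x$window_mean_rho))))
  invisible(x)
}
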