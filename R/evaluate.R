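# Indicators used to assess how well a trained wavenet generalizes:
# normalized residual score, un-centered cross-correlation / cosine
# similarity, and interspike-interval statistics.

#' Normalized residual score (1 - r^2)
#'
#' \eqn{(1-r^2) = \sum_m (y_m - \hat y_m)^2 / \sum_m (y_m - \bar y)^2}
#' where \eqn{\bar y} is the mean of the reference series. Zero means a
#' perfect prediction; the score is sensitive to small time lags even when
#' every spike is correctly identified.
#'
#' @param y reference series (length >= 2, non-constant).
#' @param y_hat predicted series of the same length.
#' @return non-negative scalar (a fraction, not a percentage).
#' @export
one_minus_r2 <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("series lengths differ")
  if (length(y) < 2) stop("need at least 2 samples")
  den <- sum((y - mean(y))^2)
  if (den == 0) stop("reference series is constant; score undefined")
  sum((y - y_hat)^2) / den
}

#' Un-centered normalized cross-correlation
#'
#' \eqn{R(k) = \sum_m y_m\,\hat y_{m+k} / (\lVert y\rVert\,\lVert\hat y\rVert)}
#' for lags `k` in `-max_lag:max_lag`, with out-of-range products treated
#' as zero. The normalization is un-centered (no mean subtraction), so
#' `R(0)` equals the cosine similarity of the two series.
#'
#' @param y,y_hat equal-length series with nonzero norms.
#' @param max_lag maximum displacement in samples.
#' @param dt optional sample step (ms) used to report lags in time units.
#' @return data.frame with columns `lag` (samples), `lag_ms` (if `dt`
#'   given), `value`.
#' @export
cross_correlation <- function(y, y_hat, max_lag, dt = NULL) {
  if (length(y) != length(y_hat)) stop("series lengths differ")
  ny <- sqrt(sum(y^2)); nh <- sqrt(sum(y_hat^2))
  if (ny == 0 || nh == 0) stop("zero-norm input")
  n <- length(y)
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(k) {
    m <- seq_len(n)
    keep <- m + k >= 1 & m + k <= n
    sum(y[m[keep]] * y_hat[m[keep] + k]) / (ny * nh)
  }, numeric(1))
  out <- data.frame(lag = lags, value = vals)
  if (!is.null(dt)) out$lag_ms <- lags * dt
  out
}

#' Cosine similarity
#'
#' The cosine of the angle between the two series seen as vectors,
#' \eqn{S_C = \langle y, \hat y\rangle / (\lVert y\rVert\,\lVert\hat y\rVert)};
#' identical to the zero-lag value of [cross_correlation()]. Scale-invariant
#' but translation-sensitive.
#'
#' @param y,y_hat equal-length series with nonzero norms.
#' @export
cosine_similarity <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("series lengths differ")
  ny <- sqrt(sum(y^2)); nh <- sqrt(sum(y_hat^2))
  if (ny == 0 || nh == 0) stop("zero-norm input")
  sum(y * y_hat) / (ny * nh)
}

#' Detect spikes by threshold crossing
#'
#' Returns the times (ms) of upward threshold crossings, discarding
#' crossings closer than `min_separation` to the previous accepted spike.
#'
#' @param v voltage series.
#' @param dt sample step (ms).
#' @param threshold crossing level; default is the midpoint of the series
#'   range (a robust model-agnostic choice when the trace contains spikes).
#' @param min_separation refractory window (ms).
#' @return numeric vector of spike times (possibly empty).
#' @export
detect_spikes <- function(v, dt, threshold = NULL, min_separation = 2) {
  if (!all(is.finite(v))) stop("non-finite voltage trace")
  if (is.null(threshold)) threshold <- (max(v) + min(v)) / 2
  n <- length(v)
  if (n < 2) return(numeric())
  up <- which(v[-1] >= threshold & v[-n] < threshold)
  times <- up * dt
  if (!length(times)) return(numeric())
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= min_separation)
    keep <- c(keep, t)
  keep
}

#' Interspike intervals
#'
#' Successive differences of a sorted spike-time sequence.
#'
#' @param spike_times numeric vector of spike times (ms).
#' @return numeric vector of ISIs (length = spikes - 1).
#' @export
interspike_intervals <- function(spike_times) {
  diff(sort(spike_times))
}

#' Overlap coefficient of two ISI distributions
#'
#' Histogram overlap \eqn{\sum_b \min(h_a(b), h_b(b))} of the two samples
#' on shared bins with both histograms normalized to unit mass; 1 for
#' identical samples, 0 for disjoint supports.
#'
#' @param isi_a,isi_b non-empty ISI samples (ms).
#' @param bin_width histogram bin width (ms); default is Freedman-Diaconis
#'   on the pooled sample.
#' @return scalar in `[0, 1]`.
#' @export
isi_overlap <- function(isi_a, isi_b, bin_width = NULL) {
  if (!length(isi_a) || !length(isi_b)) stop("empty ISI sample")
  pooled <- c(isi_a, isi_b)
  if (is.null(bin_width)) {
    # Freedman-Diaconis on the pooled sample, capped so that strongly
    # separated samples are never merged into a single bin
    iqr <- stats::IQR(pooled)
    rng <- max(diff(range(pooled)), 1e-6)
    fd <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3) else rng / 10
    bin_width <- max(min(fd, rng / 10), 1e-9)
  }
  lo <- floor(min(pooled) / bin_width) * bin_width
  hi <- ceiling(max(pooled) / bin_width + 1e-9) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  ha <- graphics::hist(isi_a, breaks = breaks, plot = FALSE)$counts
  hb <- graphics::hist(isi_b, breaks = breaks, plot = FALSE)$counts
  sum(pmin(ha / sum(ha), hb / sum(hb)))
}

#' Score a prediction against reference outputs
#'
#' Computes the full indicator set over a test window: per-variable
#' (1 - r^2) score (fraction and percent) and cosine similarity, the
#' un-centered cross-correlation of the voltage variable over a lag
#' window, and the interspike-interval statistics of reference vs
#' predicted voltage (spike times, ISIs, histogram overlap). The first
#' `transient_ms` of the window are discarded before scoring.
#'
#' @param y_true,y_hat matrices (rows = steps) or vectors; column 1 is the
#'   voltage variable.
#' @param dt sample step (ms).
#' @param transient_ms initial transient to discard (ms).
#' @param max_lag_ms cross-correlation lag window (ms).
#' @param spike_threshold optional voltage threshold for spike detection;
#'   default midpoint of the reference trace (applied to both traces).
#' @param min_separation refractory window for spike detection (ms).
#' @return object of class `score_report`.
#' @export
score_prediction <- function(y_true, y_hat, dt, transient_ms = 100,
                             max_lag_ms = 20, spike_threshold = NULL,
                             min_separation = 2) {
  y_true <- as.matrix(y_true); y_hat <- as.matrix(y_hat)
  if (!all(dim(y_true) == dim(y_hat))) stop("shape mismatch")
  drop_n <- min(nrow(y_true) - 2L, as.integer(round(transient_ms / dt)))
  if (drop_n > 0) {
    y_true <- y_true[-seq_len(drop_n), , drop = FALSE]
    y_hat <- y_hat[-seq_len(drop_n), , drop = FALSE]
  }
  vars <- colnames(y_true)
  if (is.null(vars)) vars <- paste0("y", seq_len(ncol(y_true)))
  omr <- vapply(seq_along(vars), function(i)
    one_minus_r2(y_true[, i], y_hat[, i]), numeric(1))
  sc <- vapply(seq_along(vars), function(i)
    cosine_similarity(y_true[, i], y_hat[, i]), numeric(1))
  v <- y_true[, 1]; vh <- y_hat[, 1]
  thr <- if (is.null(spike_threshold)) (max(v) + min(v)) / 2
         else spike_threshold
  sp_true <- detect_spikes(v, dt, thr, min_separation)
  sp_hat <- detect_spikes(vh, dt, thr, min_separation)
  isi_true <- interspike_intervals(sp_true)
  isi_hat <- interspike_intervals(sp_hat)
  ov <- if (length(isi_true) && length(isi_hat))
    isi_overlap(isi_true, isi_hat) else NA_real_
  xc <- cross_correlation(v, vh, max_lag = as.integer(round(max_lag_ms / dt)),
                          dt = dt)
  structure(list(one_minus_r2 = stats::setNames(omr, vars),
                 one_minus_r2_pct = stats::setNames(100 * omr, vars),
                 cosine_similarity = stats::setNames(sc, vars),
                 cross_correlation = xc,
                 spike_times_true = sp_true, spike_times_pred = sp_hat,
                 isi_true = isi_true, isi_pred = isi_hat,
                 isi_overlap = ov,
                 dt = dt, transient_ms = transient_ms),
            class = "score_report")
}

#' @export
print.score_report <- function(x, digits = 4, ...) {
  cat("Score report (transient", x$transient_ms, "ms discarded)\n")
  tab <- data.frame(`one_minus_r2_pct` = signif(x$one_minus_r2_pct, digits),
                    `cosine_similarity` = signif(x$cosine_similarity, digits))
  print(tab)
  cat("spikes (true/pred):", length(x$spike_times_true), "/",
      length(x$spike_times_pred),
      " ISI overlap:", signif(x$isi_overlap, digits), "\n")
  invisible(x)
}
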