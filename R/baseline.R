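#' Baseline (F0) estimators and the dF/F0 transform
#'
#' Three conventions for the resting-fluorescence baseline F0 are provided,
#' reflecting common practice in Ca2+ imaging:
#' \describe{
#'   \item{initial}{mean of an initial window on the trace ([f0_initial]).}
#'   \item{minimal}{mean of the sliding window minimizing
#'     `sqrt(var(window) + mean(window)^2)` ([f0_minimal]); with population
#'     variance this criterion equals the window root-mean-square, so the
#'     selected segment is the quietest low-lying stretch of the trace.}
#'   \item{smooth}{a per-frame series: the 8th percentile in a centered
#'     sliding window, then moving-average smoothed with the same window
#'     ([f0_smooth]).}
#' }
#' [compute_dff()] then forms `(F - F0) / F0`.
#'
#' @name baselines
NULL

new_baseline <- function(method, f0, window, params) {
  structure(list(method = method, f0 = f0, window = window, params = params),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  if (length(x$f0) == 1L)
    cat(sprintf("F0 %s: %.6g (window [%d, %d))\n", x$method, x$f0,
                x$window[1], x$window[2]))
  else
    cat(sprintf("F0 %s: per-frame series of length %d (window length %d)\n",
                x$method, length(x$f0), x$params$window_len))
  invisible(x)
}

trace_values <- function(trace) {
  if (inherits(trace, "fluor_trace")) trace$values
  else if (inherits(trace, "synthetic_trace")) trace$values
  else as.numeric(trace)
}

#' F0 from an initial window
#'
#' @param trace numeric vector or `"fluor_trace"`.
#' @param window_len window length in frames (default 50, i.e. 2 s at 25 Hz).
#' @return A `"baseline_model"` with scalar `f0` = mean of frames
#'   `[0, window_len)` and that window recorded as the baseline segment.
#' @export
f0_initial <- function(trace, window_len = 50) {
  x <- trace_values(trace)
  if (!is_count(window_len, 1) || window_len > length(x))
    stop_calwave("calwave_invalid", "window_len must be in [1, trace length]")
  new_baseline("initial", mean(x[seq_len(window_len)]),
               c(0L, as.integer(window_len)), list(window_len = window_len))
}

# Sliding-window mean and root-mean-square via cumulative sums.
window_stats <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n - w + 1L)
  mean <- (cs[i + w] - cs[i]) / w
  m2 <- (cs2[i + w] - cs2[i]) / w
  list(mean = mean, rms = sqrt(pmax(m2, 0)))
}

#' F0 from the minimal sliding window
#'
#' Scans all windows of length `window_len` (step 1) and selects the one
#' minimizing `sqrt(var + mean^2)` (population variance; equivalently the
#' window RMS). Ties are broken by the earliest start.
#'
#' @inheritParams f0_initial
#' @param window_len window length in frames (default 250, i.e. 10 s at 25 Hz).
#' @return A `"baseline_model"` with scalar `f0` = mean of the selected
#'   window, and that window as the baseline segment.
#' @export
f0_minimal <- function(trace, window_len = 250) {
  x <- trace_values(trace)
  if (!is_count(window_len, 1) || window_len > length(x))
    stop_calwave("calwave_invalid", "window_len must be in [1, trace length]")
  st <- window_stats(x, window_len)
  best <- which.min(st$rms)  # which.min takes the first minimum: earliest start
  new_baseline("minimal", st$mean[best],
               c(best - 1L, best - 1L + as.integer(window_len)),
               list(window_len = window_len))
}

# Centered truncated-window bounds for frame t (1-based).
trunc_window <- function(t, n, half) {
  c(max(1L, t - half), min(n, t + half))
}

#' Smoothed sliding-percentile F0 series
#'
#' For each frame, takes the `percentile`-th percentile of the trace in a
#' window of length `window_len` centered on the frame (truncated at both
#' series edges), then moving-average smooths the percentile series with the
#' same truncated window. Percentiles use linear interpolation
#' (`quantile(type = 7)`). Because edge windows contain fewer points, the
#' series degrades near the ends of the trace; this edge behavior is
#' intentional and observable downstream.
#'
#' @inheritParams f0_minimal
#' @param percentile percentile in (0, 100); default 8.
#' @return A `"baseline_model"` whose `f0` is a per-frame series.
#' @export
f0_smooth <- function(trace, window_len = 250, percentile = 8) {
  x <- trace_values(trace)
  n <- length(x)
  if (!is_count(window_len, 2)) stop_calwave("calwave_invalid", "window_len must be >= 2")
  if (!(percentile > 0 && percentile < 100))
    stop_calwave("calwave_invalid", "percentile must be in (0, 100)")
  half <- as.integer(window_len %/% 2)
  p <- vapply(seq_len(n), function(t) {
    b <- trunc_window(t, n, half)
    unname(stats::quantile(x[b[1]:b[2]], percentile / 100, type = 7))
  }, numeric(1))
  # truncated-window moving average of the percentile series
  cs <- c(0, cumsum(p))
  f0 <- vapply(seq_len(n), function(t) {
    b <- trunc_window(t, n, half)
    (cs[b[2] + 1L] - cs[b[1]]) / (b[2] - b[1] + 1L)
  }, numeric(1))
  new_baseline("smooth", f0, NULL,
               list(window_len = window_len, percentile = percentile))
}

#' dF/F0 transform
#'
#' Computes `(F - F0) / F0`, broadcasting a scalar `f0`. A nonpositive
#' baseline anywhere it is applied is a loud error (bleached or degenerate
#' traces must not silently produce sign-flipped dF/F0).
#'
#' @param trace numeric vector or `"fluor_trace"`.
#' @param baseline a `"baseline_model"` from [f0_initial()], [f0_minimal()]
#'   or [f0_smooth()].
#' @return A `"dff_trace"`: list with dimensionless `values`, the
#'   `baseline`, and `roi_id` when available.
#' @export
compute_dff <- function(trace, baseline) {
  stopifnot(inherits(baseline, "baseline_model"))
  x <- trace_values(trace)
  f0 <- baseline$f0
  if (length(f0) != 1L && length(f0) != length(x))
    stop_calwave("calwave_invalid", "baseline series length does not match trace")
  bad <- which(f0 <= 0)
  if (length(bad))
    stop_calwave("calwave_degenerate_baseline",
                 "nonpositive F0 at %d frame(s) (first: frame %d)",
                 length(bad), bad[1] - 1L)
  structure(list(values = (x - f0) / f0, baseline = baseline,
                 roi_id = if (inherits(trace, "fluor_trace")) trace$roi_id else NULL),
            class = "dff_trace")
}
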