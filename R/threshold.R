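#' Thresholding criteria for dF/F0 rasterization
#'
#' Four criteria turn a dF/F0 trace into a binary activity raster. The
#' reference population is either the baseline segment (`baseline_*`) or the
#' whole trace (`trace_*`); a frame is active when its dF/F0 value exceeds
#' the reference mean by `sd_multiple` reference SDs (`*_sd`), or when its
#' one-sided upper-tail z-probability under `Normal(mu_ref, sd_ref)` is
#' below `alpha` (`*_z`, equivalent to a `qnorm(1 - alpha)`-SD threshold).
#' Ties at the threshold are inactive (strict inequality). No
#' multiple-testing correction is applied: the z criterion is a per-point
#' test, which is precisely why it admits ~`alpha` false-active frames on
#' pure noise.
#'
#' @param criterion one of `"baseline_sd"`, `"trace_sd"`, `"baseline_z"`,
#'   `"trace_z"`.
#' @param sd_multiple SD multiple for the `*_sd` criteria (default 2.5).
#' @param alpha one-sided significance level for the `*_z` criteria
#'   (default 0.05).
#' @param baseline_segment 0-based half-open frame interval `c(start, end)`
#'   supplying the reference statistics for the `baseline_*` criteria
#'   (see [default_baseline_segment()]).
#' @return A `"threshold_spec"`.
#' @export
threshold_spec <- function(criterion = c("baseline_sd", "trace_sd",
                                         "baseline_z", "trace_z"),
                           sd_multiple = 2.5, alpha = 0.05,
                           baseline_segment = NULL) {
  criterion <- match.arg(criterion)
  if (!(sd_multiple > 0)) stop_calwave("calwave_invalid", "sd_multiple must be > 0")
  if (!(alpha > 0 && alpha < 1)) stop_calwave("calwave_invalid", "alpha must be in (0, 1)")
  structure(list(criterion = criterion, sd_multiple = sd_multiple,
                 alpha = alpha, baseline_segment = baseline_segment),
            class = "threshold_spec")
}

#' Apply a thresholding criterion to a dF/F0 trace
#'
#' @param dff a `"dff_trace"` from [compute_dff()] (or a numeric dF/F0
#'   vector).
#' @param spec a [threshold_spec()]. For `baseline_*` criteria a
#'   `baseline_segment` must be present (set one with
#'   [default_baseline_segment()]).
#' @return An `"event_raster"`: list with integer 0/1 `active` series, the
#'   `method` label, and `degenerate` flag. A zero reference SD yields an
#'   all-zero raster flagged `degenerate = TRUE` with a machine-readable
#'   warning (class `calwave_degenerate_reference`) so that batch sweeps
#'   survive dead traces.
#' @export
threshold_raster <- function(dff, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  x <- if (inherits(dff, "dff_trace")) dff$values else as.numeric(dff)
  n <- length(x)
  ref <- if (spec$criterion %in% c("baseline_sd", "baseline_z")) {
    seg <- spec$baseline_segment
    if (is.null(seg) || seg[2] <= seg[1] || seg[1] < 0 || seg[2] > n)
      stop_calwave("calwave_invalid",
                   "criterion '%s' needs a valid baseline_segment inside the trace",
                   spec$criterion)
    x[(seg[1] + 1L):seg[2]]
  } else x
  mu <- mean(ref)
  sigma <- sqrt(mean((ref - mu)^2))  # population SD, as in the F0-minimal criterion
  mult <- if (spec$criterion %in% c("baseline_sd", "trace_sd"))
    spec$sd_multiple else stats::qnorm(1 - spec$alpha)
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate) {
    warn_calwave("calwave_degenerate_reference",
                 "zero-variance reference population: all-zero raster")
    active <- integer(n)
  } else {
    active <- as.integer(x > mu + mult * sigma)
  }
  structure(list(active = active, method = spec$criterion,
                 degenerate = degenerate,
                 threshold = if (degenerate) NA_real_ else mu + mult * sigma),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("Event raster (%s): %d/%d active frames%s\n", x$method,
              sum(x$active), length(x$active),
              if (isTRUE(x$degenerate)) " [degenerate reference]" else ""))
  invisible(x)
}

#' Baseline segment for the baseline-referenced criteria
#'
#' The `initial` and `minimal` baselines carry their own window, which is
#' passed through. The `smooth` baseline has no single window; by package
#' convention the segment is the window of the minimal-RMS criterion
#' (as in [f0_minimal()]) applied to the dF/F0 series itself, i.e. the
#' quietest stretch of the normalized trace.
#'
#' @param baseline the `"baseline_model"` used to build `dff`.
#' @param dff the `"dff_trace"`.
#' @param window_len window length for the smooth-baseline convention;
#'   defaults to the baseline's own window length.
#' @return 0-based half-open `c(start, end)`.
#' @export
default_baseline_segment <- function(baseline, dff, window_len = NULL) {
  stopifnot(inherits(baseline, "baseline_model"))
  if (baseline$method %in% c("initial", "minimal")) return(baseline$window)
  x <- if (inherits(dff, "dff_trace")) dff$values else as.numeric(dff)
  w <- if (is.null(window_len)) baseline$params$window_len else window_len
  w <- min(w, length(x))
  st <- window_stats(x, w)
  best <- which.min(st$rms)
  c(best - 1L, best - 1L + as.integer(w))
}
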