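#' Event detection methods
#'
#' Thirteen detectors are available under one interface: twelve dF/F0
#' methods named `"f0-{initial|minimal|smooth}-{bsd|tsd|bz|tz}"` (baseline
#' convention x thresholding criterion: `bsd`/`tsd` = 2.5 SD above the
#' baseline/trace mean, `bz`/`tz` = one-sided z-test at alpha against the
#' baseline/trace reference), and `"wavelet"`, the Morse-CWT ridgewalking
#' detector with noise-calibrated significance thresholds.
#'
#' @return `detection_methods()` returns the character vector of method ids.
#' @export
detection_methods <- function() {
  c(outer(c("f0-initial", "f0-minimal", "f0-smooth"),
          c("bsd", "tsd", "bz", "tz"), paste, sep = "-"),
    "wavelet")
}

parse_method <- function(method) {
  if (!method %in% detection_methods())
    stop_calwave("calwave_invalid", "unknown method '%s' (see detection_methods())", method)
  if (method == "wavelet") return(list(kind = "wavelet"))
  parts <- strsplit(method, "-", fixed = TRUE)[[1]]
  list(kind = "dff", baseline = parts[2],
       criterion = c(bsd = "baseline_sd", tsd = "trace_sd",
                     bz = "baseline_z", tz = "trace_z")[parts[3]])
}

#' Detect Ca2+ events in one fluorescence trace
#'
#' Runs one of the thirteen detectors (see [detection_methods()]) on a raw
#' fluorescence trace and returns the binary raster, the discrete events
#' and (optionally) their features.
#'
#' @param trace numeric vector or `"fluor_trace"` of raw fluorescence.
#' @param method method id.
#' @param window_len baseline window length; defaults to 50 frames for
#'   `f0-initial` and 250 for `f0-minimal`/`f0-smooth`.
#' @param sd_multiple,alpha thresholding parameters (dF/F0 methods).
#' @param scales,thresholds [build_scale_set()] and
#'   [calibrate_thresholds()] results (required for `"wavelet"`).
#' @param extent_mult wavelet event extent multiplier
#'   (see [events_from_ridges()]).
#' @param lookback per-event F0 lookback (wavelet pathway).
#' @param compute_features if `FALSE`, skip amplitude computation (faster
#'   for detection-performance sweeps).
#' @return A `"ca_detection"`: list with `method`, `raster`
#'   (`"event_raster"`), `events` (data.frame), and for dF/F0 methods the
#'   `baseline` and `dff` used.
#' @export
detect_events <- function(trace, method, window_len = NULL,
                          sd_multiple = 2.5, alpha = 0.05,
                          scales = NULL, thresholds = NULL, extent_mult = 1,
                          lookback = 25, compute_features = TRUE) {
  spec <- parse_method(method)
  x <- trace_values(trace)
  if (spec$kind == "wavelet") {
    if (is.null(scales) || is.null(thresholds))
      stop_calwave("calwave_invalid",
        "method 'wavelet' needs a scale set and calibrated thresholds: run build_scale_set() and calibrate_thresholds()")
    rs <- walk_ridges(find_scale_maxima(morse_cwt(x, scales)), scales,
                      keep_points = FALSE)
    sig <- filter_ridges(rs, thresholds)
    er <- events_from_ridges(sig, scales, extent_mult)
    events <- er$events
    if (compute_features && nrow(events))
      events <- event_features(events, x, "wavelet", lookback)
    return(structure(list(method = method, raster = er$raster, events = events),
                     class = "ca_detection"))
  }
  bl <- switch(spec$baseline,
    initial = f0_initial(x, if (is.null(window_len)) 50 else window_len),
    minimal = f0_minimal(x, if (is.null(window_len)) 250 else window_len),
    smooth = f0_smooth(x, if (is.null(window_len)) 250 else window_len))
  dff <- compute_dff(x, bl)
  seg <- if (spec$criterion %in% c("baseline_sd", "baseline_z"))
    default_baseline_segment(bl, dff) else NULL
  raster <- threshold_raster(dff, threshold_spec(spec$criterion, sd_multiple,
                                                 alpha, seg))
  events <- events_from_raster(raster, dff)
  if (compute_features && nrow(events))
    events <- event_features(events, dff, "dff")
  structure(list(method = method, raster = raster, events = events,
                 baseline = bl, dff = dff),
            class = "ca_detection")
}

#' @export
print.ca_detection <- function(x, ...) {
  cat(sprintf("Detection [%s]: %d event(s), %d active frame(s)\n",
              x$method, nrow(x$events), sum(x$raster$active)))
  invisible(x)
}

#' Run several detectors over several traces
#'
#' Applies each requested method to each trace; per-ROI failures are
#' isolated (recorded as `NULL` with a warning) rather than aborting the
#' batch. When `out_dir` is given, rasters, events and the effective
#' configuration are persisted there.
#'
#' @param traces list of `"fluor_trace"` objects (or numeric vectors).
#' @param methods method ids (default: all thirteen).
#' @param out_dir optional output directory.
#' @param ... passed to [detect_events()] (e.g. `scales`, `thresholds`).
#' @return Nested list `results[[method]][[roi]]` of `"ca_detection"`s.
#' @export
run_detect <- function(traces, methods = detection_methods(), out_dir = NULL,
                       ...) {
  ids <- vapply(seq_along(traces), function(i) {
    t <- traces[[i]]
    if (inherits(t, "fluor_trace")) as.character(t$roi_id) else sprintf("roi%d", i)
  }, character(1))
  results <- lapply(methods, function(m) {
    per_roi <- lapply(seq_along(traces), function(i) {
      tryCatch(detect_events(traces[[i]], m, ...),
               error = function(e) {
                 warn_calwave("calwave_roi_failure", "ROI '%s', method '%s': %s",
                              ids[i], m, conditionMessage(e))
                 NULL
               })
    })
    names(per_roi) <- ids
    per_roi
  })
  names(results) <- methods
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- c(list(methods = methods, rois = ids), list(...))
    cfg <- cfg[vapply(cfg, function(x) is.atomic(x) || is.list(x) &&
                        !inherits(x, c("scale_set", "ridge_thresholds")), logical(1))]
    fp <- list(...)$thresholds
    if (!is.null(fp)) cfg$calibration_fingerprint <- fp$fingerprint
    jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
    for (m in methods) {
      ok <- !vapply(results[[m]], is.null, logical(1))
      if (!any(ok)) next
      write_rasters(lapply(results[[m]][ok], `[[`, "raster"),
                    file.path(out_dir, paste0("rasters_", m, ".tsv")))
      ev <- do.call(rbind, lapply(names(results[[m]])[ok], function(id) {
        e <- results[[m]][[id]]$events
        if (nrow(e)) cbind(roi = id, method = m, e) else NULL
      }))
      if (!is.null(ev)) write_events(ev, file.path(out_dir, paste0("events_", m, ".json")))
    }
  }
  results
}

#' Tiered nonparametric group comparison of event features
#'
#' Convenience wrapper over [aggregate_features()] for condition-labeled
#' feature tables: Mann-Whitney U per measure per tier between two
#' conditions, Kruskal-Wallis across methods at the ROI-mean tier.
#'
#' @param features per-event data.frame with `roi`, `slice`, `group`
#'   (condition label) and feature columns; optionally `method`.
#' @return As [aggregate_features()].
#' @export
run_compare <- function(features) {
  if (!"group" %in% names(features))
    stop_calwave("calwave_invalid", "features must carry a 'group' condition label")
  if (length(unique(features$group)) < 2L)
    stop_calwave("calwave_invalid", "need >= 2 conditions")
  aggregate_features(features)
}
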