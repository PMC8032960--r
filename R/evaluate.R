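#' Score a raster against ground-truth event bounds
#'
#' `false_positive_fraction` is the fraction of active frames lying outside
#' every ground-truth interval (0 when nothing is active);
#' `events_captured_fraction` is the fraction of ground-truth frames marked
#' active (vacuously 1 when there are no ground-truth frames). Both depend
#' only on the 2x2 frame-overlap table between raster and truth.
#'
#' @param raster `"event_raster"` or 0/1 vector.
#' @param truth data.frame of 0-based half-open `start`, `end` intervals
#'   (e.g. the `truth` of a [generate_trace()] result).
#' @return Named list `false_positive_fraction`, `events_captured_fraction`.
#' @export
score_raster <- function(raster, truth) {
  a <- if (inherits(raster, "event_raster")) raster$active else as.integer(raster)
  ind <- frames_in_intervals(length(a), truth$start, truth$end)
  act <- a == 1L
  fp <- if (!any(act)) 0 else sum(act & !ind) / sum(act)
  cap <- if (!any(ind)) 1 else sum(ind & act) / sum(ind)
  list(false_positive_fraction = fp, events_captured_fraction = cap)
}

#' Sweep detector performance over an event frequency x duration grid
#'
#' For each grid cell, generates `reps` synthetic traces, runs the detector,
#' scores each raster against the known event bounds and averages both
#' scores. Cells whose event count cannot be packed without overlap fall
#' back to overlap-allowing placement (with merged truth intervals) when
#' `allow_overlap = "auto"`; failures are recorded per cell without
#' aborting the sweep. The whole sweep is deterministic given `seed`.
#'
#' @param method detector id (see [detection_methods()]).
#' @param frequencies vector of event counts per trace.
#' @param durations vector of event durations (frames).
#' @param reps replicates per cell (default 20).
#' @param seed master seed; per-trace seeds are derived from it.
#' @param config_args named list of [sim_config()] overrides (e.g.
#'   `event_shape`, `snr`, `n_frames`).
#' @param allow_overlap `FALSE`, `TRUE`, or `"auto"` (overlap only where
#'   packing is infeasible).
#' @param ... passed to [detect_events()] (`scales`, `thresholds`,
#'   `window_len`, ...).
#' @return A `"performance_surface"`: data.frame with one row per cell:
#'   `frequency`, `duration`, `false_positive_fraction`,
#'   `events_captured_fraction`, `reps`, `overlap`, `failed`.
#' @export
sweep_performance <- function(method, frequencies, durations, reps = 20,
                              seed = NULL, config_args = list(),
                              allow_overlap = "auto", ...) {
  parse_method(method)  # validate early
  grid <- expand.grid(frequency = frequencies, duration = durations,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(grid) * reps)
  fp <- cap <- numeric(nrow(grid))
  ovl <- failed <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    base <- config_args
    base$n_events <- grid$frequency[g]
    base$event_duration <- grid$duration[g]
    n_frames <- if (is.null(base$n_frames)) 3001 else base$n_frames
    base$allow_overlap <- isTRUE(allow_overlap) ||
      (identical(allow_overlap, "auto") &&
         grid$frequency[g] * grid$duration[g] > n_frames)
    ovl[g] <- base$allow_overlap
    sc_fp <- sc_cap <- numeric(reps)
    ok <- TRUE
    for (r in seq_len(reps)) {
      base$seed <- seeds[[(g - 1L) * reps + r]]
      res <- tryCatch({
        tr <- generate_trace(do.call(sim_config, base))
        det <- detect_events(tr$values, method, compute_features = FALSE, ...)
        score_raster(det$raster, tr$truth)
      }, error = function(e) e)
      if (inherits(res, "error")) { ok <- FALSE; break }
      sc_fp[r] <- res$false_positive_fraction
      sc_cap[r] <- res$events_captured_fraction
    }
    failed[g] <- !ok
    fp[g] <- if (ok) mean(sc_fp) else NA_real_
    cap[g] <- if (ok) mean(sc_cap) else NA_real_
  }
  out <- cbind(grid, false_positive_fraction = fp,
               events_captured_fraction = cap, reps = reps,
               overlap = ovl, failed = failed)
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  class(out) <- c("performance_surface", "data.frame")
  out
}

#' Locate the performance-transition frequency of a captured-fraction curve
#'
#' Operationalizes "where the detector begins to fail": the plateau is the
#' mean captured fraction over the 3 lowest frequencies, and the breakdown
#' frequency is the largest frequency whose captured fraction is still at
#' least `(1 - rel_drop)` of the plateau.
#'
#' @param frequencies increasing event counts (>= 4 points), or a
#'   `"performance_surface"` restricted to one duration.
#' @param captured captured fractions matching `frequencies` (ignored when a
#'   surface is given).
#' @param rel_drop relative drop defining failure (default 0.10).
#' @return list with `breakdown` (frequency), `plateau`, and `curve`
#'   (data.frame `frequency`, `captured`).
#' @export
find_transition <- function(frequencies, captured = NULL, rel_drop = 0.10) {
  if (inherits(frequencies, "performance_surface")) {
    surf <- frequencies
    if (length(unique(surf$duration)) != 1L)
      stop_calwave("calwave_invalid", "surface must be restricted to one duration")
    captured <- surf$events_captured_fraction
    frequencies <- surf$frequency
  }
  o <- order(frequencies)
  f <- frequencies[o]; cp <- captured[o]
  if (length(f) < 4L)
    stop_calwave("calwave_invalid", "need at least 4 frequency points")
  plateau <- mean(cp[1:3])
  ok <- cp >= (1 - rel_drop) * plateau
  breakdown <- if (any(ok)) max(f[ok]) else NA_real_
  list(breakdown = breakdown, plateau = plateau,
       curve = data.frame(frequency = f, captured = cp))
}
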