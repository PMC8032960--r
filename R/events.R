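#' Events from a binary raster
#'
#' Events are maximal runs of active frames. The event center is the frame
#' of maximum dF/F0 within the run when a dF/F0 trace is supplied, and the
#' run midpoint otherwise.
#'
#' @param raster an `"event_raster"` or 0/1 vector.
#' @param dff optional `"dff_trace"` (or numeric vector) used to locate
#'   event centers.
#' @return data.frame with 0-based half-open `start`, `end`, plus `center`
#'   and `duration` (frames). Empty for an all-zero raster.
#' @export
events_from_raster <- function(raster, dff = NULL) {
  a <- if (inherits(raster, "event_raster")) raster$active else as.integer(raster)
  stopifnot(all(a %in% c(0L, 1L)))
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  on <- r$values == 1L
  ev <- data.frame(start = starts[on], end = ends[on])
  if (nrow(ev) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      center = integer(), duration = integer()))
  x <- if (is.null(dff)) NULL
       else if (inherits(dff, "dff_trace")) dff$values else as.numeric(dff)
  ev$center <- vapply(seq_len(nrow(ev)), function(i) {
    if (is.null(x)) return(ev$start[i] + (ev$end[i] - ev$start[i] - 1L) %/% 2L)
    win <- (ev$start[i] + 1L):ev$end[i]
    win[which.max(x[win])] - 1L
  }, integer(1))
  ev$duration <- ev$end - ev$start
  ev
}

#' Events and raster from significant ridges
#'
#' Each significant ridge yields one event centered on the frame of its
#' maximum CWT amplitude. The event extent is the central window at the
#' scale of that maximum: `[t* - w*, t* + w* + 1)` clipped to the trace,
#' with `w*` the half-width at that scale. The raster is the union of all
#' extents; overlapping extents remain distinct events (each significant
#' ridge counts as one event for frequency) even though their raster frames
#' merge.
#'
#' @param ridges a significance-filtered [walk_ridges()] result (see
#'   [filter_ridges()]).
#' @param scales the matching [build_scale_set()].
#' @param extent_mult multiplier on the half-width defining the event
#'   extent (default 1 uses the linking window itself).
#' @return list with `events` (data.frame `start`, `end`, `center`,
#'   `duration`, `scale_index`, `cwt_amp`) and `raster` (`"event_raster"`,
#'   method `"wavelet"`). No significant ridges give an empty raster
#'   (the dead-ROI behavior).
#' @export
events_from_ridges <- function(ridges, scales, extent_mult = 1) {
  stopifnot(inherits(ridges, "ridge_set"), inherits(scales, "scale_set"))
  if (!identical(ridges$fingerprint, attr(scales, "fingerprint")))
    stop_calwave("calwave_stale_calibration", "ridges and scale set do not match")
  n <- ridges$n_frames
  s <- ridges$summary
  hw_by_index <- scales$half_width[match(s$max_scale_index, scales$scale_index)]
  w <- as.integer(round(extent_mult * hw_by_index))
  ev <- data.frame(start = pmax(0L, s$max_frame - w),
                   end = pmin(n, s$max_frame + w + 1L),
                   center = s$max_frame,
                   scale_index = s$max_scale_index,
                   cwt_amp = s$max_amp)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  rownames(ev) <- NULL
  ev$duration <- ev$end - ev$start
  active <- integer(n)
  active[frames_in_intervals(n, ev$start, ev$end)] <- 1L
  raster <- structure(list(active = active, method = "wavelet",
                           degenerate = FALSE, threshold = NA_real_),
                      class = "event_raster")
  list(events = ev[c("start", "end", "center", "duration", "scale_index", "cwt_amp")],
       raster = raster)
}

#' Per-event baseline from the trace segment preceding an event
#'
#' Mean of the up-to-`lookback` frames immediately before the event start,
#' excluding frames belonging to any other detected event; when no eligible
#' frame precedes the event, the frames immediately following the event end
#' are used instead (same exclusions).
#'
#' @param values raw fluorescence series.
#' @param event one row (list or data.frame row) with `start`, `end`.
#' @param all_events data.frame of all detected events in the trace.
#' @param lookback number of frames considered (default 25, i.e. 1 s at
#'   25 Hz).
#' @return Scalar fluorescence baseline.
#' @export
per_event_f0 <- function(values, event, all_events, lookback = 25) {
  n <- length(values)
  occupied <- frames_in_intervals(n, all_events$start, all_events$end)
  eligible <- function(frames) {
    frames <- frames[frames >= 0L & frames < n]
    frames[!occupied[frames + 1L]]
  }
  pre <- eligible(seq.int(event$start - lookback, event$start - 1L))
  use <- if (length(pre)) pre else eligible(seq.int(event$end, event$end + lookback - 1L))
  if (!length(use))
    stop_calwave("calwave_degenerate_baseline",
                 "no eligible frames around event [%d, %d) for a per-event F0",
                 event$start, event$end)
  mean(values[use + 1L])
}

#' Event amplitudes and durations
#'
#' In the dF/F0 pathway the amplitude is the maximum dF/F0 value within the
#' event window. In the wavelet pathway each event is normalized by its own
#' baseline ([per_event_f0()]): amplitude = `max((F - f0) / f0)` over the
#' window. A nonpositive per-event F0 yields an `NA` amplitude with a
#' warning rather than aborting the batch.
#'
#' @param events data.frame of events (`start`, `end`, 0-based half-open).
#' @param trace dF/F0 trace (`"dff_trace"`/numeric, dff pathway) or raw
#'   fluorescence (wavelet pathway).
#' @param pathway `"dff"` or `"wavelet"`.
#' @param lookback passed to [per_event_f0()] (wavelet pathway).
#' @return `events` with `amplitude` (and `f0` in the wavelet pathway)
#'   columns added.
#' @export
event_features <- function(events, trace, pathway = c("dff", "wavelet"),
                           lookback = 25) {
  pathway <- match.arg(pathway)
  if (nrow(events) == 0L) {
    events$amplitude <- numeric(0)
    if (pathway == "wavelet") events$f0 <- numeric(0)
    return(events)
  }
  if (any(events$end <= events$start))
    stop_calwave("calwave_invalid", "empty event window")
  if (pathway == "dff") {
    x <- if (inherits(trace, "dff_trace")) trace$values else as.numeric(trace)
    events$amplitude <- vapply(seq_len(nrow(events)), function(i)
      max(x[(events$start[i] + 1L):events$end[i]]), numeric(1))
  } else {
    x <- trace_values(trace)
    f0 <- vapply(seq_len(nrow(events)), function(i)
      tryCatch(per_event_f0(x, events[i, ], events, lookback),
               error = function(e) NA_real_), numeric(1))
    amp <- rep(NA_real_, nrow(events))
    ok <- !is.na(f0) & f0 > 0
    if (any(!ok))
      warn_calwave("calwave_degenerate_baseline",
                   "%d event(s) with missing or nonpositive per-event F0: amplitude set NA",
                   sum(!ok))
    amp[ok] <- vapply(which(ok), function(i)
      max((x[(events$start[i] + 1L):events$end[i]] - f0[i]) / f0[i]), numeric(1))
    events$f0 <- f0
    events$amplitude <- amp
  }
  events
}

#' Fraction of ROIs active per frame
#'
#' @param rasters list of `"event_raster"`s (or 0/1 vectors) of equal
#'   length, one per ROI.
#' @return Numeric series in `[0, 1]`: per-frame fraction of active ROIs.
#' @export
activation_probability <- function(rasters) {
  if (length(rasters) == 0L) stop_calwave("calwave_invalid", "no rasters")
  m <- do.call(cbind, lapply(rasters, function(r)
    if (inherits(r, "event_raster")) r$active else as.integer(r)))
  rowMeans(m)
}

#' Three-tier feature aggregation and group comparisons
#'
#' Summarizes per-event features at three population scales: all events
#' pooled, per-ROI means, and per-slice means (event counts are reported at
#' the ROI tier as frequency). When a two-level `group` label is supplied,
#' Mann-Whitney U tests compare the groups per measure per tier; with a
#' `method` label, a Kruskal-Wallis test (plus pairwise Mann-Whitney
#' follow-ups) compares methods at the ROI-mean tier. Tiers with fewer than
#' two groups are skipped with a notice.
#'
#' @param features data.frame with per-event rows: feature columns
#'   `duration`, `amplitude`, plus label columns `roi` and `slice` (and
#'   optionally `group`, `method`).
#' @param measures feature columns to summarize.
#' @return list with `tiers` (named list of data.frames), `comparisons`
#'   (data.frame of test results, possibly empty), and `notices`.
#' @export
aggregate_features <- function(features, measures = c("duration", "amplitude")) {
  stopifnot(all(c("roi", "slice") %in% names(features)))
  measures <- intersect(measures, names(features))
  lab_cols <- intersect(c("group", "method"), names(features))
  roi_keys <- c("slice", "roi", lab_cols)
  roi_means <- stats::aggregate(features[measures],
                                features[roi_keys], mean, na.rm = TRUE)
  counts <- stats::aggregate(list(frequency = features$roi),
                             features[roi_keys], length)
  roi_means <- merge(roi_means, counts, by = roi_keys)
  slice_means <- stats::aggregate(roi_means[c(measures, "frequency")],
                                  roi_means[c("slice", lab_cols)], mean, na.rm = TRUE)
  tiers <- list(all_events = features, roi_means = roi_means,
                slice_means = slice_means)
  comparisons <- list(); notices <- character(0)
  if ("group" %in% names(features)) {
    for (tier in names(tiers)) {
      dat <- tiers[[tier]]
      gl <- unique(dat$group)
      if (length(gl) < 2L) {
        notices <- c(notices, sprintf("tier '%s': <2 groups, comparison skipped", tier))
        next
      }
      ms <- intersect(c(measures, "frequency"), names(dat))
      for (m in ms) {
        a <- dat[[m]][dat$group == gl[1]]; b <- dat[[m]][dat$group == gl[2]]
        if (length(a) < 1L || length(b) < 1L) next
        p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
        comparisons[[length(comparisons) + 1L]] <-
          data.frame(tier = tier, measure = m, test = "mann_whitney",
                     p_value = p, n1 = length(a), n2 = length(b))
      }
    }
  }
  if ("method" %in% names(features) &&
      length(unique(roi_means$method)) >= 2L) {
    for (m in intersect(c(measures, "frequency"), names(roi_means))) {
      kw <- stats::kruskal.test(roi_means[[m]], factor(roi_means$method))
      comparisons[[length(comparisons) + 1L]] <-
        data.frame(tier = "roi_means", measure = m, test = "kruskal_wallis",
                   p_value = kw$p.value, n1 = nrow(roi_means), n2 = NA)
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    else data.frame(tier = character(), measure = character(),
                    test = character(), p_value = numeric(),
                    n1 = integer(), n2 = integer())
  list(tiers = tiers, comparisons = comparisons, notices = notices)
}
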