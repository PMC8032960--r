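#' Per-scale local maxima of a CWT sheet
#'
#' A frame is a local maximum at a scale iff its amplitude strictly exceeds
#' both neighbors; for plateaus of equal values the leftmost frame stands
#' for the plateau, and a plateau is a maximum only if strictly above the
#' values on both sides. Series endpoints are never maxima.
#'
#' @param sheet a [morse_cwt()] result.
#' @return List (one element per scale row, largest scale first) of lists
#'   with 0-based `frame` and `amp` vectors.
#' @export
find_scale_maxima <- function(sheet) {
  stopifnot(inherits(sheet, "cwt_sheet"))
  apply_rows <- function(a) {
    r <- rle(a)
    k <- length(r$values)
    if (k < 3L) return(list(frame = integer(0), amp = numeric(0)))
    starts <- cumsum(c(0L, r$lengths[-k]))  # 0-based start of each run
    i <- 2:(k - 1L)
    is_max <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
    sel <- i[is_max]
    list(frame = as.integer(starts[sel]), amp = r$values[sel])
  }
  lapply(seq_len(nrow(sheet$amp)), function(j) apply_rows(sheet$amp[j, ]))
}

#' Link per-scale maxima into ridges (ridgewalking)
#'
#' Starting from the maxima at the largest scale, the walker proceeds to
#' smaller scales. A maximum extends a live ridge when it falls within the
#' central window of the *preceding* (larger) scale centered on the ridge
#' tip. If several maxima fall in one ridge's window only the
#' largest-amplitude one is appended (amplitude ties: earlier frame); the
#' others initialize new ridges, as do maxima outside every window. When a
#' maximum lies in two ridges' windows, the ridge whose tip is temporally
#' closer claims it (ties: the earlier-initialized ridge). A ridge that
#' receives no maximum at a scale is terminated: gaps in scale are not
#' allowed. Every input maximum ends up in exactly one ridge, so the summed
#' ridge lengths equal the total maxima count; isolated maxima persist as
#' single-point ridges (they are removed later by the length criterion).
#'
#' @param maxima output of [find_scale_maxima()].
#' @param scales the [build_scale_set()] the sheet was computed with.
#' @param keep_points if `FALSE`, only per-ridge summaries are returned
#'   (faster; sufficient for noise calibration).
#' @return A `"ridge_set"`: list with `summary` (data.frame `ridge`,
#'   `length`, `max_scale_index`, `max_frame`, `max_amp`), `points`
#'   (data.frame `ridge`, `scale_index`, `frame`, `amplitude`, or `NULL`),
#'   `n_frames` and the scale-set `fingerprint`.
#' @export
walk_ridges <- function(maxima, scales, keep_points = TRUE) {
  stopifnot(inherits(scales, "scale_set"))
  K <- nrow(scales)
  if (length(maxima) != K)
    stop_calwave("calwave_invalid", "maxima list length does not match scale set")
  hw <- scales$half_width
  sidx <- scales$scale_index
  total <- sum(vapply(maxima, function(m) length(m$frame), integer(1)))

  # per-ridge accumulators (a ridge id is its creation order)
  r_len <- integer(total); r_maxamp <- numeric(total)
  r_maxrow <- integer(total); r_maxframe <- integer(total)
  n_r <- 0L
  if (keep_points) {
    p_r <- integer(total); p_row <- integer(total)
    p_f <- integer(total); p_a <- numeric(total); n_p <- 0L
  }

  live_id <- integer(0); live_tip <- integer(0)

  add_points <- function(ids, row, f, a) {
    m <- length(ids)
    if (m == 0L) return(invisible())
    idx <- n_p + seq_len(m)
    p_r[idx] <<- ids; p_row[idx] <<- row; p_f[idx] <<- f; p_a[idx] <<- a
    n_p <<- n_p + m
  }
  new_ridges <- function(row, f, a) {
    m <- length(f)
    if (m == 0L) return(integer(0))
    ids <- n_r + seq_len(m)
    r_len[ids] <<- 1L; r_maxamp[ids] <<- a
    r_maxrow[ids] <<- row; r_maxframe[ids] <<- f
    n_r <<- n_r + m
    ids
  }

  for (row in seq_len(K)) {
    mf <- maxima[[row]]$frame; ma <- maxima[[row]]$amp
    m <- length(mf)
    if (row == 1L || length(live_id) == 0L) {
      ids <- new_ridges(row, mf, ma)
      if (keep_points) add_points(ids, row, mf, ma)
      live_id <- ids; live_tip <- mf
      next
    }
    if (m == 0L) { live_id <- integer(0); live_tip <- integer(0); next }
    w <- hw[row - 1L]
    L <- length(live_id)
    # candidate index range of each live ridge's window (maxima sorted by frame)
    lo <- findInterval(live_tip - w - 1L, mf) + 1L
    hi <- findInterval(live_tip + w, mf)
    claimed <- logical(m)
    got <- rep(NA_integer_, L)   # maximum index appended to each live ridge
    need <- which(lo <= hi)
    # deferred acceptance: each starving ridge proposes the largest unclaimed
    # maximum in its window; conflicts over one maximum go to the ridge with
    # the temporally closer tip (ties: the earlier-initialized ridge); losers
    # retry until their windows hold no unclaimed maxima.
    while (length(need)) {
      prop <- rep(NA_integer_, L)
      for (i in need) {
        rng <- lo[i]:hi[i]
        cand <- rng[!claimed[rng]]
        if (length(cand))
          prop[i] <- cand[which.max(ma[cand])]  # ties: earliest frame
      }
      pr <- which(!is.na(prop))
      if (!length(pr)) break
      key <- prop[pr]
      o <- order(key, abs(live_tip[pr] - mf[key]), live_id[pr])
      win <- pr[o][!duplicated(key[o])]
      got[win] <- prop[win]
      claimed[prop[win]] <- TRUE
      need <- setdiff(need, win)
    }
    ext <- which(!is.na(got))
    if (length(ext)) {
      ids <- live_id[ext]; kf <- mf[got[ext]]; ka <- ma[got[ext]]
      r_len[ids] <- r_len[ids] + 1L
      upd <- ka > r_maxamp[ids]
      r_maxamp[ids[upd]] <- ka[upd]
      r_maxrow[ids[upd]] <- row
      r_maxframe[ids[upd]] <- kf[upd]
      if (keep_points) add_points(ids, row, kf, ka)
      next_id <- ids; next_tip <- kf
    } else {
      next_id <- integer(0); next_tip <- integer(0)
    }
    rest <- which(!claimed)
    nid <- new_ridges(row, mf[rest], ma[rest])
    if (keep_points) add_points(nid, row, mf[rest], ma[rest])
    live_id <- c(next_id, nid)
    live_tip <- c(next_tip, mf[rest])
  }

  summary <- data.frame(ridge = seq_len(n_r), length = r_len[seq_len(n_r)],
                        max_scale_index = sidx[r_maxrow[seq_len(n_r)]],
                        max_frame = r_maxframe[seq_len(n_r)],
                        max_amp = r_maxamp[seq_len(n_r)])
  points <- NULL
  if (keep_points && total > 0L) {
    points <- data.frame(ridge = p_r[seq_len(n_p)],
                         scale_index = sidx[p_row[seq_len(n_p)]],
                         frame = p_f[seq_len(n_p)],
                         amplitude = p_a[seq_len(n_p)])
    points <- points[order(points$ridge, -points$scale_index), ]
    rownames(points) <- NULL
  } else if (keep_points) {
    points <- data.frame(ridge = integer(), scale_index = integer(),
                         frame = integer(), amplitude = numeric())
  }
  structure(list(summary = summary, points = points,
                 n_frames = attr(scales, "n_frames"),
                 fingerprint = attr(scales, "fingerprint")),
            class = "ridge_set")
}

#' @export
print.ridge_set <- function(x, ...) {
  cat(sprintf("Ridge set: %d ridge(s), lengths %s\n", nrow(x$summary),
              if (nrow(x$summary)) paste0(min(x$summary$length), "..",
                                          max(x$summary$length)) else "-"))
  invisible(x)
}

#' Filter ridges by the calibrated significance criteria
#'
#' A ridge is significant iff it passes through at least `min_ridge_length`
#' scales AND the scale of its maximum CWT amplitude lies strictly above
#' `min_max_scale` (ridges whose maxima occur at or below that scale index
#' are excluded as short noise). Both criteria must hold.
#'
#' @param ridges a [walk_ridges()] result.
#' @param thresholds a [calibrate_thresholds()] result whose scale-set
#'   fingerprint matches the one the ridges were walked under.
#' @return The `"ridge_set"` restricted to significant ridges.
#' @export
filter_ridges <- function(ridges, thresholds) {
  stopifnot(inherits(ridges, "ridge_set"), inherits(thresholds, "ridge_thresholds"))
  if (!identical(ridges$fingerprint, thresholds$fingerprint))
    stop_calwave("calwave_stale_calibration",
                 "thresholds were calibrated for a different scale set; re-run calibrate_thresholds()")
  keep <- ridges$summary$length >= thresholds$min_ridge_length &
    ridges$summary$max_scale_index > thresholds$min_max_scale
  out <- ridges
  out$summary <- ridges$summary[keep, , drop = FALSE]
  rownames(out$summary) <- NULL
  if (!is.null(ridges$points)) {
    out$points <- ridges$points[ridges$points$ridge %in% out$summary$ridge, , drop = FALSE]
    rownames(out$points) <- NULL
  }
  out
}

#' Calibrate ridge significance thresholds by white-noise modeling
#'
#' Generates `n_series` Gaussian white-noise series, runs the CWT and
#' ridgewalker on each, pools all ridges, and builds empirical CDFs of
#' ridge length and of the scale index of each ridge's maximum amplitude
#' ("event size"). `min_ridge_length` is the smallest length excluding at
#' least `exclusion` of all noise ridges by length alone. The event-size
#' criterion exists to remove short *noise* ridges that nevertheless pass
#' the length test, so by default `min_max_scale` is calibrated on the
#' conditional CDF among noise ridges that survive the length criterion
#' (`scale_conditional = TRUE`); set `scale_conditional = FALSE` to
#' calibrate it on the marginal CDF of all noise ridges instead (this
#' raises the cutoff and discards genuine short-duration events, because
#' the marginal CDF is dominated by very short ridges that the length
#' criterion already removes). Unit noise variance is used: both
#' statistics are amplitude-free, so the calibration holds across noise
#' variances. Thresholds are bound to the scale set by its fingerprint and
#' must be recalibrated when it changes.
#'
#' @param scales a [build_scale_set()] result (its `n_frames` fixes the
#'   series length).
#' @param n_series number of noise series (>= 100; default 10000).
#' @param exclusion target exclusion rate in (0, 1), default 0.98.
#' @param scale_conditional calibrate the event-size cutoff among
#'   length-surviving noise ridges (default) or marginally.
#' @param seed RNG seed for the noise batch.
#' @return A `"ridge_thresholds"`: `min_ridge_length`, `min_max_scale`,
#'   `exclusion`, empirical CDF tables (`length_cdf`, `scale_cdf`),
#'   `n_ridges`, calibration metadata, and the scale-set `fingerprint`.
#' @export
calibrate_thresholds <- function(scales, n_series = 10000, exclusion = 0.98,
                                 scale_conditional = TRUE, seed = NULL) {
  stopifnot(inherits(scales, "scale_set"))
  if (!is_count(n_series, 100)) stop_calwave("calwave_invalid", "n_series must be >= 100")
  if (!(exclusion > 0 && exclusion < 1))
    stop_calwave("calwave_invalid", "exclusion must be in (0, 1)")
  n <- attr(scales, "n_frames")
  stats <- noise_ridge_stats(scales, n_series, seed)
  if (nrow(stats) < 50 / (1 - exclusion))
    stop_calwave("calwave_calibration_unstable",
                 "only %d noise ridges: too few to estimate the %.3g CDF tail",
                 nrow(stats), exclusion)
  N <- nrow(stats)
  len_tab <- tabulate(stats$length)
  len_cum <- cumsum(len_tab) / N            # P(length <= L)
  # smallest L with P(length < L) >= exclusion
  min_len <- which(len_cum >= exclusion)[1] + 1L
  sc_tab <- tabulate(stats$max_scale_index, nbins = nrow(scales))
  sc_cum <- cumsum(sc_tab) / N              # P(max scale <= s), marginal
  sc_pop <- if (scale_conditional)
    stats$max_scale_index[stats$length >= min_len] else stats$max_scale_index
  if (scale_conditional && length(sc_pop) < 5 / (1 - exclusion))
    stop_calwave("calwave_calibration_unstable",
                 "only %d length-surviving noise ridges: too few for the conditional event-size CDF",
                 length(sc_pop))
  sc_cond_cum <- cumsum(tabulate(sc_pop, nbins = nrow(scales))) / length(sc_pop)
  min_scale <- which(sc_cond_cum >= exclusion)[1]
  structure(list(min_ridge_length = min_len, min_max_scale = min_scale,
                 scale_conditional = scale_conditional,
                 exclusion = exclusion,
                 length_cdf = data.frame(length = seq_along(len_cum),
                                         cdf = len_cum),
                 scale_cdf = data.frame(scale_index = seq_along(sc_cum),
                                        cdf = sc_cum),
                 n_ridges = N, n_series = n_series, series_len = n,
                 seed = seed, fingerprint = attr(scales, "fingerprint")),
            class = "ridge_thresholds")
}

# Pooled (length, max-scale-index) statistics of ridges walked on white noise.
noise_ridge_stats <- function(scales, n_series, seed = NULL) {
  n <- attr(scales, "n_frames")
  with_local_seed(seed, {
    out <- vector("list", n_series)
    for (i in seq_len(n_series)) {
      x <- rnorm(n)
      rs <- walk_ridges(find_scale_maxima(morse_cwt(x, scales)), scales,
                        keep_points = FALSE)
      out[[i]] <- rs$summary[c("length", "max_scale_index")]
    }
    do.call(rbind, out)
  })
}

#' @export
print.ridge_thresholds <- function(x, ...) {
  cat(sprintf("Ridge significance thresholds (%.3g%% exclusion, %d noise ridges from %d series of %d frames):\n",
              100 * x$exclusion, x$n_ridges, x$n_series, x$series_len))
  cat(sprintf("  min ridge length: %d scales; event-size scale index: > %d (%s CDF)\n",
              x$min_ridge_length, x$min_max_scale,
              if (isTRUE(x$scale_conditional)) "conditional" else "marginal"))
  invisible(x)
}

#' Serialize / restore calibrated thresholds
#'
#' Thresholds are written as JSON carrying the criteria, both empirical
#' CDFs, the calibration metadata and the scale-set fingerprint, so a
#' stored calibration can be checked against the scale set it is applied
#' to (see [filter_ridges()]).
#'
#' @param thresholds a [calibrate_thresholds()] result.
#' @param path JSON file path.
#' @return `write_thresholds` returns `path` invisibly; `read_thresholds`
#'   returns a `"ridge_thresholds"` object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "ridge_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$min_ridge_length <- as.integer(x$min_ridge_length)
  x$min_max_scale <- as.integer(x$min_max_scale)
  structure(x, class = "ridge_thresholds")
}
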