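#' Read ROI fluorescence traces from delimited text
#'
#' The expected layout is one header row of ROI identifiers followed by one
#' row per frame (frames in rows, ROIs in columns, 0-based frame index
#' implicit). Ragged rows and non-numeric (including `NaN`) cells are parse
#' errors that name the offending line.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param frame_rate sampling rate in Hz attached to each trace.
#' @return A list of `"fluor_trace"` objects: `roi_id`, `values`,
#'   `frame_rate`. A header-only file yields an empty list.
#' @export
read_traces <- function(path, sep = "\t", frame_rate = 25) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) stop_calwave("calwave_parse", "empty file: %s", path)
  ids <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  ncol <- length(ids)
  nrow <- length(lines) - 1L
  vals <- matrix(NA_real_, nrow, ncol)
  for (i in seq_len(nrow)) {
    cells <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1]]
    if (length(cells) != ncol)
      stop_calwave("calwave_parse", "line %d: expected %d fields, found %d",
                   i + 1L, ncol, length(cells))
    x <- suppressWarnings(as.numeric(cells))
    if (any(is.na(x) | is.nan(x)))
      stop_calwave("calwave_parse", "line %d: non-numeric value '%s'",
                   i + 1L, cells[which(is.na(x) | is.nan(x))[1]])
    vals[i, ] <- x
  }
  lapply(seq_len(ncol), function(j) {
    structure(list(roi_id = ids[j], values = vals[, j], frame_rate = frame_rate),
              class = "fluor_trace")
  })
}

#' Write ROI traces as delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_traces(write_traces(x))` round-trips to better than 12 significant
#' digits.
#'
#' @param traces list of `"fluor_trace"` objects, a numeric matrix
#'   (frames x ROIs), or a single numeric vector.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, sep = "\t") {
  if (is.numeric(traces)) traces <- as.matrix(traces)
  if (is.matrix(traces)) {
    ids <- colnames(traces)
    if (is.null(ids)) ids <- paste0("roi", seq_len(ncol(traces)))
    m <- traces
  } else {
    ids <- vapply(traces, function(t) as.character(t$roi_id), character(1))
    m <- do.call(cbind, lapply(traces, `[[`, "values"))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(ids, collapse = sep), con)
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(body, con)
  invisible(path)
}

#' Write binary event rasters as delimited 0/1 text
#' @param rasters a 0/1 matrix (frames x ROIs), or list of rasters
#'   (`"event_raster"` objects or 0/1 vectors).
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_rasters <- function(rasters, path, sep = "\t") {
  if (is.list(rasters) && !is.data.frame(rasters)) {
    m <- do.call(cbind, lapply(rasters, function(r)
      if (inherits(r, "event_raster")) r$active else r))
  } else m <- as.matrix(rasters)
  storage.mode(m) <- "integer"
  write_traces(m, path, sep)
}

#' Write detected events as JSON records
#' @param events data.frame of events (0-based half-open `start`, `end`, plus
#'   any feature columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' ROI pixel mask set
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param rois named list; each element a two-column matrix of 1-based
#'   `(row, col)` pixel coordinates.
#' @return An object of class `"roi_mask_set"`.
#' @export
roi_mask_set <- function(dim, rois) {
  stopifnot(length(dim) == 2L, length(rois) > 0L)
  if (is.null(names(rois)) || anyDuplicated(names(rois)))
    stop_calwave("calwave_invalid", "rois must be uniquely named")
  for (nm in names(rois)) {
    px <- rois[[nm]]
    if (!is.matrix(px) || ncol(px) != 2L)
      stop_calwave("calwave_invalid", "ROI '%s': pixels must be a 2-column matrix", nm)
    if (any(px[, 1] < 1 | px[, 1] > dim[1] | px[, 2] < 1 | px[, 2] > dim[2]))
      stop_calwave("calwave_invalid", "ROI '%s': pixels outside image bounds", nm)
  }
  structure(list(dim = as.integer(dim), rois = rois), class = "roi_mask_set")
}

# Chebyshev dilation of a logical mask by w pixels (square structuring
# element), done separably along rows then columns.
dilate_chebyshev <- function(mask, w) {
  if (w == 0L) return(mask)
  shift_or <- function(m, along) {
    out <- m
    n <- dim(m)[along]
    for (k in seq_len(w)) {
      if (along == 1L) {
        out[seq_len(n - k), ] <- out[seq_len(n - k), , drop = FALSE] | m[(k + 1):n, , drop = FALSE]
        out[(k + 1):n, ] <- out[(k + 1):n, , drop = FALSE] | m[seq_len(n - k), , drop = FALSE]
      } else {
        out[, seq_len(n - k)] <- out[, seq_len(n - k), drop = FALSE] | m[, (k + 1):n, drop = FALSE]
        out[, (k + 1):n] <- out[, (k + 1):n, drop = FALSE] | m[, seq_len(n - k), drop = FALSE]
      }
    }
    out
  }
  shift_or(shift_or(mask, 1L), 2L)
}

roi_logical_mask <- function(masks, roi_id) {
  m <- matrix(FALSE, masks$dim[1], masks$dim[2])
  m[masks$rois[[roi_id]]] <- TRUE
  m
}

#' Neuropil subtraction via a pixel halo around an ROI
#'
#' The neuropil estimate is the mean trace over a halo of pixels within
#' Chebyshev distance `halo_width` of the ROI (dilation by a square
#' structuring element), excluding the ROI's own pixels and pixels belonging
#' to any other ROI. The returned trace is the ROI-mean trace minus the
#' halo-mean trace, per frame. If the halo is empty the ROI trace is
#' returned unchanged with attribute `empty_halo = TRUE` and a warning.
#'
#' @param stack numeric array `frames x rows x cols` of pixel intensities.
#' @param masks a [roi_mask_set()].
#' @param roi_id name of the ROI to extract.
#' @param halo_width halo width in pixels (default 60).
#' @param frame_rate sampling rate attached to the output trace.
#' @return A `"fluor_trace"` (neuropil-subtracted).
#' @export
subtract_neuropil <- function(stack, masks, roi_id, halo_width = 60,
                              frame_rate = 25) {
  stopifnot(inherits(masks, "roi_mask_set"), length(dim(stack)) == 3L)
  if (!roi_id %in% names(masks$rois))
    stop_calwave("calwave_not_found", "unknown ROI '%s'", roi_id)
  if (!all(dim(stack)[2:3] == masks$dim))
    stop_calwave("calwave_invalid", "stack dimensions do not match masks")
  roi_mask <- roi_logical_mask(masks, roi_id)
  all_rois <- Reduce(`|`, lapply(names(masks$rois), roi_logical_mask, masks = masks))
  halo <- dilate_chebyshev(roi_mask, as.integer(halo_width)) & !all_rois
  pix_trace <- function(mask) {
    idx <- which(mask)
    nf <- dim(stack)[1]
    rowMeans(matrix(stack[rep(seq_len(nf), length(idx)) +
                          (rep(idx, each = nf) - 1L) * nf], nrow = nf))
  }
  roi_trace <- pix_trace(roi_mask)
  if (!any(halo)) {
    warn_calwave("calwave_empty_halo", "ROI '%s': empty halo, no neuropil subtracted", roi_id)
    out <- roi_trace
    empty <- TRUE
  } else {
    out <- roi_trace - pix_trace(halo)
    empty <- FALSE
  }
  structure(list(roi_id = roi_id, values = out, frame_rate = frame_rate),
            class = "fluor_trace", empty_halo = empty)
}

#' Read a multi-page TIFF image stack
#'
#' Thin wrapper returning the `frames x rows x cols` array layout used by
#' [subtract_neuropil()]. Requires the `tiff` package.
#'
#' @param path TIFF file path.
#' @return Numeric array `frames x rows x cols`.
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_calwave("calwave_invalid", "reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  aperm(simplify2array(lapply(pages, as.matrix)), c(3, 1, 2))
}
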