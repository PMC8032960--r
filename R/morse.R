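#' Generalized Morse wavelet parameters
#'
#' The analytic Morse wavelet family has frequency-domain form
#' `Psi(w) ~ w^beta * exp(-w^gamma)` for `w > 0` (zero for `w <= 0`).
#' `gamma = 3` ("Airy" wavelets) is the default because it minimizes the
#' Heisenberg time-frequency area; `beta = 2` sets the order. The peak
#' (energy-maximizing) frequency of the mother wavelet is
#' `(beta/gamma)^(1/gamma)` radians/frame.
#'
#' @param gamma shape parameter (> 0), default 3.
#' @param beta order parameter (> 0), default 2, constant across scales.
#' @return A `"morse_params"` list.
#' @export
morse_params <- function(gamma = 3, beta = 2) {
  if (!(gamma > 0) || !(beta > 0))
    stop_calwave("calwave_invalid", "gamma and beta must be > 0")
  structure(list(gamma = gamma, beta = beta), class = "morse_params")
}

morse_peak_freq <- function(params) (params$beta / params$gamma)^(1 / params$gamma)

# Time-domain standard deviation of the mother wavelet's energy envelope,
# computed numerically on a fine oversampled grid (second moment of
# |psi(t)|^2); the SD at scale s is s times this. Cached per (gamma, beta).
morse_mother_sigma_t <- local({
  cache <- new.env(parent = emptyenv())
  function(params) {
    key <- sprintf("%.12g_%.12g", params$gamma, params$beta)
    if (!is.null(cache[[key]])) return(cache[[key]])
    wp <- morse_peak_freq(params)
    N <- 2^16
    dt <- 0.02 / wp
    om <- 2 * pi * (0:(N - 1)) / (N * dt)
    psi_f <- numeric(N)
    posk <- 2:(N / 2 + 1)
    w <- om[posk]
    psi_f[posk] <- w^params$beta * exp(-w^params$gamma)
    p <- Mod(stats::fft(psi_f, inverse = TRUE))^2
    p <- p / sum(p)
    tg <- c(0:(N / 2 - 1), -(N / 2):(-1)) * dt
    tbar <- sum(p * tg)
    cache[[key]] <- sqrt(sum(p * (tg - tbar)^2))
    cache[[key]]
  }
})

#' Build the scale set for a trace length
#'
#' Peak frequencies are log-spaced from just below the Nyquist frequency
#' (`0.95 * pi` rad/frame) down to the frequency at which the wavelet's
#' footprint of `P = sqrt(beta * gamma) / pi` periods spans the whole
#' series (`2 * pi * P / n_frames`), at `density` voices per octave.
#' Scales are ordered largest (lowest frequency) first; `scale_index`
#' counts 1 at the smallest scale. Each scale carries a central-window
#' half-width `round(c_win * sigma_t)` where `sigma_t` is the time-domain
#' standard deviation of the wavelet's energy envelope at that scale,
#' obtained numerically from a finely discretized mother wavelet and scaled
#' by `s` (direct discretization at the working resolution is corrupted by
#' Nyquist-truncation ringing at the smallest scales); these windows drive
#' both ridge linking and wavelet event extents.
#'
#' All significance thresholds downstream are tied to the exact scale set by
#' a fingerprint: recalibrate whenever the scale set or Morse parameters
#' change.
#'
#' @param n_frames trace length the set is built for (>= 8).
#' @param params a [morse_params()].
#' @param density voices per octave (default 4).
#' @param c_win central-window multiplier on `sigma_t` (default 2).
#' @param nyquist_cushion highest peak frequency as a fraction of Nyquist.
#' @return A `"scale_set"`: data.frame with columns `row`, `scale_index`,
#'   `scale`, `freq` (peak frequency, rad/frame), `sigma_t`, `half_width`;
#'   attributes carry the Morse parameters, the precomputed frequency-domain
#'   filters, and the calibration fingerprint.
#' @export
build_scale_set <- function(n_frames, params = morse_params(), density = 4,
                            c_win = 2, nyquist_cushion = 0.95) {
  stopifnot(inherits(params, "morse_params"))
  if (!is_count(n_frames, 8))
    stop_calwave("calwave_invalid", "n_frames must be an integer >= 8")
  P <- sqrt(params$beta * params$gamma) / pi
  w_low <- 2 * pi * P / n_frames
  w_high <- nyquist_cushion * pi
  if (w_low >= w_high)
    stop_calwave("calwave_invalid", "n_frames too small for a valid scale range")
  K <- ceiling(density * log2(w_high / w_low))
  if (K < 2) stop_calwave("calwave_invalid", "scale range admits fewer than 2 scales")
  freq <- exp(seq(log(w_low), log(w_high), length.out = K))  # largest scale first
  wp <- morse_peak_freq(params)
  scale <- wp / freq

  n_pad <- 2^ceiling(log2(n_frames))
  k <- 0:(n_pad - 1)
  omega <- 2 * pi * k / n_pad
  pos <- k >= 1 & k <= n_pad / 2
  filters <- matrix(0, n_pad, K)
  # bandpass (amplitude) normalization: each filter peaks at 2 at its scale's
  # peak frequency, so a unit oscillation at that frequency transforms to a
  # unit-magnitude coefficient.  White-noise coefficient SD then scales as
  # 1/sqrt(scale), concentrating noise ridge maxima at the smallest scales --
  # the basis of the event-size exclusion criterion.
  peak_val <- wp^params$beta * exp(-wp^params$gamma)
  for (j in seq_len(K)) {
    sw <- scale[j] * omega[pos]
    psi_f <- numeric(n_pad)
    psi_f[pos] <- 2 * sw^params$beta * exp(-sw^params$gamma) / peak_val
    filters[, j] <- psi_f
  }
  sigma_t <- scale * morse_mother_sigma_t(params)
  out <- data.frame(row = seq_len(K), scale_index = K:1, scale = scale,
                    freq = freq, sigma_t = sigma_t,
                    half_width = pmax(1L, as.integer(round(c_win * sigma_t))))
  # rounding cannot break monotonicity, but guard the invariant explicitly
  out$half_width <- rev(cummax(rev(out$half_width)))
  attr(out, "params") <- params
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "n_pad") <- n_pad
  attr(out, "density") <- density
  attr(out, "c_win") <- c_win
  attr(out, "filters") <- filters
  attr(out, "fingerprint") <- sprintf(
    "morse[g=%.10g,b=%.10g]n=%d,K=%d,dens=%.10g,cwin=%.10g,cush=%.10g",
    params$gamma, params$beta, n_frames, K, density, c_win, nyquist_cushion)
  class(out) <- c("scale_set", "data.frame")
  out
}

#' @export
print.scale_set <- function(x, ...) {
  cat(sprintf("Morse scale set: %d scales for %d-frame traces (gamma=%g, beta=%g)\n",
              nrow(x), attr(x, "n_frames"), attr(x, "params")$gamma,
              attr(x, "params")$beta))
  cat(sprintf("  peak freq %.4g..%.4g rad/frame; half-widths %d..%d frames\n",
              x$freq[1], x$freq[nrow(x)], x$half_width[1], x$half_width[nrow(x)]))
  invisible(x)
}

#' Continuous wavelet transform with generalized Morse wavelets
#'
#' Applies the analytic frequency-domain Morse filter of every scale by FFT
#' (zero-padded to the next power of two, padding removed afterwards).
#' The trace is linearly detrended first: fluorescence traces carry a large
#' positive offset and a bleaching trend which would otherwise dominate the
#' large-scale coefficients through the padding boundaries (a dead, bleached
#' trace must transform to a quiet sheet). The sheet stores the positive
#' part of the *in-phase* (real) component of the analytic transform:
#' Ca2+ events are upward bump-shaped deflections, to which the in-phase
#' component responds at full amplitude, while the quadrature component
#' picks up sharp-edge (step) responses that would masquerade as
#' small-scale structure. Deterministic and linear in the input, so sheet
#' amplitudes are positively homogeneous.
#'
#' @param trace numeric vector (or `"fluor_trace"`) whose length matches the
#'   scale set's `n_frames`.
#' @param scales a [build_scale_set()] result.
#' @return A `"cwt_sheet"`: list with `amp` (scales x frames magnitude
#'   matrix, largest scale in row 1), `scales`, and `roi_id` when available.
#' @export
morse_cwt <- function(trace, scales) {
  stopifnot(inherits(scales, "scale_set"))
  x <- trace_values(trace)
  n <- attr(scales, "n_frames")
  if (length(x) != n)
    stop_calwave("calwave_invalid", "trace length %d does not match scale set (%d)",
                 length(x), n)
  if (anyNA(x) || any(!is.finite(x)))
    stop_calwave("calwave_invalid", "trace contains non-finite values")
  n_pad <- attr(scales, "n_pad")
  t0 <- seq_len(n) - 1
  scale0 <- max(abs(x))
  fit <- stats::lm.fit(cbind(1, t0), x)
  x <- unname(fit$residuals)
  # a trace that is numerically an exact line (e.g. flat or pure bleach)
  # leaves only floating-point dust: its sheet is identically zero
  if (max(abs(x)) <= 1e-10 * (1 + scale0)) x[] <- 0
  X <- stats::fft(c(x, numeric(n_pad - n)))
  M <- attr(scales, "filters") * X  # column-wise recycling of X
  W <- stats::mvfft(M, inverse = TRUE) / n_pad
  amp <- t(pmax(Re(W[seq_len(n), , drop = FALSE]), 0))
  structure(list(amp = amp, scales = scales,
                 roi_id = if (inherits(trace, "fluor_trace")) trace$roi_id else NULL),
            class = "cwt_sheet")
}

#' @export
print.cwt_sheet <- function(x, ...) {
  cat(sprintf("CWT sheet: %d scales x %d frames (max amplitude %.4g)\n",
              nrow(x$amp), ncol(x$amp), max(x$amp)))
  invisible(x)
}

#' @export
plot.cwt_sheet <- function(x, ...) {
  image(x = seq_len(ncol(x$amp)) - 1L, y = seq_len(nrow(x$amp)),
        z = t(x$amp[rev(seq_len(nrow(x$amp))), , drop = FALSE]),
        xlab = "frame", ylab = "scale index (1 = smallest)",
        col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
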