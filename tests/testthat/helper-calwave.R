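# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

scales_3001 <- function() fixture("scales_3001", function() build_scale_set(3001))

# Noise calibration shared by detector-level tests (250 series keeps the
# conditional event-size CDF well estimated).
thresholds_3001 <- function() fixture("thresholds_3001", function()
  calibrate_thresholds(scales_3001(), n_series = 250, seed = 424242))

# A small scale set for cheap structural tests.
scales_512 <- function() fixture("scales_512", function() build_scale_set(512))

# Build a cwt_sheet object directly from an amplitude matrix, for tests of
# maxima finding / walking that need controlled sheets.
fake_sheet <- function(amp, scales) {
  structure(list(amp = amp, scales = scales, roi_id = NULL),
            class = "cwt_sheet")
}

# Random connected-ish adjacency matrix on n nodes with edge prob p.
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}
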