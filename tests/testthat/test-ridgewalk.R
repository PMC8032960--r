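test_that("per-scale maxima follow the strict-local-maximum rule", {
  ss <- scales_512()
  sheet <- fake_sheet(rbind(rep(1, 7), c(0, 1, 0, 2, 0, 1, 0)), ss[1:2, ])
  mx <- find_scale_maxima(sheet)
  expect_length(mx[[1]]$frame, 0L)              # constant row: none
  expect_equal(mx[[2]]$frame, c(1L, 3L, 5L))

  # plateau: leftmost frame, only if strictly above both sides
  sheet2 <- fake_sheet(matrix(c(0, 2, 2, 2, 1, 0, 3, 3, 0, 0), 2, byrow = TRUE),
                       ss[1:2, ])
  mx2 <- find_scale_maxima(sheet2)
  expect_equal(mx2[[1]]$frame, 1L)
  expect_equal(mx2[[2]]$frame, 1L)
  # plateau touching the series start is not a maximum
  expect_length(find_scale_maxima(
    fake_sheet(matrix(c(3, 3, 0, 0, 0), 1), ss[1, , drop = FALSE]))[[1]]$frame, 0L)
  # plateau touching the series end is not a maximum
  sheet3 <- fake_sheet(matrix(c(0, 1, 2, 2, 2), 1), ss[1, , drop = FALSE])
  expect_length(find_scale_maxima(sheet3)[[1]]$frame, 0L)

  # brute-force oracle on random rows
  set.seed(10)
  a <- rnorm(200)
  sheet4 <- fake_sheet(matrix(a, 1), ss[1, , drop = FALSE])
  got <- find_scale_maxima(sheet4)[[1]]$frame
  want <- which(a[2:199] > a[1:198] & a[2:199] > a[3:200])  # 0-based: idx
  expect_equal(got, as.integer(want))
})

test_that("ridge walking links, splits on gaps, and partitions maxima", {
  ss <- build_scale_set(256)
  K <- nrow(ss)
  mk_maxima <- function(frames_per_row) {
    lapply(frames_per_row, function(f)
      list(frame = as.integer(f), amp = rep(1, length(f)) + seq_along(f) * 0.1))
  }
  # one aligned maximum per scale -> a single full-length ridge
  mx <- mk_maxima(rep(list(100L), K))
  rs <- walk_ridges(mx, ss)
  expect_equal(nrow(rs$summary), 1L)
  expect_equal(rs$summary$length, K)

  # a missing interior scale splits the ridge in two
  rows <- rep(list(100L), K); rows[[10]] <- integer(0)
  rs2 <- walk_ridges(mk_maxima(rows), ss)
  expect_equal(nrow(rs2$summary), 2L)
  expect_equal(sort(rs2$summary$length), sort(c(9L, K - 10L)))

  # two far-apart chains stay separate at full length
  rs3 <- walk_ridges(mk_maxima(rep(list(c(20L, 230L)), K)), ss)
  expect_equal(nrow(rs3$summary), 2L)
  expect_equal(rs3$summary$length, c(K, K))

  # partition property on genuine noise sheets
  set.seed(5)
  for (i in 1:3) {
    sheet <- morse_cwt(rnorm(256), ss)
    mx <- find_scale_maxima(sheet)
    rs <- walk_ridges(mx, ss)
    expect_equal(sum(rs$summary$length),
                 sum(vapply(mx, function(m) length(m$frame), integer(1))))
    # points table is consistent with the summary
    expect_equal(nrow(rs$points), sum(rs$summary$length))
    expect_equal(unname(c(table(rs$points$ridge))), rs$summary$length)
    # scale indices strictly consecutive within each ridge
    by_r <- split(rs$points$scale_index, rs$points$ridge)
    expect_true(all(vapply(by_r, function(s) all(diff(sort(s)) == 1), logical(1))))
  }
})

test_that("amplitude ties append the earlier frame; closer tips claim shared maxima", {
  ss <- build_scale_set(256)[1:2, ]
  ss$half_width <- c(50L, 50L)
  # one ridge at frame 100; two tied maxima at 90 and 110 in its window
  mx <- list(list(frame = 100L, amp = 1),
             list(frame = c(90L, 110L), amp = c(2, 2)))
  rs <- walk_ridges(mx, ss)
  tip <- rs$points[rs$points$ridge == 1 & rs$points$scale_index == ss$scale_index[2], ]
  expect_equal(tip$frame, 90L)

  # shared maximum between two ridges goes to the temporally closer tip
  mx2 <- list(list(frame = c(100L, 130L), amp = c(1, 1)),
              list(frame = 120L, amp = 1))
  rs2 <- walk_ridges(mx2, ss)
  expect_equal(rs2$summary$length, c(1L, 2L))   # ridge 2 (tip 130) claims 120
})

test_that("significance filtering enforces both criteria with strict boundaries", {
  ss <- scales_512()
  set.seed(9)
  rs <- walk_ridges(find_scale_maxima(morse_cwt(rnorm(512), ss)), ss)
  thr <- structure(list(min_ridge_length = 5L, min_max_scale = 3L,
                        exclusion = 0.9, fingerprint = attr(ss, "fingerprint")),
                   class = "ridge_thresholds")
  kept <- filter_ridges(rs, thr)$summary
  expect_true(all(kept$length >= 5L))
  expect_true(all(kept$max_scale_index > 3L))
  s <- rs$summary
  expect_equal(nrow(kept), sum(s$length >= 5L & s$max_scale_index > 3L))

  thr$fingerprint <- "other"
  expect_error(filter_ridges(rs, thr), class = "calwave_stale_calibration")
})

test_that("noise calibration is deterministic and validates on held-out noise", {
  ss <- scales_512()
  thr1 <- calibrate_thresholds(ss, n_series = 400, seed = 7)
  thr2 <- calibrate_thresholds(ss, n_series = 400, seed = 7)
  expect_identical(thr1[c("min_ridge_length", "min_max_scale")],
                   thr2[c("min_ridge_length", "min_max_scale")])

  # held-out marginal exclusion of the length criterion: between the target
  # and the discrete-quantile overshoot achieved on the training batch
  held <- calwave:::noise_ridge_stats(ss, 400, seed = 8)
  excl_len <- mean(held$length < thr1$min_ridge_length)
  achieved <- thr1$length_cdf$cdf[thr1$min_ridge_length - 1L]
  expect_gte(achieved, 0.98)
  se <- sqrt(0.98 * 0.02 / nrow(held))
  expect_gt(excl_len, 0.98 - 3 * se)
  expect_lt(excl_len, achieved + 3 * se)

  # degenerate target: near-zero exclusion pushes thresholds to their minima
  thr0 <- calibrate_thresholds(ss, n_series = 120, exclusion = 1e-6,
                               scale_conditional = FALSE, seed = 3)
  expect_lte(thr0$min_ridge_length, 2L)
  expect_lte(thr0$min_max_scale, 1L)
})

test_that("a clean single event yields one significant ridge near its peak", {
  ss <- scales_3001()
  thr <- thresholds_3001()
  cfg <- sim_config(n_events = 1, event_duration = 100, noise_sd = 1e-9,
                    snr = 69.9e9, seed = 42)  # effectively noiseless, peak 69.9
  tr <- generate_trace(cfg)
  rs <- walk_ridges(find_scale_maxima(morse_cwt(tr$values, ss)), ss,
                    keep_points = FALSE)
  sig <- filter_ridges(rs, thr)$summary
  expect_gte(nrow(sig), 1L)
  # the strongest significant ridge sits at the event peak within its
  # central window (low-amplitude trend-artifact ridges may appear
  # elsewhere: the significance criteria are amplitude-free)
  top <- sig[which.max(sig$max_amp), ]
  expect_lte(abs(top$max_frame - tr$truth$peak),
             ss$half_width[match(top$max_scale_index, ss$scale_index)])
  # the event itself is covered by exactly one raster run
  er <- events_from_ridges(filter_ridges(rs, thr), ss)
  runs <- events_from_raster(er$raster)
  expect_equal(sum(runs$start < tr$truth$end & runs$end > tr$truth$start), 1L)
})
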