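test_that("raster runs become events with dff-located centers", {
  ev <- events_from_raster(c(0,0,0,1,1,0,0,1,1,1,0,0))
  expect_equal(ev$start, c(3L, 7L))
  expect_equal(ev$duration, c(2L, 3L))
  expect_equal(nrow(events_from_raster(rep(0L, 5))), 0L)
  all1 <- events_from_raster(rep(1L, 6))
  expect_equal(all1$start, 0L)
  expect_equal(all1$end, 6L)

  dff <- c(0, 0, 0, 1, 5, 0, 0, 2, 9, 3, 0, 0)
  ev2 <- events_from_raster(c(0,0,0,1,1,0,0,1,1,1,0,0), dff)
  expect_equal(ev2$center, c(4L, 8L))
  # sum of durations equals active frame count
  set.seed(4)
  r <- as.integer(runif(300) < 0.3)
  expect_equal(sum(events_from_raster(r)$duration), sum(r))
})

test_that("ridge events use the central window, clipped at boundaries", {
  ss <- scales_3001()
  mk_rs <- function(frame, scale_index) {
    structure(list(summary = data.frame(ridge = seq_along(frame),
                                        length = rep(50L, length(frame)),
                                        max_scale_index = scale_index,
                                        max_frame = frame,
                                        max_amp = rep(1, length(frame))),
                   points = NULL, n_frames = 3001L,
                   fingerprint = attr(ss, "fingerprint")),
              class = "ridge_set")
  }
  idx <- ss$scale_index[which.min(abs(ss$half_width - 40))]
  w <- ss$half_width[match(idx, ss$scale_index)]
  er <- events_from_ridges(mk_rs(1500L, idx), ss)
  expect_equal(er$events$start, 1500L - w)
  expect_equal(er$events$end, 1501L + w)
  expect_equal(er$events$duration, 2L * w + 1L)
  expect_equal(sum(er$raster$active), 2L * w + 1L)

  er2 <- events_from_ridges(mk_rs(5L, idx), ss)
  expect_equal(er2$events$start, 0L)
  expect_equal(er2$events$end, 5L + w + 1L)

  # no significant ridges -> empty raster and event list (dead-ROI behavior)
  er3 <- events_from_ridges(mk_rs(integer(0), integer(0)), ss)
  expect_equal(nrow(er3$events), 0L)
  expect_equal(sum(er3$raster$active), 0L)

  # overlapping extents: distinct events, unioned raster
  er4 <- events_from_ridges(mk_rs(c(1500L, 1510L), c(idx, idx)), ss)
  expect_equal(nrow(er4$events), 2L)
  expect_equal(sum(er4$raster$active), 2L * w + 1L + 10L)
  # run-derived events match the raster's active frames (consistency)
  rev <- events_from_raster(er4$raster)
  expect_equal(sum(rev$duration), sum(er4$raster$active))
})

test_that("per-event F0 uses preceding frames, exclusions, and the fallback", {
  v <- c(rep(7, 30), rep(50, 10), rep(3, 20))
  ev <- data.frame(start = 30L, end = 40L)
  expect_equal(per_event_f0(v, ev[1, ], ev), 7)

  # event at frame 0: fall back to the frames after the event
  ev0 <- data.frame(start = 0L, end = 10L)
  v0 <- c(rep(50, 10), rep(3, 20))
  expect_equal(per_event_f0(v0, ev0[1, ], ev0), 3)

  # frames occupied by a previous event are excluded (brute-force oracle)
  set.seed(14)
  v2 <- rnorm(100, 10)
  evs <- data.frame(start = c(35L, 50L), end = c(45L, 60L))
  got <- per_event_f0(v2, evs[2, ], evs, lookback = 25)
  elig <- setdiff(25:49, 35:44)
  expect_equal(got, mean(v2[elig + 1L]))

  # nothing eligible anywhere -> degenerate
  evA <- data.frame(start = 0L, end = 100L)
  expect_error(per_event_f0(v2, evA[1, ], evA), class = "calwave_degenerate_baseline")
})

test_that("amplitudes follow the pathway definitions", {
  ev <- data.frame(start = 2L, end = 6L)
  d <- rep(0.4, 10)
  expect_equal(event_features(ev, d, "dff")$amplitude, 0.4)

  # wavelet pathway: F peaking at twice the local baseline gives amplitude 1
  v <- rep(5, 70)
  v[31:35] <- c(6, 8, 10, 8, 6)
  evw <- data.frame(start = 30L, end = 35L)
  f <- event_features(evw, v, "wavelet")
  expect_equal(f$f0, 5)
  expect_equal(f$amplitude, 1)

  # brute-force max over the window on random inputs
  set.seed(19)
  d2 <- rnorm(50)
  ev2 <- data.frame(start = c(5L, 30L), end = c(15L, 42L))
  got <- event_features(ev2, d2, "dff")$amplitude
  expect_equal(got, c(max(d2[6:15]), max(d2[31:42])))

  expect_error(event_features(data.frame(start = 5L, end = 5L), d2, "dff"),
               class = "calwave_invalid")
})

test_that("activation probability is the per-frame column mean", {
  r1 <- c(1L, 0L, 1L, 0L)
  expect_equal(activation_probability(list(r1, r1, r1)), r1)
  expect_equal(activation_probability(list(r1, 1L - r1)), rep(0.5, 4))
  set.seed(23)
  rs <- replicate(7, as.integer(runif(40) < 0.3), simplify = FALSE)
  expect_equal(activation_probability(rs), rowMeans(do.call(cbind, rs)))
  expect_error(activation_probability(list()), class = "calwave_invalid")
})

test_that("tiered aggregation recomputes means and runs the right tests", {
  set.seed(33)
  f <- data.frame(roi = rep(paste0("r", 1:6), each = 20),
                  slice = rep(c("s1", "s2"), each = 60),
                  group = rep(c("ctl", "drug"), each = 60),
                  duration = c(rnorm(60, 10), rnorm(60, 10)),
                  amplitude = runif(120))
  out <- aggregate_features(f)
  rm <- out$tiers$roi_means
  for (i in seq_len(nrow(rm)))
    expect_equal(rm$duration[i], mean(f$duration[f$roi == rm$roi[i]]))
  expect_equal(sum(rm$frequency), nrow(f))

  # identical groups: Mann-Whitney finds nothing at the all-events tier
  p_all <- out$comparisons$p_value[out$comparisons$tier == "all_events" &
                                   out$comparisons$measure == "duration"]
  expect_gt(p_all, 0.05)

  # method-shifted durations: Kruskal-Wallis detects separation
  g <- data.frame(roi = rep(paste0("r", 1:30), times = 3),
                  slice = "s1",
                  method = rep(c("m1", "m2", "m3"), each = 30),
                  duration = rnorm(90, 10) + rep(c(0, 1, 2), each = 30),
                  amplitude = 1)
  kw <- aggregate_features(g)$comparisons
  expect_lt(kw$p_value[kw$test == "kruskal_wallis" & kw$measure == "duration"], 0.05)

  # single-group tier is skipped with a notice
  one <- aggregate_features(transform(f, group = "only"))
  expect_true(length(one$notices) > 0)
})
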