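---
title: "Detecting Ca2+ transients: dF/F0 thresholding and wavelet ridgewalking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Ca2+ transients: dF/F0 thresholding and wavelet ridgewalking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calwave)
```

## The problem

Single-cell Ca2+ imaging reduces, after segmentation, to one fluorescence
time series per ROI. Everything downstream — event frequencies, durations,
amplitudes, and functional networks built from co-activity — depends on how
that series is turned into a set of discrete events. calwave implements two
families of detectors under one interface so that this methodological choice
can itself be studied:

* **dF/F0 thresholding** (twelve variants): normalize the trace by a
  baseline estimate F0 and mark frames exceeding a statistical threshold;
* **wavelet ridgewalking**: transform the trace with generalized Morse
  wavelets, link per-scale local maxima into ridges, and keep ridges that
  pass noise-calibrated significance criteria.

A ground-truth simulator, detector scoring against known event bounds, and
phi-coefficient network construction complete the toolkit.

## Baselines and thresholds

Three F0 conventions cover common practice:

* `f0_initial(trace, window_len = 50)` — mean of an initial window
  (2 s at 25 Hz). Cheap, but blind to drift and fragile when activity
  overlaps the window.
* `f0_minimal(trace, window_len = 250)` — mean of the sliding window
  minimizing `sqrt(var + mean^2)`. With population variance this criterion
  equals the window root-mean-square, so the selected segment is the
  quietest low-lying stretch. It adapts to where the trace is quiet, but
  requires such a stretch to exist.
* `f0_smooth(trace, window_len = 250, percentile = 8)` — the 8th percentile
  in a centered sliding window, then moving-average smoothed with the same
  window. This tracks slow drift. Windows are truncated at the series
  edges, so the estimate degrades near the start and end of the trace;
  this is inherent to the construction and deliberately not masked.

  Note the estimator is *biased low by construction* (a low percentile of
  noise sits ~1.4 noise SD below the mean); the thresholding step is
  referenced to the dF/F0 statistics, so the bias mostly cancels, but the
  three methods do not estimate the same quantity on pure noise.

`compute_dff()` forms `(F - F0)/F0` and refuses nonpositive baselines
loudly: a bleached trace whose F0 estimate crosses zero would otherwise
silently flip event signs.

Four thresholding criteria (`threshold_raster()`): the reference population
is the baseline segment (`baseline_*`) or the whole trace (`trace_*`), and
the rule is either mean + 2.5 SD (`*_sd`) or a one-sided z-test at
alpha = 0.05 (`*_z`, equivalent to mean + 1.645 SD). Reference SDs are
population SDs, consistent with the F0-minimal criterion. Ties at the
threshold are inactive. No multiple-testing correction is applied — the z
criterion is a per-frame test, which is exactly why it admits ~5% false
active frames on pure noise (and the 2.5 SD rule ~0.62%); the test suite
verifies both rates. A zero-variance reference yields an all-zero raster
with a machine-readable warning rather than an error, so batch sweeps
survive dead traces.

The baseline segment for the `baseline_*` criteria is the baseline's own
window for `initial`/`minimal`. The smooth baseline has no single window;
by package convention (`default_baseline_segment()`) the quietest
minimal-RMS window of the *dF/F0 series* is used. This convention is ours;
no canonical choice exists for a per-frame baseline.

## The Morse CWT

The analytic generalized Morse wavelet has frequency-domain form
`Psi(w) ~ w^beta exp(-w^gamma)` for `w > 0`. We fix `gamma = 3` (the
"Airy" family, minimal Heisenberg area) and `beta = 2`. Peak frequencies
are log-spaced at `density = 4` voices per octave from just below Nyquist
down to the frequency whose wavelet footprint of
`P = sqrt(beta*gamma)/pi` periods spans the series; for 3001-frame traces
this yields 44 scales. Each scale carries a central-window half-width
`round(2 * sigma_t)`, where `sigma_t` is the time SD of the wavelet's
energy envelope, computed numerically once for the mother wavelet on a
fine grid and scaled by `s` (direct discretization at working resolution
is corrupted by Nyquist-truncation ringing at the smallest scales). These
windows drive both ridge linking and event extents.

Three transform-level choices matter and are worth stating precisely:

1. **Bandpass (amplitude) normalization.** Each filter peaks at 2, so a
   unit oscillation at a scale's peak frequency transforms to a
   unit-magnitude coefficient, and white-noise coefficient SD scales as
   `1/sqrt(s)`. Noise structure therefore concentrates at the smallest
   scales — the premise of the "short noise" exclusion criterion. Under
   unit-energy normalization noise variance is flat across scales and that
   criterion loses its meaning.
2. **Linear detrending before the FFT.** Fluorescence traces carry a large
   positive offset and a bleaching trend; against zero padding these would
   dominate the large-scale coefficients and generate spurious
   boundary-anchored ridges on every trace, including dead ones. A dead,
   bleached ROI must transform to a quiet sheet.
3. **The sheet stores the positive in-phase (real) component**, not the
   modulus. Ca2+ events are upward bump-shaped deflections, to which the
   in-phase component responds at full amplitude; the quadrature component
   responds to sharp *edges*. For transients with near-instantaneous rise,
   the modulus of the onset's step response is nearly scale-invariant and
   slightly exceeds the matched-scale bump response, which would place the
   ridge maximum at the smallest scales and misclassify genuine events as
   short noise. The in-phase sheet suppresses the quadrature step response
   and anchors ridge maxima at the matched scale.

Boundary handling is zero padding to the next power of two; events close
to the series edges lose part of their wavelet support and may be missed
or truncated. This edge effect is documented, measurable in the simulator,
and deliberately not hidden.

## Ridgewalking

`find_scale_maxima()` takes strict per-scale local maxima (plateaus count
once, at their leftmost frame; endpoints never). `walk_ridges()` starts
ridges from the maxima at the largest scale and proceeds to smaller
scales: a maximum may extend a live ridge when it falls within the central
window of the preceding (larger) scale centered on the ridge tip. Several
rules need fixing beyond that sentence, and the package fixes them as
follows:

* each ridge appends the **largest-amplitude unclaimed** maximum in its
  window (amplitude ties: earlier frame);
* when one maximum is contested by several ridges, the **temporally
  closer tip** claims it (ties: earlier-initialized ridge); losers retry
  on the remaining unclaimed maxima (deferred acceptance), so a ridge
  terminates only when its window holds no unclaimed maximum;
* scale gaps terminate ridges; terminated ridges are never revived;
* leftover maxima initialize new ridges, so every maximum belongs to
  exactly one ridge — the summed ridge lengths equal the total maxima
  count (a tested invariant).

## Noise calibration

`calibrate_thresholds()` runs the full CWT + walk on Gaussian white-noise
series (unit variance — both significance statistics are amplitude-free,
so the calibration is noise-level-independent) and pools all ridges.

* `min_ridge_length` is the smallest length excluding at least 98% of all
  noise ridges by length alone.
* `min_max_scale` — the event-size criterion — is by default calibrated on
  the **conditional** CDF among noise ridges that already pass the length
  criterion. The criterion exists to remove short noise ridges that
  survive the length test; the marginal CDF is instead dominated by
  single-point and near-single-point ridges the length criterion already
  removes, and its 98% quantile would sit above the matched scale of
  short-duration events, excluding them wholesale.
  `scale_conditional = FALSE` gives the marginal variant; both CDFs are
  stored in the returned object.

For 3001-frame traces at 44 scales the defaults land at a minimum length
of ~26 scales and an event-size cutoff at scale index ~13 — proportionally
the same place in the scale set as the published operating points of this
detector family. Thresholds carry a fingerprint of the exact scale set and
`filter_ridges()` refuses a mismatched calibration: any change to the
Morse parameters, density, window multiplier or trace length requires
recalibration.

A ridge is significant iff it meets **both** criteria, with strict
boundary semantics: length >= threshold, max-amplitude scale index
strictly greater than the cutoff.

## Events and features

Raster-pathway events are maximal runs of active frames; duration is run
length; amplitude is the maximum dF/F0 inside the run. Wavelet-pathway
events are one per significant ridge, centered on the frame of maximum
amplitude, with extent equal to the central window at that scale (clipped
at the trace bounds). The extent rule is a package decision — the method
defines only the center — and the same window that drives linking is the
natural footprint; it is exposed as `extent_mult`. Overlapping extents
remain distinct events for frequency counting, while the raster is their
union.

Wavelet events are normalized per event: `per_event_f0()` averages up to
25 frames (1 s) immediately preceding the event, excluding frames inside
any other event, falling back to the frames after the event when nothing
precedes it. Amplitude is then `max((F - f0)/f0)` over the window.

`aggregate_features()` summarizes at three tiers (all events pooled,
per-ROI means, per-slice means) and runs Mann-Whitney U tests between two
conditions per measure per tier, plus Kruskal-Wallis across methods at the
ROI tier. These are standard tests called from base R, reported with
sample sizes; tiers with fewer than two groups are skipped with a notice.

## The simulator

`generate_trace()` builds
`baseline + bleach_slope*t + sum(kernels) + N(0, noise_sd)`. Kernels
(`make_event_kernel()`) are right triangles (instant rise, linear decay to
zero one frame past the end), exponentials (`tau = duration/3`, so the
labeled duration holds ~95% of the transient mass), or isosceles triangles
emulating slower astrocytic transients. Every event peaks at
`snr * noise_sd`.

Defaults define the reference conditions: 3001 frames at 25 Hz (a
two-minute recording), SNR 69.9 (high-quality somatic signals),
`baseline_level = 100` and `noise_sd = 1` arbitrary units (shot noise at
1% of resting fluorescence, typical of slice imaging), and a bleach slope
of -10% of baseline across the trace, a realistic mild photobleach.

Placement draws the required number of non-overlapping intervals uniformly
at random via the gap construction (offsets drawn uniformly from the free
space, then cumulative event widths added), which samples the same
distribution as rejection sampling of iid starts but remains exact for
tight packings. When the requested events cannot fit, the error reports
how many would; `allow_overlap = TRUE` switches to independent placement
with merged ground-truth intervals.

What the simulator does *not* model: indicator (GCaMP) rise/decay
kinetics, photon shot noise scaling with signal, movement artifacts, and
spatial structure. Tests passing on these traces demonstrate the
detectors' behavior under idealized additive white noise; real recordings
add failure modes (correlated noise, baseline steps) outside this scope.

`measure_snr()` closes the loop: it regresses the bleach out of the
non-event frames and returns per-event peak-over-residual-SD, the same
definition the `snr` parameter uses; simulated traces round-trip to the
configured SNR within sampling error (a tested property).

## Scoring and transitions

`score_raster()` reduces detection quality to two frame-counting
fractions: false positives (active frames outside all truth bounds, over
active frames) and events captured (truth frames active, over truth
frames), with the natural vacuous conventions. `sweep_performance()`
averages both over replicate traces on an event-count x duration grid,
deterministically per seed. `find_transition()` operationalizes "where the
detector begins to fail": plateau = mean captured fraction at the three
lowest counts; breakdown = the largest count still within 10% of the
plateau. The 10% rule is a package constant, exposed as `rel_drop`; any
such rule on a gradually declining curve places the breakdown well before
the visual high-to-low boundary (which sits nearer the 50% level), and
results should be read with that in mind.

Reference problem sizes, chosen to characterize each regime while keeping
a full run in the low minutes: 500 + 500 white-noise series for
calibration and held-out validation; 20 replicates per grid cell; event
counts 5-100 for the wavelet (duration 20), 2-60 at width 1 for
F0-initial, 1-12 at width 500 for F0-minimal (overlap-allowed where six
500-frame events already fill the trace).

## Networks

`phi_coef()` is the 2x2 contingency-table correlation; any zero marginal
(a constant raster) gives 0 by convention. `build_network()` keeps edges
with phi >= 0.2 (boundary kept). `graph_measures()` reports density,
mean local clustering (degree < 2 contributes 0), degree assortativity,
Louvain modularity under a fixed seed, characteristic path length over
finite distances only (the excluded-pair count is always reported), and
global efficiency as the mean inverse distance with `1/Inf = 0`. The
shorthand "efficiency is the inverse of the path length" is also reported
(`efficiency_inverse_cpl`) for comparability with that loose usage, but
the standard mean-inverse-distance definition is the primary one; the two
agree only on distance-regular graphs. Graph routines are backed by
igraph; the test suite checks them against brute-force BFS, triangle, and
exhaustive-partition oracles on small graphs.

## Numerical conventions, in one place

* Frames are 0-based; intervals half-open `[start, end)`; scale index 1 is
  the smallest scale.
* Percentiles use linear interpolation (`quantile type 7`); reference SDs
  are population SDs; windows at series edges truncate.
* Strict inequality at every threshold; documented tie-breaks everywhere
  a tie is possible (earliest window, earliest frame, earlier ridge).
* Traces that are numerically an exact line (flat or pure bleach) leave
  floating-point dust after detrending; the sheet is zeroed below
  `1e-10 * (1 + max|x|)` so that dead traces are exactly quiet.
* All randomness flows through explicit seeds; sweeps and calibrations are
  bit-reproducible given a seed.

## Known limitations

* **Edge effects**: events within roughly a wavelet footprint of the trace
  ends lose ridge support and may be truncated or missed.
* **Trend-artifact ridges**: an event biases the global linear detrend,
  and the residual tilt can form long, low-amplitude large-scale ridges
  that pass the amplitude-free significance criteria — a source of rare
  false events on otherwise quiet traces.
* **Crowding**: as events pack closer than the wavelet support at the
  scales needed to satisfy the ridge-length criterion, neighboring events
  merge at large scales and the per-event ridge branches shorten; one
  event of a close pair is then dropped. Captured fraction therefore
  declines gradually with event count — the wavelet detector's
  characteristic failure mode.
* **Very short events** (a few frames at 25 Hz) sit at scales inside the
  calibrated short-noise band and are largely invisible to the wavelet
  pathway; the dF/F0 detectors capture them easily at high SNR.
* The smooth baseline degrades at the series ends (truncated windows), and
  the trace-z criterion on event-rich traces can fail to mark anything —
  both are properties of the methods themselves that the package
  reproduces rather than repairs.
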