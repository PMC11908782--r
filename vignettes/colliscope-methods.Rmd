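---
title: "colliscope: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colliscope: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`colliscope` implements the trial-correlation analysis workflow for
two-photon calcium imaging of the auditory midbrain: stimulus design,
signal extraction, responsiveness flagging, tuning and modulation indices,
tonotopy regression, spontaneous-event detection and reporting. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the choices made where the method as usually
described leaves room for interpretation.

## The measurement model

A cell's somatic fluorescence is modeled as a baseline subject to slow
photobleaching, plus stimulus-evoked calcium transients, plus a scaled
contribution of the surrounding neuropil, plus noise:

$$F_\mathrm{cell}(t) = B(t)\,\bigl(1 + \textstyle\sum_i a_i\,k(t - t_i)\bigr)
  + c \cdot F_\mathrm{np}(t) + \varepsilon(t).$$

The pipeline inverts this model step by step:

1. **Filtering.** Separable Gaussian smoothing, spatial sigma 1 px (surface
   views) or 2 px (prism views) and temporal sigma 2 frames, kernels
   truncated at 4 sigma and normalized, reflection padding at the edges.
   `gaussianFilterTraces()` provides the temporal arm alone for workflows
   that start from extracted traces; inter-trial correlations are computed
   on filtered signals, which matters at realistic noise levels.
2. **Extraction.** Mean pixel value over each ROI mask; the neuropil
   reference is the mean over an annulus grown by binary dilation until its
   area reaches at least 4 times the ROI area, excluding every cell mask.
3. **Neuropil correction.** `corrected = cell − 0.4 × neuropil`. The
   coefficient is the conventional 0.4 and is exposed
   (`neuropilCorrect(coefficient=)`); correction happens before
   normalization.
4. **ΔF/F.** `(F − B)/B` with `B(t)` a per-cell straight line. The default
   (`percentile_trend`) fits the line robustly (Huber M-estimate, ordinary
   least squares as fallback for degenerate fits) through the running
   10th-percentile envelope of the trace, so evoked transients do not drag
   the baseline upward; `linear_trend` is a plain least-squares line for
   quiescent recordings. The envelope is evaluated on a grid of ~256 window
   positions (window 10 s): a two-parameter line gains nothing from
   per-frame evaluation. Non-positive baselines raise an error naming the
   cells rather than producing silent nonsense.

## Responsiveness and tuning

Trials are cut to `[onset − preS, onset + 500 ms + postS]` and grouped by
the (level, frequency) combination. The default window is onset to
onset + 1.1 s (`preS = 0`, `postS = 0.6`): the post-stimulus 600 ms — one
inter-stimulus interval — keeps offset responses inside the window. At
29.9 Hz that is 33 samples. Repeats may come from several runs of the same
grid; `segmentTrials()` concatenates them by combination identity and does
not model run-level batch effects.

A cell × combination is flagged responsive when the mean pairwise Pearson
correlation across repeats is **strictly** above the threshold — 0.6 for
the tone/AM grids, 0.4 for somatosensory and bimodal comparisons. Pairs
involving a zero-variance (constant) trial have no defined correlation and
contribute r = 0, with a message. Response magnitude is the trapezoidal
AUC of the trial-averaged ΔF/F from stimulus onset to the window end,
restricted to positive deflections (excitatory responses); the signed
integral is available via `positiveOnly = FALSE`.

Best tone/modulation frequency is the flagged combination with maximal AUC
across **all** levels (the alternative — a fixed level — is not used; the
per-level best is what the SMI/TMI computation pairs with the same-level
unmodulated response). Exact AUC ties resolve toward the lower frequency
and are reported. The 0 Hz AM condition is the unmodulated reference and
is never a BMF candidate. The receptive-field sum counts flagged
combinations per level; larger totals mean broader receptive fields.

Timing classes (ON / OFF / ON–OFF) are an explicit operationalization:
peaks of the trial-averaged ΔF/F in the stimulus window and the
post-offset window are each compared with k = 3 standard deviations of the
pre-stimulus baseline (so classification needs `preS > 0`). The bimodal
response index RI is the ratio of the bimodal to the auditory-alone AUC;
RI exactly 1 is classed "unchanged" (ties are logged; the dichotomy
suppressed/enhanced covers essentially all real cells).

## Tonotopy

Cells are placed along a named anatomical axis. The distance measure
defaults to the scalar projection onto the axis direction from its
starting point; for a cell on the axis line this equals the straight-line
distance from the starting point, which is available verbatim as
`method = "euclidean"`. The projection default is what makes different
axes through the same field distinguishable — the straight-line distance
from a shared origin is the same number for every axis — and cells behind
the origin (negative projection) are excluded with a message, since the
convention for them is undefined.

Distances are binned in half-open 50 µm bins; per bin the geometric means
of BTF and of distance are taken (zero distances are substituted by the
bin's lower edge + 1 µm, logged, since the geometric mean of zero is
degenerate). Degree-1 and degree-2 ordinary least squares are fitted to
the binned pairs and both R² values reported; the quadratic can never be
worse (nested models). Because the geometric mean implies multiplicative
structure, fits default to log2(BTF), with raw Hz as an option; at least 3
bins are required for the linear fit, 4 for the quadratic.

## Spontaneous events

Traces are detrended with a least-squares polynomial (default order 2,
constant term added back so the level is preserved). Each frame is then
scored against the trailing 1 s sliding **baseline** window — 29 frames at
29.9 Hz — and an event requires z strictly above 3.0. Three detector
details are deliberate design choices:

- *Baseline exclusion.* Frames already above threshold are activity, not
  baseline, and do not enter the sliding window. Without this, a transient
  contaminates its own reference within 2–3 frames, deflating z and
  truncating events.
- *Merge gap.* Crossings separated by at most 6 sub-threshold frames
  (~0.2 s, a fraction of the ~0.7 s indicator decay) belong to one
  transient; shot noise briefly dips a single event under threshold.
- *Duration floor.* An event must hold at least 3 supra-threshold frames
  (~100 ms, well below any credible GECI transient). A per-frame 3-sigma
  rule alone fires at P(t₂₈ > 3) ≈ 0.003 per frame — several false events
  per minute on pure noise at 29.9 Hz; the floor counts supra-threshold
  frames, not the merged span, so pairs of isolated noise crossings do not
  qualify.

The window SD is used by default; a global-SD mode is provided. Detection
is exactly invariant to additive offsets (traces are centered on entry).

## The synthetic-data generator

`generateCells()` and `simulateTraces()` define the study conditions under
which the pipeline is validated:

- **Kinetics:** difference-of-exponentials transient, rise 50 ms, decay
  700 ms (red-GECI-like), sampled at the frame rate and normalized to peak
  1, so the evoked peak ΔF/F equals the stated amplitude exactly.
- **Tuning:** Gaussian in log2 frequency around a latent preference,
  bandwidth 0.6–1.0 octaves; evoked amplitude scales linearly with sound
  level from a per-cell (per-compartment-settable) threshold, default
  40 dB SPL, to the grid maximum. The reported `true_btf_hz`/`true_bmf_hz`
  is the grid frequency with maximal expected response under that curve,
  which makes "exact grid recovery" well defined even for continuous
  gradient preferences.
- **Layout:** uniform positions in a 400 µm field; under the gradient
  layout the latent preference spans 3 octaves along a chosen axis with
  0.25-octave per-cell jitter; module/matrix compartments come from
  circular blobs totalling the requested area fraction (default 0.3).
- **Contamination and noise:** exponential bleaching (default off for unit
  tests, 600 s where realism matters), a shared neuropil signal with a
  weak (10%) evoked component mixed into the somatic trace at
  coefficient 0.4, and white Gaussian noise (default SD 10 a.u. against a
  ~100 a.u. baseline, i.e. evoked amplitudes of 0.5–1.5 ΔF/F sit at 4–15×
  the per-frame ΔF/F noise).
- **Phenotypes:** 85% responsive cells; modality mix 70% auditory-only,
  10% somatosensory-only, 20% bimodal; timing mix 70/20/10
  onset/offset/both; bimodal gain log-normal around 1 (σ = 0.4);
  unmodulated-noise response at 0.2–0.6 of the best response. Spontaneous
  transients are Poisson at 0.05 Hz in the stimulus-free generator (and
  off by default in the evoked generator, so noise-free fixtures are
  exactly flat where they should be).

`renderMovie()` paints each cell as a uniform disk at its trace value over
the clean neuropil field, using the same oval rasterization as the ImageJ
ROI reader, so ROI round trips and extraction recover trace values
exactly.

What the generator does **not** emulate: motion artifacts, optical
point-spread and depth-dependent blur, vasculature shadows, overlapping
somata, indicator nonlinearity and saturation, run-to-run drift, and
correlated (shared) noise beyond the neuropil term. Passing the recovery
suites therefore shows that the pipeline's inference is correct when its
own model assumptions hold — it does not certify performance on data whose
artifacts violate them (that is what the ROC validation against human
labels is for on real recordings).

## Determinism, problem sizes, file formats

Every stochastic routine takes an integer seed, uses it through an
isolated RNG scope, and restores the caller's RNG state; fixed inputs give
bitwise-identical traces, tables, JSON and PNG maps (the pipeline writes
no timestamps, and the ROI zip writer uses fixed entry metadata). The test
and acceptance suites run at desk scale by design: 8–30 cells per
simulated experiment, 10 seeds per recovery estimate, 120 s spontaneous
recordings, 96–128 px movies — sizes chosen so the whole suite documents
the method rather than exercising hardware.

Schedules are plain delimited text (six fixed columns plus commented
header metadata, lossless round trip); ROI sets are ImageJ .roi zip
archives (rect/oval/polygon records) or labeled-mask TIFFs; stacks are
multi-page 16-bit TIFFs; tables are CSV with JSON sidecars/manifests.

## Known limitations

- The baseline model is a straight line; recordings with strongly
  non-exponential bleaching over tens of minutes would need the polynomial
  detrend (spontaneous module) or an external baseline passed to
  `computeDff(baseline=)`.
- Neuropil annulus growth assumes sparse ROIs; in dense fields the
  4×-area target may be unreachable and extraction stops with an error
  naming the cell rather than silently shrinking the target.
- Repeats are pooled across runs without run-level normalization.
- The ROI writer emits oval/rect records (and reads polygons); freehand
  outlines are rasterized on read but not written.
- `populationSummary()` reports fractions of labeled pools only; it does
  not test differences between compartments — use standard tests
  (`chisq.test`, `kruskal.test`) on the returned counts.
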