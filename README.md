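# colliscope

Two-photon calcium-imaging analysis for the mouse inferior colliculus (IC)
— the auditory midbrain — and similar tonotopically organized structures.
`colliscope` takes you from stimulus schedules and motion-corrected movies
(or pre-extracted ROI traces) to responsive-cell flags, frequency tuning,
spectral/temporal modulation indices, audio–somatosensory (bimodal)
response classification, tonotopic gradient fits, spontaneous-event
detection, and pseudocolor cell maps. A ground-truthed synthetic-data
generator makes every stage testable without raw imaging data.

## Who it is for

Labs doing in vivo two-photon GECI imaging (e.g. jRGECO1a at ~29.9 Hz,
512×512) of the IC dorsal cortex or lateral cortex, presenting tone and
amplitude-modulated (AM) noise grids, who want a reproducible, scriptable
version of the classic trial-correlation analysis workflow.

## The analysis in brief

**Stimuli.** Pure tones span 5–40 kHz in half-octave steps (7 carriers) at
40–80 dB SPL in 10 dB steps — 35 combinations; AM-noise uses modulation
rates {0, 2, 4, …, 256} Hz (0 = unmodulated) at the same levels — 45
combinations. 500 ms stimuli, 600 ms inter-stimulus interval, played in
seeded random order.

**Signals.** After optional Gaussian filtering (σ<sub>xy</sub> = 1–2 px,
σ<sub>t</sub> = 2 frames), per-cell fluorescence is the mean over the ROI
mask; the neuropil signal is the mean over a surrounding annulus grown to
≥ 4× the ROI area. Then

- neuropil correction: F<sub>corr</sub> = F<sub>cell</sub> − 0.4 ·
  F<sub>neuropil</sub>
- ΔF/F: (F<sub>corr</sub> − B) / B, with B a per-cell straight-line
  baseline fitted to the running 10th-percentile envelope (photobleaching
  factored in).

**Responsiveness.** Trials of the same level × frequency combination are
cut into windows (onset → onset + 500 ms + 600 ms); a cell × combination is
flagged responsive when the mean pairwise Pearson correlation across
repeats is strictly above 0.6 (0.4 for somatosensory/bimodal comparisons).
Response magnitude is the trapezoidal AUC of the trial-averaged ΔF/F,
restricted to excitatory (positive) deflections.

**Derived measures.**

- BTF / BMF: flagged combination with maximal AUC (ties → lower frequency).
- RFS: count of flagged combinations per level and in total (receptive-field
  breadth).
- SMI = (R<sub>BTF</sub> − R<sub>unmod</sub>) / (R<sub>BTF</sub> +
  R<sub>unmod</sub>) and TMI likewise with R<sub>BMF</sub>, per sound level,
  both in [−1, 1].
- RI = R<sub>bimodal</sub> / R<sub>auditory-alone</sub>; RI > 1 enhanced,
  RI < 1 suppressed.
- Tonotopy: cells projected onto an anatomical axis, binned at 50 µm,
  geometric means of BTF and distance per bin, linear vs quadratic OLS with
  R² for both (on log2 BTF by default).
- Spontaneous events: polynomial detrend, then z > 3 against a trailing 1 s
  (29-frame) sliding baseline.

## Worked example

```r
library(colliscope)

grid  <- buildToneGrid(5000, 40000)          # 7 carriers x 5 levels
sched <- makeSchedule(grid, nRepeats = 5, seed = 1)
cells <- generateCells(30, layout = "gradient", seed = 2)
expt  <- simulateTraces(cells, sched, noiseSd = 10, seed = 3)

corr <- neuropilCorrect(gaussianFilterTraces(traces(expt)), 0.4,
                        gaussianFilterTraces(neuropil(expt)))
dffT <- computeDff(corr, frameRate(expt))
tens <- segmentTrials(dffT, sched)
tab  <- flagResponsive(tens, threshold = 0.6)
bf   <- bestFrequency(tab, "tone")

cen <- cbind(x_um = cells$x_um, y_um = cells$y_um)
rownames(cen) <- cells$cell_id
fit <- assessTonotopy(cen[bf$cell_id, ], bf$best_hz, axisFromAngle(0))

tens; head(bf, 3); fit
```

Printed output from this session:

```
TrialTensor: 30 cells x 35 combos x 5 repeats x 33 samples (1.10 s)
   cell_id   best_hz  best_auc level_db
1 cell_001  7071.068 0.7044267       80
2 cell_002 20000.000 0.8130241       80
3 cell_003 14142.136 0.3911489       80
TonotopyFit along 'axis_0deg' (50 um bins, log2 scale): 8 bins
  R2 linear = 0.949, R2 quadratic = 0.952
```

`tens` holds 1.1 s trial windows (33 samples at 29.9 Hz). `tab` has one row
per cell × combination with `mean_r`, the `responsive` flag and the AUC
magnitude; 22 of 30 cells end up responsive, and `bf` holds each one's best
tone frequency in Hz (cell 1 prefers 7.1 kHz at 80 dB SPL). The fit says
the implanted 3-octave gradient along the x axis is recovered with a linear
R² of 0.95, and the quadratic fit is (as the nested model) at least as
good.

A command-line interface wraps the same functions:

```sh
exec/colliscope schedule --type tone --seed 1 --out sched.csv
exec/colliscope simulate --n-cells 20 --seed 1 --out simdir
exec/colliscope run --stack simdir/movie.tif --rois simdir/rois.zip \
                    --schedule simdir/schedule.csv --out results
```

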