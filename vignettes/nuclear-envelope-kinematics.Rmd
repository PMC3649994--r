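---
title: "Quantifying chromosome-end aggregate mobility on the nuclear envelope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome-end aggregate mobility on the nuclear envelope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrack)
```

## The biological problem

At the onset of meiotic prophase in *C. elegans*, the chromosome end
carrying the pairing centre attaches to the inner nuclear envelope, where
SUN/KASH bridges couple it to cytoplasmic dynein. The envelope-spanning
SUN-1 protein concentrates at these attachment sites into mobile
aggregates: a few large *patches* in wild-type transition-zone nuclei,
versus many small, sluggish *foci* in movement-defective mutants. The
mobility of these aggregates — quantified from 15-minute SUN-1::GFP
time-lapse movies as projected speed distributions and per-track "arc
coverage" — is the readout that links motor-driven chromosome-end movement
to homolog pairing and, ultimately, chiasma formation scored at diakinesis.

`netrack` implements the full quantitative chain for such studies:

1. a seeded synthetic movie generator with known ground truth,
2. projection, background subtraction and drift registration,
3. spot detection with focus/patch classification (1.1 µm boundary),
4. optimal-assignment track linking with fusion/split annotation,
5. projected-speed and arc-coverage kinematics,
6. the cytological statistics (pairing Fisher tests, DAPI-body/bivalent
   accounting with Mann-Whitney comparisons, count histograms,
   synapsis-association tallies, respiration normalization).

Because no raw movies or per-nucleus scoring tables from such studies are
publicly deposited, every stage is exercised against synthetic data whose
generative parameters are known. The synthetic generator is first-class,
tested code: it defines the study conditions under which the pipeline's
guarantees are stated.

## The motion model

Aggregate motion on the envelope is modelled as a two-state process
*on the true 3D sphere* (radius 2 µm by default, the conventional size of a
germline transition-zone nucleus), and only projected to 2D at analysis
time — the measured quantities are *projected* speeds, so projection loss
must be part of the simulation, not an afterthought.

* **Run state** — processive motion along a great circle at `run_speed`
  (default 190 nm/s, the characteristic dynein-driven transport speed),
  with exponentially distributed run durations (`run_persistence`).
* **Dwell state** — tangential diffusion with coefficient
  `diffusion_coeff` (µm²/s); `pause_fraction` sets the long-run fraction
  of time spent dwelling.

This is phenomenological, not a biophysical stepping model: its purpose is
to produce speed and arc distributions with the right qualitative
structure. Fusion (3D proximity below `fusion_radius`, volumes add) and
splitting (Poisson rate `split_rate`, volume halves) reproduce the
frequent merge/split events seen in live imaging.

Three presets bundle motion parameters with an aggregate census:

| preset | aggregates | diameter (µm) | character |
|--------|-----------|---------------|-----------|
| `wt`   | 3 patches | 1.2–1.6 | frequent 190 nm/s runs (pause fraction 0.40) |
| `spd3` | 8 foci    | 0.55–0.90 | rare short runs (pause fraction 0.93), moderate diffusion |
| `jf18` | 6 foci    | 0.55–0.90 | pure slow diffusion (3·10⁻⁴ µm²/s) |

The preset parameter values are this package's own calibration, chosen once
so that the downstream ordering — wild type > spd3 > jf18 in mean arc and
in the fraction of fast (≥ 160 nm/s) intervals — holds through the full
pipeline; they are deliberately not presented as measured quantities.

## Image formation

The acquisition geometry defaults mirror live SUN-1 imaging: 181 frames at
5 s (15 min), 1 µm-spaced z sections, ~0.107 µm pixels. Each aggregate is
rendered as a 3D Gaussian whose photon count is proportional to its volume
(patches outshine foci) and decays with a photobleaching half-life; the
lateral sigma combines the object size (FWHM = diameter) with a 0.15 µm
PSF, the axial sigma uses a 2× wider PSF. Poisson shot noise on signal
plus camera background, and Gaussian read noise, complete the model
(`shot_noise = FALSE` gives deterministic renders for calibration). The
default photon budget puts a 1 µm aggregate at a peak-to-background SNR
near 10. One root seed drives everything; per-nucleus substreams are
derived from it so nuclei are independent yet exactly reproducible.

What the generator does *not* emulate: neighbouring nuclei and gut
autofluorescence (scenes contain only the simulated nuclei), chromatin
texture, z-dependent aberrations, and stage drift is off by default.
Passing tests therefore demonstrate correctness of the measurement chain
under controlled optics, not robustness to every artefact of a real
acquisition.

## The measurement chain and its numerical choices

**Projection and background.** Maximum-intensity projection over z, then
subtraction of a large-kernel Gaussian background estimate (sigma 10× the
spot scale; output clipped at 0). The blur uses border-renormalised
weights, so flat fields are removed exactly.

**Registration.** Per-frame translation against frame 1 (not pairwise, to
avoid drift accumulation) by cross-correlation, refined to subpixel
precision with an upsampled matrix DFT (factor 20); frames are resampled
by the inverse shift via the Fourier shift theorem. Integer shifts are
recovered exactly and subpixel shifts to better than 0.1 px on structured
scenes. In the pipeline wrapper registration is **off by default**: drift
estimation needs static structure to lock onto, which real fields provide
but a synthetic scene consisting solely of moving puncta does not — there
the correlation peak chases the aggregates themselves.

**Detection.** Difference-of-Gaussians candidates across a geometric scale
ladder spanning the expected diameter range, non-maximum suppression
across space and scale, then a photometric cut: the local peak must exceed
`threshold_snr` robust noise units (noise estimated per frame by MAD).
The single-frame default is 3 (the conventional blob-detection floor); the
movie-level pipeline uses 5, which on 181-frame movies suppresses the
noise-spike false positives that a 3σ cut admits at the finest scale.
Centroids are intensity-weighted within a scale-matched window, iterated
twice. Diameters are measured as the equivalent-circle diameter of the
connected region above half the peak (the FWHM for a Gaussian spot,
intensity-scale invariant); the focus/patch boundary at 1.1 µm is
half-open with equality assigned to *patch*.

**Linking.** Exact minimal-cost assignment (Jonker–Volgenant/Hungarian)
between track heads and detections per frame pair, squared-displacement
cost under a hard gate of 1.5 µm per 5 s (300 nm/s — comfortably above
the 190 nm/s motor speed so the fast tail is never truncated), with
birth/death slack at gate², gap closing up to 2 missed frames, and an
infinitesimal lexicographic tie-break for determinism. Fusion events are
annotated when a track dies next to a surviving neighbour, splits when a
track is born next to a pre-existing one; a track end followed within a
few frames by a birth at the same place is classified as a detection
dropout, not an event (`rebirth_window`, default 6 frames ≈ the timescale
over which two spots crossing in projection re-separate).

**Kinematics.** Projected speeds are per-interval displacements divided by
elapsed time (nm/s), pooled per nucleus or genotype; gap-spanning
intervals are excluded from threshold fractions by default. The reported
fractions follow the literal phrasing of the source analyses: *above*
40 nm/s is strict (>), *160 nm/s and higher* is inclusive (≥). Arc
coverage converts a track's total projected path length to the angle it
would subtend along the nuclear circumference
(`arc = path / (2πR) · 360`), which is additive, rotation invariant, and
monotone in distance travelled — the plotting convention of the source
analyses is described only in prior work, so this operationalisation is
the package's own, documented choice. Track overlap is the fraction of
rasterised (Bresenham, 1 px polyline) visited pixels shared by two or
more tracks.

## What tracking can and cannot promise

Two physical limits surface repeatedly in validation and deserve to be
stated plainly:

* **Projection conflation.** Two aggregates at different depths can
  project within the optical merge distance (~2 effective sigmas). While
  conflated they yield one detection; recall measured against ground
  truth necessarily drops in crowded patch-scale scenes. Detection
  guarantees (recall/precision ≥ 0.95) are therefore stated for
  resolvable, focus-scale scenes at SNR ≥ 5.
* **Identity through encounters.** At 5 s sampling a 190 nm/s run covers
  ~0.95 µm per frame — comparable to inter-aggregate spacing — and after
  a close encounter no gated nearest-neighbour linker (motion-model
  prediction is deliberately out of scope) can tell which spot is which.
  Track *fragments* remain individually correct, which is why live-imaging
  studies routinely report several-fold more tracks than aggregates per
  nucleus. Identity guarantees are stated for tracks that never close
  within the merge distance; speed and arc statistics, which pool over
  intervals, are insensitive to fragmentation (speed-fraction recovery is
  within 5 percentage points of ground truth end to end).

## Cytology statistics

Diakinesis accounting uses the 2n = 12 karyotype identity: with
`bodies = bivalents + univalents` and `2·bivalents + univalents = 12`,
the mean bivalent count is simply `12 − mean bodies` (6 bodies ⇔ 6
bivalents, 12 bodies ⇔ 12 univalents). The oocyte simulator draws
bivalents as Binomial(6, chiasma probability), so the estimator
`(12 − mean bodies)/6` recovers the chiasma probability — a property the
tests verify.

Pairing is scored as "one focus per nucleus": a single signal, or two
signals within 0.75 µm in 3D (inclusive; the conventional *C. elegans*
FISH merge distance — the source protocol states no number, so ours is
documented and configurable). Zone comparisons use two-sided Fisher exact
tests, uncorrected for multiple testing, matching field practice of
reporting raw per-zone p-values. Germline positions are supplied
normalised to [0, 1] and binned into equal-length zones (position 1.0
belongs to the last zone) because absolute gonad landmarks cannot be
reconstructed from score tables.

Body-count comparisons use a two-sided Mann–Whitney test with a
tie-aware exact permutation distribution (counting dynamic programme over
doubled midranks) whenever both samples have ≤ 20 observations, and the
normal approximation with tie and continuity correction above that.
The cutoff matters because body counts are small tied integers:
`stats::wilcox.test` declines exact p-values under ties, while at these
sample sizes the exact distribution is cheap. The two-sided exact p-value
is `P(|W − μ| ≥ |w − μ|)`, which coincides with the classical doubled
one-tail for untied data.

Focus/patch/RAD-51 count histograms report per-zone percentages over
configurable bins (default 0, 1–2, 3–5, 6–10, >10; the exact source
binning is not fully legible, hence configurable), with elongated RAD-51
structures tallied as a separate "stretch" category. Synapsis association
classifies one or two X-chromosome pairing-centre signals against SC
polylines within 0.3 µm. Respiration records normalise the mean of the
7 per-well oxygen-consumption measurements by the counted worms in that
well and compare genotypes with Welch's t-test across well replicates.

## Reproducibility and problem sizes

`run_pipeline()` executes simulate → project → detect → link → summarise
per condition from a single YAML/R configuration with one root seed, and
writes a manifest with MD5 content hashes; identical configuration and
seed give byte-identical artifacts. `render_report()` draws the standard
three panels per condition (track map, arc fan, speed distribution) with
axes shared across conditions.

The validation suite runs at deliberately chosen problem sizes: full
acquisition geometry (181 frames) for the detection/recovery and
preset-ordering checks with 10 nuclei or 10 replicates; shorter movies
(40–120 frames) for unit-level properties; 100-seed cohorts for the
statistical-magnitude checks; and exhaustive enumeration domains
(all 2×2 tables with N ≤ 20, all 3-letter tied arrangements with n ≤ 6,
all ≤ 4-spot × 5-frame linking instances) for the exact-test and
assignment oracles. These sizes give stable pass/fail behaviour while a
full run of the suite stays in the minutes range on one CPU.

## Known limitations

* Motion is phenomenological; no force balance, no chromatin tether
  elasticity, no dynein stepping statistics.
* Detection operates on 2D projections (as the source analyses tracked
  projections); 3D detection is out of scope.
* Nucleus geometry comes from ground truth (synthetic) or a supplied ROI;
  there is no automatic nucleus segmentation.
* No multiple-testing correction is applied anywhere, by design, to match
  the conventions of the analyses being reproduced.
* Mean-squared-displacement analysis and genotype-level statistical tests
  on speed distributions are intentionally absent (none are reported in
  the analyses this package reproduces).
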