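---
title: "Quantifying calcium-channel splice isoforms at the active zone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium-channel splice isoforms at the active zone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azquant)
```

## The measurement problem

Drosophila has a single Ca_v_2 calcium-channel gene, *cacophony* (cac),
whose mutually exclusive splice exons produce isoforms that may differ in
where they localize and what they contribute to transmitter release at
larval neuromuscular-junction (NMJ) active zones (AZs). Asking whether
two isoforms differ requires four quantitative readouts, each of which
this package implements end to end, together with seeded simulators that
generate inputs with known ground truth:

1. **How many channels sit in one AZ?** Answered by photoconverting
   mEOS4b-tagged channels and counting bleaching steps
   (`count_channels_trace()` and friends).
2. **Do tagged channels colocalize with the AZ scaffold?** Answered by
   Pearson/Manders coefficients under automatic Costes thresholds inside
   an HRP membrane mask (`coloc_within_mask()`).
3. **Where exactly does the channel cluster sit in the scaffold ring?**
   Answered by nanoscopy puncta detection and in-plane nearest-punctum
   distances (`detect_puncta()`, `nearest_brp_distance()`), plus
   scaffold-masked intensity comparisons and per-AZ isoform-content
   classification.
4. **What does transmission look like?** Answered by evoked-EPSC
   metrics from two-electrode voltage clamp: amplitude, half-width,
   charge, paired-pulse ratios, depression kinetics and mean quantal
   content (`measure_epsc()`, `compute_ppr()`, `fit_depression()`,
   `mean_quantal_content()`).

## Channel counting from photobleaching traces

### Model

A movie is acquired at 20 Hz (pixels 71 nm) with an initial 250-frame
illumination phase, after which UV light photoconverts the green mEOS4b
tag to its red form. The red fluorescence of one AZ — summed over a
5 x 5-pixel ROI after annulus background subtraction — rises as channels
convert and then decays to zero as they irreversibly bleach, passing
through reversible dark states ("blinks") on the way. The channel count
is

$$N = \frac{F_{\text{peak}}}{F_1},$$

where $F_{\text{peak}}$ is the maximal converted fluorescence shortly
after UV onset and $F_1$ the fluorescence of a single molecule,
estimated from the discrete steps that isolated blinking/bleaching
events produce late in the trace. Counts are reported un-rounded; means
over AZs are fractional by design.

### Step fitting

Steps are found by exact penalized least-squares change-point
segmentation (a pruned dynamic program; `detect_steps()`). The penalty
per change point defaults to $2\hat\sigma^2\log n$ with $\hat\sigma$
from the median absolute first difference — a BIC-like choice that keeps
flat noisy traces unsegmented while recovering steps at
signal-to-noise ratios of a few. Two numerical guards matter:

* a penalty floor of $10^4\, n\, \varepsilon\, \overline{x^2}$ keeps the
  penalty above the rounding error of cumulative-sum SSE evaluation, so
  noiseless traces segment uniquely (ties go to fewer change points);
* the minimum segment length is 2 frames.

On traces short enough to enumerate, the segmentation provably equals
brute-force search over all change-point placements; the test suite
checks this on a 50-case fixture set.

### Unitary intensity

Step amplitudes late in the trace (at or beyond the midpoint of the
post-onset sequence) form a multimodal distribution — single events at
$F_1$, coincident double events at $2F_1$. The estimator collects
downward *and* upward step magnitudes, excludes steps flanked by
segments shorter than 3 frames (shorter events are averaged with bright
frames and yield fractional amplitudes), excludes amplitudes below
`peak / max_channels` (with at most a few dozen channels per AZ, nothing
dimmer can be one molecule), isolates the smallest mode by exact 1-D
dynamic-programming clustering ($k \in \{1,2,3\}$ by mean silhouette;
deterministic, no RNG), and returns its median. AZs with no usable late
events fail QC with an explicit reason and are excluded from cohort
summaries, which report per-animal means and the mean of animal means
per genotype, flagging animals with fewer than 30 passing AZs.

### What the simulator emulates

`simulate_bleach_traces()`/`simulate_bleach_movie()` step each
fluorophore through a 4-state Markov chain per frame — unconverted
$\to$ converted-bright $\leftrightarrow$ converted-dark $\to$ bleached —
with defaults `conversion_rate = 0.1`, `bleach_rate = 0.001`,
`blink_off_rate = 0.003`, `blink_on_rate = 0.15` per frame. The
published counting method does not constrain mEOS4b blinking kinetics,
so these are free parameters chosen once to give fast, near-complete
conversion, bleaching distributed over the acquisition, and a handful of
isolated single-molecule events per trace late in the sequence. Movies
render each AZ as a Gaussian spot (unit-integral PSF, default
$\sigma = 1.3$ px) with optional rigid drift, constant background and
Gaussian camera noise (Poisson shot noise available by flag but off by
default — additive noise suffices for estimator testing). Trace-level
simulation adds the noise per trace sample; the movie path adds it per
pixel, and the 5 x 5 ROI sum then carries $\sqrt{25}$-fold noise. One
top-level seed derives independent child streams per AZ, so adding an AZ
never perturbs the others.

The recovery study conditions (300 traces, true counts uniform in 4..16,
unitary 100 a.u., trace SNR 10, 2500 frames, onset at frame 250) are
fixed in the acceptance suite, which requires a mean absolute counting
error of at most one channel and exact recovery of noiseless staircases.
What passing does **not** show: robustness to the spatially varying
background, out-of-focus light and incomplete photoconversion of real
TIRF recordings, which have no synthetic counterpart here.

### Drift correction

`correct_drift()` registers each frame to the temporal-median image by
FFT cross-correlation with parabolic subpixel refinement and bilinear
resampling. Frames that barely correlate with the reference (normalized
peak below 0.2 — e.g. pure-noise frames before photoconversion) carry no
registration information and are passed through unshifted rather than
chasing a spurious peak.

## Colocalization with Costes thresholds

All coefficients are computed strictly inside a membrane mask built from
the HRP channel (`build_mask()`: Gaussian smoothing, Otsu threshold on
the voxel histogram, removal of components below 9 voxels). Voxels
outside the mask never contribute — to the regression, the thresholds or
the coefficients.

`costes_thresholds()` fits the orthogonal (total least squares)
regression $b \approx \beta a + \alpha$ over masked voxels — orthogonal
because both channels carry noise — then lowers a candidate threshold
$T_a$ through the observed intensities of channel $a$ (with
$T_b = \beta T_a + \alpha$) until the Pearson correlation of the voxels
below *both* thresholds first reaches zero or below. Ties break toward
the lower threshold by scan order. Two edge policies: perfectly
proportional channels never cross (the correlation below threshold stays
1) and return the minimum intensities flagged `"no Costes crossing"`;
globally anti-correlated channels have an empty below-threshold set
along their negative-slope regression line at every candidate, and are
treated as crossing immediately at the top of the scan. For images with
more unique intensities than `max_candidates` (default 1024) the scan
descends through an evenly decimated subset; below the cap it is
exhaustive and equal to brute force, which the acceptance suite verifies
on constructed 64 x 64 pairs to machine precision along with the
Pearson/Manders direct-summation identities.

Manders coefficients default to the Costes-thresholded variant
($M_1$ = fraction of channel-a intensity in voxels where $b$ exceeds
$T_b$; $M_2$ symmetric); passing `thresholds = NULL` gives the
any-positive-signal variant, since which of the two the original
analysis used is not determinable.

## Puncta geometry, masked intensity and isoform content

### Geometry

In nanoscopy stacks (defaults: 24.44 nm in-plane sampling, 191.69 nm
z-steps) each AZ appears as a central cac cluster ringed by four brp
scaffold puncta. `detect_puncta()` smooths with a 1-voxel Gaussian,
takes local maxima per focal plane above `median + k MAD` of the masked
voxels ($k = 6$; at the conventional 3 the false-maximum rate over
$\sim 10^5$ background voxels ruins precision, while 6 stays an order of
magnitude below a punctum's smoothed peak), enforces a 3-voxel minimum
separation brightest-first (which also removes cross-plane duplicates of
one punctum), and refines centers by intensity-weighted centroid of the
above-threshold signal. On noiseless images the MAD is zero, so the
threshold falls back to 2% of the dynamic range, keeping PSF side-lobes
and z-smear ghosts out. Positions use one convention everywhere:
0-based voxel indices, axis order $(z, y, x)$, centers at voxel centers,
physical position = index x voxel size.

`nearest_brp_distance()` takes, for each cac punctum, the Euclidean
in-plane $(y,x)$ distance to the nearest brp punctum with the identical
plane index — no z-interpolation, matching an analysis done within
single optical sections — and counts cac puncta with no same-plane
partner as exclusions. The acceptance suite requires the median
recovered distance on noiseless rings of 106 nm to sit within half an
in-plane voxel of truth, and within 2 voxels under default noise.

### Masked intensity and normalization

`masked_intensity()` measures a signal channel inside the scaffold mask,
optionally dilated in-plane (an AZ's ring must be dilated by ~3 voxels
for its component to cover the central cluster), with per-AZ components
merged when separated by fewer than 2 voxels. `normalize_to_control()`
divides by the control-group mean, so controls normalize to 1.0 and the
operation is idempotent. The two-condition study (true per-AZ means 2:1,
three simulated animals of ~30+ AZs each per condition) must recover a
genotype-mean ratio in [0.45, 0.55].

### Content classification

An AZ is called positive for a tagged isoform when its mean masked
intensity exceeds the background median plus $k$ background MADs
($k = 3$), with the background sampled inside the HRP mask but outside
the dilated scaffold components. Because the tested statistic is a
*mean over a component*, the background spread is scaled by
$1/\sqrt{n_{\text{voxels}}}$ — the standard error of a background mean
of the same size; with `n_voxels = 1` the per-voxel rule is recovered.
Without this matching, a diffraction-limited cluster diluted over a
ring-shaped component (mean a few a.u.) can never clear a per-voxel
threshold. How the original analysis called an AZ "containing" an
isoform is not stated anywhere; this rule is the package's own
definition and the main caveat when comparing content fractions.

### What the synapse simulator emulates

`simulate_synapse_stack()` renders boutons (smoothed ellipsoidal HRP
signal), places AZs inside them with a realistic ~0.6 µm
nearest-neighbor spacing (so per-AZ mask components remain separable),
and draws each AZ's content class from configurable fractions (defaults
95% dual-isoform, 5% single-isoform, matching the regime the method is
meant to detect, with a 2:1 default intensity ratio between the two
isoform channels). Spots are Gaussian with the PSF as their width;
with `psf_sigma = 0`, point masses are split trilinearly over the eight
neighboring voxels, which preserves subvoxel centers exactly (plain
voxel snapping biases the nearest-of-four distance median about one
voxel low). Not emulated: STED depletion physics, vectorial PSFs,
tilted-AZ side views (all rings lie in one focal plane), antibody
labeling noise, and tissue background structure.

## Evoked-transmission metrics

Sweeps (50 kHz) are filtered offline with a zero-phase Gaussian kernel
whose response is −3 dB at the requested cutoff:
$\sigma_t = \sqrt{-\ln(10^{-3/20})/(2\pi^2)}/f_c \approx 0.1325/f_c$ s,
normalized to unit sum so the DC gain is exactly 1. The acceptance suite
asserts −3 dB ± 0.1 dB at 360 Hz, DC gain within $10^{-6}$, and zero
phase.

`measure_epsc()` defines the baseline as the mean over a 5 ms window
ending 0.5 ms before the stimulus, the amplitude as the positive
magnitude of the peak inward deflection within a 20 ms response window,
the half-width by linear interpolation at half-amplitude, and the charge
as $\int(\text{baseline} - I)\,dt$ (nA·s = nC), by default counting only
samples below baseline. The response and baseline windows are not
specified by the source methods and are configurable. Within summating
high-frequency trains, amplitudes are measured from the pre-train
baseline (consistent with burst charge "below baseline prior to
stimulation"); for 1 Hz trains, where the trace returns to rest, the
per-stimulus local baseline applies. Amplitudes at or below 3 pre-stimulus
SDs are flagged `"no event"`.

Paired-pulse ratios are reported under both published schemes — mean of
per-sweep $A_2/A_1$ (scheme A) and ratio of mean amplitudes (scheme B) —
which coincide exactly when all first amplitudes are equal. The
coefficient of variation across animals is reported per inter-pulse
interval. Depression trains are fitted per animal with
$A(t) = P + (A_0 - P)e^{-t/\tau}$ by Levenberg–Marquardt least squares,
initialized from the first amplitude, the mean of the last 20% of
points, and the half-crossing time; constant trains are flagged
degenerate rather than fitted. At the reference conditions (plateau
$0.8 A_0$, $\tau = 5$ s, 60 points at 1 Hz) the noiseless fit is exact
to within 1%. With 5% multiplicative amplitude noise the per-fit $\tau$
scatter is large — the decay spans only 20% of $A_0$, so that noise is
25% of the fitted component and single-fit errors of ~20% are
information-limited, not an estimator defect — and the recovery check
is therefore evaluated on the aggregate (mean $\hat\tau$ over
100 seeds within 15%), mirroring the per-animal-fit-then-average
procedure used experimentally. Mean quantal content divides the mean
evoked amplitude by the mean miniature amplitude of the same recording;
miniature *detection* is deliberately out of scope — the function
ingests amplitude lists (from the simulator's truth or any external
detector).

The TEVC simulator adds a difference-of-exponentials kernel (1 ms rise,
6 ms decay, peak-normalized) per stimulus, scaled for twin pulses by a
per-IPI paired-pulse ratio and for trains by the geometric recursion
$A_{k+1} = P + (A_k - P)e^{-\Delta t/\tau}$ (whose closed form the tests
re-derive independently), plus Poisson miniatures with lognormal
amplitudes and Gaussian noise. EPSCs are negative (inward) deflections
throughout.

## Pipeline, reproducibility and problem sizes

`az_load_config()` validates a declarative YAML configuration (unknown
keys rejected with a closest-match suggestion, defaults filled, a stable
MD5 hash attached); `az_run_pipeline()` executes the selected stages in
dependency order, writes per-stage CSVs plus a JSON run report whose
counts reconcile (input = passed + excluded), and derives every random
stream from the single configured seed, so reruns are byte-identical —
asserted file-by-file in the acceptance suite.

Simulation sizes throughout tests and the acceptance script were chosen
as the smallest cohorts at which the recovery targets are statistically
meaningful: 300 traces for counting MAE, 3 animals x ~32 AZs per
condition for the two-fold comparison, 20 image pairs for the Costes
oracle, 3 stacks per geometry condition, 100 seeds for the depression
study, 50 fixture traces (length ≤ 60 so full enumeration of up to 4
change points stays exact) for the segmentation oracle.

## Known limitations

* The counting estimator assumes conversion is fast relative to
  bleaching; if most molecules bleach before the population peak, the
  peak under-counts. QC flags only the absence of late events, not this
  regime.
* Rare traces whose late events are all coincident doubles can still
  halve the unitary estimate; at the study conditions this affects on
  the order of 1% of traces and is visible as isolated large errors.
* Distances are in-plane only; a tilted AZ would foreshorten its ring,
  a geometry the simulator does not generate.
* The content-classification rule (presence threshold) is this package's
  own construction; content fractions from real data depend on it and on
  labeling efficiency, which is not modeled.
* PPR at short intervals is measured against the local pre-pulse
  baseline while the first response still decays, which slightly
  underestimates unit ratios (~5% at a 10 ms interval with a 6 ms decay
  kernel); this mirrors the stated measurement convention rather than
  correcting for summation.
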