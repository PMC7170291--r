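---
title: "The structured noise index: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The structured noise index: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniqc)
```

## The problem

A gamma camera's daily flood-field image is the central element of nuclear
medicine quality control: a spatially uniform source is imaged and the
result inspected for nonuniformities caused by failing photomultiplier
tubes, drifting energy corrections, or stale uniformity maps. Traditional
pixel-value metrics such as integral uniformity (IU) respond to the
*amplitude* of excursions and are easily swamped by counting noise, so
subtle but clinically visible structure -- a faint blob, a ripple, a band --
often passes numerically while failing visual inspection.

The structured noise index (SNI) attacks the problem in the frequency
domain: counting (quantum) noise has a flat ("white") power spectrum whose
level is known exactly from the count density, so anything *above* that
floor is structure. Weighting the comparison by a model of human contrast
sensitivity makes the score track what an expert would actually notice.

## The model

For an image patch $I(x_i, y_j)$ with pixel pitch $\Delta x, \Delta y$, the
single-realization 2D noise power spectrum is

$$ NPS(u, v) \;=\; \frac{\Delta x\, \Delta y}{N_x N_y}
   \left| \sum_{i,j} \left( I(x_i, y_j) - \bar I \right)
   e^{-2\pi i (u x_i + v y_j)} \right|^2 $$

in units counts$^2$·mm$^2$ (`compute_nps_2d()`). For Poisson counting noise
the per-pixel variance equals the mean, so the quantum component of the NPS
is flat at $\bar I\,\Delta x\,\Delta y$ (`quantum_nps_level()`); the ideal
ensemble average over many regions is *not* taken -- each ROI is one
realization with global-mean subtraction only, no windowing, and an
optional (default off) 2D linear detrend hook.

Both the input and the structure spectrum are weighted by the radial human
visual response

$$ V(r) \;=\; r^{1.3} \exp(-c\, r^2), $$

with $r$ in cycles/degree and $c = 1.3/(2 r_*^2) = 0.040625$ chosen in
closed form so the response peaks at $r_* = 4$ cycles/degree under the
reference viewing geometry (150 cm distance, 6.5 cm displayed image). Image
frequencies map to visual angle through the small-angle relation
$r = f_{\text{cyc/px}} \cdot (W/\text{display}) \cdot d \cdot \pi/180$,
where $W$ is always the *full* image width in pixels: the display size
refers to the whole flood, so a 64-px roving ROI occupies $64/W$ of it and
every ROI shares one frequency mapping. The SNI is then

$$ \mathrm{SNI} \;=\;
   \frac{\int NPS_{\text{structure}}\, V \, du\, dv}
        {\int NPS_{\text{input}}\, V\, du\, dv} \in [0, 1], $$

with discrete sums over all frequency bins (the DC bin carries zero
weight). 0 means purely quantum noise; values near 1 mean structure
dominates.

### Quantum subtraction at $M = 1$: why the integral is clamped, not the bins

With a single realization each non-DC NPS bin fluctuates approximately as
$q \cdot \mathrm{Exp}(1)$ about the quantum level $q$. Summing per-bin
clamped residuals $\max(NPS - q, 0)$ therefore has expectation
$q e^{-1} \approx 0.37 q$ per bin *even for a perfectly clean flood*, and
drives the null image score above the alert thresholds -- in simulation,
every defect-free 5M-count flood would alert. Because the integrals in the
SNI ratio are linear, subtracting the quantum level from the *integrated*
filtered power and clamping once,

$$ \text{numerator} = \max\Big( \textstyle\sum_b w_b\, NPS_b \;-\;
   q \sum_b w_b,\; 0 \Big), $$

is the same subtraction without the order-statistics bias; `sni_for_patch()`
does exactly this. The per-bin clamped spectrum is still available from
`structured_nps()` for display. Under this rule defect-free 256×256 floods
at 5×10⁶ counts score ≈0.27 on average at the image level, comfortably
below the 0.50 lower alert threshold, while a 20% PMT dropout scores ≈0.90.

### Weighting exponent

Whether the NPS should be weighted by $V$ or by $V^2$ (treating $V$ as an
amplitude transfer function) is genuinely open; both are implemented via
`viewing_geometry(filter_exponent = )`. The default is $V^1$: it spreads
weight over more frequency bins, which lowers the variance of the null
score (structure-free 64×64 patches at 1000 counts/pixel stay below 0.2 in
≈96% of realizations, versus ≈90% under $V^2$) without materially changing
detection. Absolute SNI values -- and therefore the 0.50/0.60 thresholds --
depend on this choice, so it is a configuration field, not a constant.

## ROI scheme

Two large equally sized overlapping square ROIs cover the central 90% of
the field: side $s = \mathrm{round}(0.9 \cdot \min(\text{rows, cols}))$,
anchored at the top-left and bottom-right corners of the centered
90%-region (`large_rois()`); on a square image they coincide and are
deduplicated. Local defects are caught by a 64×64 roving window shifted in
16-px increments over the whole image (`roving_rois()`), with one extra
edge-clamped position per axis when the span is not step-aligned -- a
256×256 flood yields 169 roving positions. The image score is the maximum
over all ROIs (`image_sni()`), ties broken by the earliest ROI with the
large squares ordered first. Dimension rounding is half-up and centered
regions place any odd leftover margin pixel at the bottom/right; the same
conventions are used by the UFOV/CFOV masks.

## Artifact image

`artifact_image()` zeroes every Fourier coefficient whose magnitude is
consistent with counting noise and inverse-transforms the rest. Under the
Gaussian null with per-pixel variance $\bar I$, non-DC coefficients of the
unnormalized DFT have Rayleigh-distributed magnitude with scale
$\sqrt{N_x N_y \bar I / 2}$; the cutoff is the $1 - 1/(N_x N_y)$ quantile
of that law, i.e. one expected false coefficient per image (the handful of
self-conjugate real-valued bins follow a half-normal rather than Rayleigh
law; at the default quantile the effect on the retained count is
negligible). The paper-level convention decided here: thresholding is
per-bin on magnitude (not radially pooled), retained coefficients keep
magnitude and phase, and the map is computed on the full image so it can
sit in the diagnostic quadrant figure.

## Integral uniformity baseline

`integral_uniformity()` implements the classical
$100\,(\max - \min)/(\max + \min)$ over NEMA-style 9-point-smoothed pixels
within the UFOV (centered 90% of the field) or CFOV (centered 75% of the
UFOV dimensions; 230² and 173² on a 256² flood). No physical rebinning is
applied -- vendor programs typically rebin to coarser matrices before
scoring, so absolute values here are self-consistent rather than
vendor-identical. A consequence worth knowing: on an *unbinned* 256² flood
at a typical 5×10⁶ total counts (≈76 counts/pixel) the smoothed Poisson
noise alone produces IU well above the conventional 5% action limit, which
is precisely why pixel-value metrics at full resolution are either noisy or
must discard spatial detail -- the failure mode the SNI avoids.

## The simulator and what it does (not) emulate

`make_sensitivity_map()` composes multiplicative defect fields -- Gaussian
PMT dropout (depth = amplitude, FWHM in px), unit-mean linear gradients
(peak-to-peak swing $2a$), sinusoids ($1 + a \sin$), and border bands --
renormalized to unit mean so the count target is independent of the
defects; `simulate_flood()` draws independent Poisson counts at a
5×10⁶-count, 256×256 default, the typical daily flood. Defect shapes are
simulator conventions chosen to mimic the documented failure classes, not
reconstructions of any particular clinical incident; the "service-worthy"
truth label defaults to amplitude ≥ 0.10. What is *not* modeled: collimator
scatter, energy windows, dead time, isotope decay, detector-specific
correlated noise, and uniformity-correction-map interactions. Passing tests
on these floods therefore demonstrate the metric's statistical behavior
under Poisson noise with known structure -- not calibration against any
specific camera fleet.

Per-image seeds derive from a campaign seed, the station name and the day
through a fixed integer-mixing rule, so campaigns are reproducible image by
image and truth labels depend only on the schedule.

## Pipeline conventions

* Alert levels: lower 0.50 (physics only), upper 0.60 (adds clinical and
  engineering staff); "exceeds" is strict (`>`), configurable to `>=`.
* Sorting of incoming DICOMs is a pure function of header fields: station
  allow-list, description tokens, minimum counts (from the pixel sum, never
  a header tag), allowed matrix sizes; the rejection reason names the first
  failing criterion.
* Every ingested file yields exactly one record -- analyzed, skipped or
  errored. The store is an append-only CSV keyed by
  (station, acquired_at, analysis_version).
* Notification is a pluggable function; the default writes plain-text
  messages to an outbox directory so the pipeline is testable without mail
  infrastructure. Figures are PNG with the layout and scores recorded in
  text chunks, rendered as deterministic bitmaps.
* The DICOM layer is a minimal Explicit VR Little Endian implementation
  (16-bit unsigned grayscale plus the sorting attributes), round-trip
  validated against an independent reader in the test suite.

## Validation statistics

Sensitivity is computed per service event: an image-quality-related event
is detected if any record for its station within the event's date span
exceeds the threshold. False positives are counted as *maximal runs* of
consecutive alerting days overlapping no event -- a multi-day repair
produces several poor floods but one instance. The coefficient of variation
uses the sample (n−1) standard deviation; the fleet CV divides the average
per-station SD by the average per-station mean. Both the pooled sensitivity
(all events together) and per-period reports can be produced; the worked
fixtures in the test suite exercise 7/7, 24/26 and 8/26 arithmetic and a
five-run false-positive fixture.

## Problem sizes used in the checks

The packaged checks run on 256×256 floods at 5×10⁶ counts (100 seeds for
the null alert rate, 100 paired seeds per dropout amplitude), 128×128
floods for the sweep-oracle and pipeline fixtures, 64×64 patches for
spectrum-level checks (200 seeds per count level), and 20 simulated
10-day × 2-station campaigns for the SNI-vs-IU sensitivity comparison.
These sizes give stable Monte-Carlo estimates while keeping the whole suite
around a minute on a single core.

## Known limitations

* Absolute SNI values depend on the weighting exponent and display
  geometry; thresholds tuned at one configuration do not transfer.
* The quantum floor assumes pure Poisson statistics; detector corrections
  that correlate neighboring pixels lower the effective floor and would
  bias SNI slightly upward.
* The IU baseline is self-consistent, not a replica of any vendor's
  uniformity program.
* Missing-QC detection and notification delivery are in-process features;
  transport (DICOM C-STORE, SMTP) is deployment plumbing outside the
  package.
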