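---
title: "Methods: calcium oscillation detection and culture-level analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium oscillation detection and culture-level analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calosc)
```

## The detection model

A cell's signal is the ROI-mean indicator fluorescence $F$ in relative units
(0–255) sampled at `frame_rate` Hz (4 Hz by default). Detection proceeds in
four fixed steps:

1. **Smoothing.** $S_i = (F_i + F_{i+1})/2$ — averaging neighbouring points,
   length $N-1$.
2. **Derivative.** $D_i = S_{i+1} - S_i$, length $N-2$.
3. **Threshold.** $\theta = k \cdot \mathrm{SD}(D)$ with detection accuracy
   coefficient $k = 0.45$. The SD is taken over the whole derivative,
   event epochs included, as population SD (divide by $N$); both are
   switchable in `detection_params()`. Because $\theta$ is proportional to
   the scale of $D$, detection is exactly invariant under affine maps
   $aF + b$, $a > 0$ — a property the test suite checks on random traces.
4. **Run pairing.** A maximal run of $D > +\theta$ opens an oscillation at
   its first sample (fluorescence rising); the first subsequent maximal run
   of $D < -\theta$ closes it at the run's *last* sample, so the decay tail
   up to threshold re-entry counts toward the duration. Further positive
   runs while an event is open extend it (no nesting); an event still open
   at the end of the recording closes at the last frame — recordings are
   finite windows over ongoing activity, so a truncated oscillation is
   still an oscillation. A flat trace gives $\theta = 0$ and no events.

Suprathreshold points only mark "beginnings and endings"; which sign marks
which is a modelling decision. Rising fluorescence is the only physically
sensible onset for a calcium transient, so positive excursions open and
negative excursions close. Whether the original software allowed
re-triggering mid-event, or excluded detected events from the SD
(iterative thresholding), is unknown; this implementation extends open
events and uses a single global SD. An independent straight-line
re-implementation of the whole chain serves as the oracle in the tests:
both agree exactly on 10,000 random traces.

Index conventions: $D_i$ is assigned to raw frame $i+1$ (the centre of the
smoothing/differencing stencil), frames are 1-based in R, and frame $f$
occurs at $(f-1)/\texttt{frame\_rate}$ seconds. `min_event_samples`
defaults to 1 (no minimum duration is imposed).

## Culture-level parameters

`summarize_activity()` reports the percentage of working cells (≥ 1
oscillation), the oscillation frequency, and the mean duration. The
frequency denominator is ambiguous in common usage (all cells vs active
cells); the default averages over *working* cells, because cultures with
few active cells still report a nonzero per-cell frequency — the pattern
seen when activity collapses after an insult while surviving cells keep
oscillating. A flag switches to the all-cell denominator.

`find_sync_events()` operationalises "network-synchronous event" as: cut
time into 1-s bins, call a bin synchronous when ≥ 30% of working cells have
an onset inside it, merge adjacent qualifying bins. This rule is this
package's own construction (no published procedure exists for it) and its
outputs are labelled accordingly; the bin width should be of the order of
the network onset jitter, and the call count is non-increasing in the
participation threshold.

## The synthetic generator's stated world

`simulate_traces()` emulates a healthy dissociated culture imaged at 4 Hz:

* **Transient shape** — difference of exponentials
  $A\,(e^{-t/\tau_d} - e^{-t/\tau_r})$, peak-normalised to `amplitude`;
  $\tau_r = 0.5$ s, $\tau_d = 3$ s. A standard indicator-response form; the
  source study states no kinetics. Note these defaults give a half-maximum
  width of ≈ 3.5 s and detected onset-to-offset durations of ≈ 5 s, shorter
  than the ≈ 10 s durations printed for real cultures; slower decays
  (τ_d ≈ 8 s) would match those, but the defaults are kept as specified and
  no test asserts absolute durations.
* **Event statistics** — independent per-cell Poisson events at
  `event_rate` (2/min default) plus network events at `network_event_rate`
  (0.5/min) joined by each cell with probability `sync_fraction` (0.6) and
  Gaussian onset jitter (0.2 s). Overlapping transients sum linearly; the
  ground truth records half-maximum intervals with overlaps merged, plus
  the raw onset list (whose per-cell counts are exactly Poisson — verified
  by a chi-square goodness-of-fit on 1,000 cells).
* **Intensities** — baseline 60 r.u., amplitude 60 r.u., trace noise SD
  0.5 r.u. The study gives no amplitude or SNR figures; these defaults
  describe a bright somatic indicator on an 8-bit detector, where the
  ROI-mean over ~10² soma pixels suppresses per-pixel shot noise (~5 r.u.)
  by roughly an order of magnitude. All three are configuration, not
  constants.
* **Determinism** — one global seed drives arithmetic per-cell substream
  seeds, so the same seed reproduces recordings bitwise and adding a cell
  never perturbs the other cells' traces. Network recruitment is decided
  inside each cell's substream for the same reason.

What the generator does **not** model: photobleaching, focus drift, motion,
astrocyte-vs-neuron kinetic classes, signal-dependent (shot) noise, and
overlapping somata. A green round-trip test therefore establishes that the
detector inverts *this* generative model at realistic SNR — not that it
handles every artefact of real recordings.

One practical limit worth stating: because $\theta$ scales with SD($D$) and
the derivative of white noise retains most of its power, trace noise above
roughly 2 r.u. (at these kinetics and rates) floods the derivative with
spurious threshold crossings. The method presumes the low-noise regime of
ROI-averaged traces; it is not a spike-inference algorithm for noisy pixels.

`simulate_stack()` paints trace values into labelled ROIs over a baseline
background with independent pixel noise; at zero noise, `extract_traces()`
recovers the traces exactly (tested). `simulate_respirometry()` and
`simulate_ct_table()` produce Gaussian replicate tables around stated group
means, and Ct tables in which a fold change $f$ appears as a
$-\log_2 f$ shift of the target-gene Ct.

## Respirometry

States: V4 with complex-I substrates (glutamate/malate, before ADP), V3
after ADP, and V4 again after succinate. The respiratory control index is
RCI = V3/V4 with the **glutamate/malate V4** in the denominator — the state
measured immediately before ADP in the listed protocol order (the source
does not name the denominator explicitly). Group RCI is the mean of
per-replicate ratios, not the ratio of group means, so it carries its own
SEM as published tables do. Headline percent changes are rounded only at
the reporting layer; full precision is kept internally. One published
derived value does not reproduce exactly from the printed means:
101.34/498.6 gives 20.32% of control while 20.33% is printed — consistent
with rounding from unrounded means; comparisons are therefore made at the
printed precision.

## Expression (ΔΔCt)

Technical replicates are averaged at the Ct level; ΔCt is the target minus
reference-gene Ct per sample; ΔΔCt subtracts the *mean* ΔCt of the
calibrator group; folds are $2^{-\Delta\Delta Ct}$ with amplification
efficiency fixed at 2 (no efficiency correction is described for the source
data). Group folds are arithmetic means of per-sample folds with SEM
(bar-plot convention); a geometric option is provided since folds are
log-normal under Gaussian Ct noise. Per-sample global Ct shifts (loading or
efficiency offsets) cancel exactly.

## Group statistics

One-way ANOVA uses the standard decomposition. Dunnett's many-to-one
comparisons use the pooled error term and a two-sided adjusted p-value
$P(\max_i |T_i| \ge |t_{\text{obs}}|)$, where the $T_i$ share the control
mean (equicorrelation ½ at equal n). That null is evaluated by seeded
Monte-Carlo simulation (10⁵ draws by default) rather than a quantile table,
which keeps the package dependency-free and lets the tests check it against
an independent full-data simulation; with one comparison the exact pooled
t-test p-value is returned (the degenerate case). Adjusted p-values are
floored at the unadjusted ones, since one-draw Monte-Carlo zeros would
otherwise understate them. `type_i_error_check()` verifies the omnibus test
empirically: at α = 0.05 over 2,000 null replicates the rejection rate
falls in [0.04, 0.06].

No correction is applied across different metrics, matching the source
procedure; replicate counts are always configuration.

## Imaging details

Connected components use 8-connectivity (conventional for nucleus counting
at low magnification; diagonal-touching nuclei merge — checked against a
brute-force flood-fill oracle). Default viability thresholds come from
Otsu's method per channel; when the between-class variance plateaus across
an empty histogram gap, the split is taken at the plateau midpoint. A
total-channel count of zero yields an undefined (NA) dead fraction, never
0%, and a dead count exceeding the total count is capped with a warning.
ROI maps are caller-supplied label images; `segment_rois()` (Otsu on the
temporal mean + components + area filter) is a convenience only and no test
of published behaviour relies on it.

## Known limitations

* No ΔF/F normalisation, amplitude estimation, deconvolution, or
  overlapping-event splitting: co-occurring oscillations merge.
* The synchrony caller is an operational definition, not a published one.
* TIFF I/O is out of scope in this build; stacks and label maps are plain R
  arrays, and traces/events travel as CSV (plus JSON ground truth).
* Respirometry units are carried as opaque labels; no unit conversion.
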