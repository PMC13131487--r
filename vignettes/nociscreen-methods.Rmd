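---
title: "Methods: rule-based screening analytics for nociceptor-silencing GPCR agonists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based screening analytics for nociceptor-silencing GPCR agonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociscreen)
```

# Scope

`nociscreen` implements the quantitative rules used when screening
Gi/o-coupled GPCR agonists for their ability to silence CGRP^+^ dorsal
root ganglion (DRG) nociceptors: a KCl-pulse calcium-imaging excitability
classifier, a subtype-restricted GPCR expression screen, GloSensor cAMP
assay summaries, a family of rule-based nocifensive-behavior quantifiers,
and optically evoked EPSC (oEPSC) normalization for spinal-cord slice
recordings. Every consumer has a matching simulator with planted ground
truth, so the whole pipeline is testable end to end without any recorded
data.

The package deliberately stops at descriptive summaries. Hypothesis
testing, image processing (ROI segmentation, motion correction), animal
tracking and dose-range pharmacology are out of scope; the pipeline
consumes the tables such upstream tools produce.

# The calcium-imaging excitability classifier

## Assay model

Dissociated DRG neurons expressing a genetically encoded calcium
indicator are depolarized with repeated 25 mM KCl pulses (15 s pulses,
300 s onset-to-onset, after a 15 s lead-in; `generate_protocol()`). The
KCl-evoked calcium transient is a surrogate for evoked excitability. The
first two pulses establish a baseline; the third pulse is delivered
together with the drug (applied for the preceding 5 min); further pulses
probe wash-out.

Cell excitability for a trial is the maximum dF/F in that trial's
response window. Two rules classify each cell:

* **Baseline QC** — the first two trials must agree to within 15%:
  $|e_0 - e_1| / \bar e < 0.15$, strict. Cells failing QC are `excluded`.
* **Drug effect** — with baseline $b = (e_0 + e_1)/2$ and relative
  excitability $r = e_\mathrm{drug}/b$, a cell is `inhibited` if
  $r < 0.85$, `enhanced` if $r > 1.15$, and `unchanged` otherwise. Both
  thresholds are strict, so a drug trial at exactly 85% or 115% of
  baseline is `unchanged`.

## Design choices the assay description leaves open

* **F0 definition.** The source assay does not define the dF/F baseline.
  We use a per-trial F0: the mean raw fluorescence over the 10 s
  immediately preceding each pulse onset (`f0_window_s`, configurable).
  A per-trial baseline is robust to slow drift and photobleaching across
  the ~25 min session, and makes dF/F exactly gain-invariant.
* **QC denominator.** "Difference of excitability < 15%" names no
  denominator. The default is the mean of the two trials, which is
  symmetric in trial order; relative-to-first is available
  (`denominator = "first"`).
* **Response window.** Pulse duration + 15 s after onset, configurable.
  The single-exponential transients the simulator produces peak at
  onset, so any window containing the onset captures the max; for real
  traces the window must end before the next trial's F0 window.
* **Boundary conventions.** All three 15% comparisons are strict, and
  the soma-diameter strata are small < 25 µm, medium 25–35 µm (both ends
  inclusive), large > 35 µm; missing diameters form an `unknown` stratum
  that never excludes a cell from unstratified summaries.
* **Wash-out.** The recovery ratio (mean post-drug excitability over
  baseline) is report-only; no classification depends on it, since the
  assay description does not state whether non-recovering cells were
  excluded.
* **Aggregation.** Percentages are reported pooled across cells; because
  the per-cell table keeps every cell, per-coverslip or per-animal
  averaging can be layered on top by the caller.

## The population simulator

`simulate_population()` generates traces as
$F(t) = F_0\,(1 + \mathrm{drift}(t)) + \sum_k A_k e^{-(t-t_k)/\tau}
\mathbf{1}[t \ge t_k] + \varepsilon$, with an instantaneous rise at each
pulse onset $t_k$ and single-exponential decay — the simplest transient
shape with a well-defined maximum. Noise is i.i.d. Gaussian with SD
`noise_sd` · F0 (no photon-count model), per-cell amplitudes are
lognormal around `transient_amplitude` · F0, and diameters come from a
configurable three-component mixture of zero-truncated normals.
A `responder_fraction` of cells has its drug-trial amplitude multiplied
by `effect_multiplier`.

Defaults describe the study conditions the classifier is validated
under: 500 cells, responder fraction 0.4, effect multiplier 0.5, noise
SD 0.01, decay constant 8 s, amplitude 2 (peak dF/F ≈ 2), 2 Hz sampling.
The source assay reports neither its noise level nor transient kinetics,
so the noise and kinetic defaults are nominal values typical of cultured
DRG imaging and are fully configurable. Randomness derives from one root
seed via documented per-generator streams
(`stream = (seed · 7919 + offset) mod (2^31 − 1)`, a distinct offset per
generator), so identical configurations are bit-identical and the
diameter draw does not perturb the responder draw.

What the simulator does **not** emulate: movement artifacts, overlapping
ROIs, indicator saturation and nonlinearity, spontaneous (non-evoked)
transients, and run-down of responses over trials. Passing recovery
tests therefore validates the classifier's logic, not its robustness to
those real-data pathologies.

# The subtype-restriction expression screen

Given a gene × subtype expression-summary matrix (normalized means or
fraction-of-cells — the screen is agnostic, thresholds are in the
matrix's own units) and subtype class labels (CGRP, LTMR, proprioceptor,
other), a gene is **restricted** when it is expressed (value ≥
`on_threshold`, inclusive) in at least one CGRP^+^ subtype and not
expressed (value < `off_threshold`) in every LTMR and proprioceptor
subtype. Two thresholds are kept because "expressed in" and "not
expressed in" are asymmetric judgments; with `on = off` and a binary
matrix the screen reduces to exact set logic. Class `other` subtypes
(e.g. TrpM8^+^, MrgprD^+^) neither qualify nor disqualify a gene — the
stated criterion names only LTMRs and proprioceptors as exclusion
classes — but `strict_other = TRUE` adds them. Since no numeric
expression threshold is published, thresholds are explicit arguments
recorded in the output metadata, never buried defaults. The breadth
profile separates genes exclusive to one CGRP^+^ subtype from broadly
expressed ones.

The matrix simulator plants a restricted set (guaranteed above-threshold
in ≥ 1 CGRP^+^ subtype, background elsewhere) and a decoy set that
additionally expresses in one LTMR subtype; at `dropout = 0` recovery of
the planted set is exact by construction, which is what the recovery
tests assert.

# cAMP assay summaries

GloSensor wells are normalized as (summary of RLU over the response
window) / (mean RLU over the pre-compound baseline window); the summary
is the window **maximum** by default — robust to slow GloSensor kinetics
when the published readout ("multiple time points between 5 and 20 min
post-isoproterenol") leaves peak-vs-average open — with the mean
available. Normalization cancels per-well detector gain. Dose–response
tables report per-dose means ± SD sorted by dose with a Spearman-sign
trend descriptor, plus an optional four-parameter-logistic refinement
(least squares on log10 dose, vehicle anchoring the top asymptote) for a
half-maximal dose. The constitutive-activity index is mean normalized
receptor response over mean normalized vector response; calls use a
fixed effect-size margin δ = 0.2 (index < 0.8 → Gi-like, > 1.2 →
Gs-like) in place of the original replicate significance tests, which
are out of scope — replicate dispersion is reported so callers can apply
their own inference.

# Behavior quantifiers

All rules follow the published definitions exactly:

* **von Frey**: the 50% withdrawal threshold is the lowest filament
  force with ≥ 5 positive responses out of 10 (inclusive); if none
  qualifies the series is flagged above-range.
* **Dynamic brush**: session score = mean over trials of the maximal
  grade (0–3) per trial; allodynic at score ≥ 1.5 (inclusive, "1.5 and
  higher").
* **Pinprick**: a trial is valid only if the contact channel exceeds
  1.5 V strictly after the button press; stimulus onset is the first
  supra-threshold contact sample, movement onset the first accelerometer
  sample ≥ 0.15 V ("reached") after it, and movement magnitude the
  trapezoidal AUC over 0.4 s after stimulus onset on the recorded
  sampling grid (computed even when no movement onset is found).
* **Paw luminance**: per-frame log10(ipsi/contra) — base 10, stated here
  because the published formula names no base — with zero-luminance
  frames masked. Both the mean of per-frame log-ratios and the ratio of
  session means are emitted, because the prose and the figure legend of
  the source describe the two different forms; callers pick one and say
  which. A full session is 30 min at 25 fps = 45,000 frames.
* **Locomotion split**: locomoting ⇔ 0.5 s-smoothed centroid speed ≥
  2 cm/s, a conventional rodent open-field cutoff; the threshold is
  configurable, and the recovery tests use planted state labels rather
  than trusting the default.
* **Temperature/texture preference**: fraction of frames on the target
  side; the two sides sum to one, and 0.5 is the no-bias benchmark.
* **Event summaries** (cold/hot plate, guarding): count of annotated
  events within the observation window and latency to the first; with
  zero events the latency is censored at the window length and flagged,
  since the published scoring does not state its handling.

# oEPSC metrics

Sweep amplitudes (stored as positive magnitudes; inward currents are
recorded negative and folded) are normalized to the mean over the 10 min
pre-drug baseline. The drug effect compares the mean over
[drug_on − 120 s, drug_on) with the mean over
[drug_on + 480 s, drug_on + 600 s) — the 2 min immediately before
application versus the 2 min at 8–10 min after it, just before wash-out.
All windows are half-open on the right, so a sweep exactly at drug onset
belongs to the drug period. Stability QC passes only if every monitored
resistance stays within 20% of its first value (exactly 20% passes; the
exclusion rule is a strict "more than 20%"); a range-over-mean variant
is available. Failed QC flags the effect unusable but still reports it.
Per-cell effects are computed cell-first; pooling across cells is left
to the caller, as the published averaging order is ambiguous.

# Numerical conventions and degenerate inputs

* Strictness at every rule boundary is as stated above and locked in by
  boundary-sweep tests (the sweeps use 0.001-resolution grids; all
  boundary grid points are exactly representable, so no tolerance games
  are needed).
* Degenerate inputs degrade to flags, not crashes, wherever the
  real assay would simply discard the observation: non-positive F0
  excludes the cell with reason `degenerate-baseline`; zero-baseline
  GloSensor wells return `NA` with a `degenerate-well` warning;
  all-masked luminance sessions set `undefined`; an all-excluded
  population yields `NA` fractions with an `undefined` flag. Structural
  errors (missing channels, empty windows, non-increasing time stamps,
  duplicate gene ids) raise classed errors.
* Validation problem sizes — 500 cells × 20 seeds for responder-fraction
  recovery, 150 genes × 10 seeds for screen recovery — are the package's
  validation design: large enough that the binomial 3-SE band on a 0.4
  fraction is ±6.6%, small enough to run routinely.

# Known limitations

The simulators are built to validate rule logic, not to imitate real
recordings; all noise models are Gaussian and stationary. The screen
reproduces the restriction logic but not any published gene list, which
would require the original single-cell dataset. Constitutive-activity
calls use a fixed margin rather than inference. The 4PL refinement is a
least-squares point estimate without confidence intervals.
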