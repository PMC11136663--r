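---
title: "Quantifying pollen calcium oscillations and hypo-osmotic shock transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pollen calcium oscillations and hypo-osmotic shock transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenCaOsc)
```

## The measurement problem

Rehydrating pollen grains report their water status through cytosolic
calcium. Recordings with a GCaMP-type indicator (or a Fura-2 340/380 ratio)
show a stereotyped anatomy before germination: a first resting phase
(RePh1), a train of small-amplitude calcium oscillations (CaOscS, flashes
of roughly 2–3 times the baseline intensity), a second resting phase
(RePh2), a train of large-amplitude oscillations (CaOscL, 5 times baseline
or more) that precedes tube protrusion, and a final resting phase (RePh3).
When germination does not follow, CaOscS → RePh2 → CaOscL → RePh3-like
modules can recur. Separately, a sudden drop in external osmolarity
triggers a single hypo-osmotic calcium transient (HOSCA) whose peak grows
with the pre-incubation osmolarity and which desensitizes under repeated
challenges. The hyperosmolarity-gated channel pair OSCA2.1/OSCA2.2 acts as
the hypo-osmosensor: the double mutant shows a much longer RePh1, a
shortened CaOscS train, no distinct RePh2, a strongly diminished CaOscL
train and weaker shock responses.

This package turns the manual scoring of such recordings into a tested,
deterministic pipeline, and ships a seeded generator of synthetic
recordings with ground truth so every stage can be validated end to end.

## Trace normalization

A region-of-interest trace is normalized as
$\Delta F/F_0 = (F - F_0)/F_0$, where $F_0$ is the mean over the *first
stable window* of ten frames. "Stable" is operationalized as a coefficient
of variation of at most `cvMax = 0.05` over the window (no quantitative
criterion is in common use; 5 % comfortably exceeds shot noise at the
default SNR of 50 while rejecting windows that contain an event). If no
window qualifies, `preprocessTrace()` falls back to the first ten frames
with a warning. Note the unit convention: an event reaching $k$ times the
baseline has $\Delta F/F_0 = k - 1$, so the five-times-baseline criterion is
$\Delta F/F_0 \ge 4$.

Long recordings bleach. The correction in `correctBleaching()` is
*multiplicative*: a mono-exponential $B e^{-\lambda t}$ is fitted to
resting frames and divided out, then the trace is rescaled so the
baseline-window mean is preserved. The multiplicative form matches how an
indicator pool that loses fluorophores scales both baseline and signal; a
linear model is the fallback when the exponential fit fails or turns
non-decaying. Because spikes bias any decay fit, the fit uses only
non-event frames: with a known event mask that mask is honoured, otherwise
the package runs a trimmed provisional fit (the 60 % of frames with the
lowest log-residuals, which excludes spike frames as long as events occupy
less than ~40 % of the recording), detects events on the provisional
$\Delta F/F_0$, and refits once on the frames outside detected events.
Short shock recordings (hundreds of seconds) are not corrected by default;
bleaching is negligible on that time scale and the pre-shock baseline
anchors $F_0$.

## Spike detection and classification

`detectSpikes()` finds local maxima of a lightly smoothed trace (3-frame
centred moving average for 30-s germination sampling, no smoothing for 1-s
shock sampling), then *refines and thresholds on the unsmoothed trace*:
smoothing only stabilizes peak localization, never the measured amplitude,
so a genuine 5× event cannot be demoted by its own smoothing. Candidates
below the detection floor `detectMinDff = 1` (the lower edge of the small
2–3× band) are dropped; survivors are accepted greedily by decreasing
height subject to a minimal separation of two frame intervals; equal-height
plateaus count once, at their first frame. Onset and offset are the 20 %
of-peak crossings before and after the peak, the offset capped at the next
onset so events never overlap.

Classification rests on the one sharp amplitude boundary the field uses: an event is
**large** iff its peak $\Delta F/F_0 \ge 4$ ($F/F_0 \ge 5$), otherwise
**small**. Amplitudes between 3× and 5× baseline have no established
class of their own; the package classes them as small, and the generator
never produces them by default so that class-recovery tests are
unambiguous. Per-spike metrics report both the peak amplitude $P$ and the
peak-minus-trough $P - T$, since either convention appears in figure
annotations; the period is the mean successive same-class peak interval
and the frequency is $(n-1)$ divided by the class's active span.

## Phase segmentation

`segmentPhases()` is a one-pass greedy grammar over the classified event
list. Events separated by quiet intervals shorter than
`restMinGapS = 600` s belong to one oscillation run; longer quiet
intervals open resting segments. The 600-s default (20 frames at 30 s)
sits an order of magnitude between within-train gaps (a few minutes) and
resting phases (tens of minutes). A run containing a large event is split
at the first large event's onset, the remainder being promoted to CaOscL
— the large-amplitude train is the later, germination-proximal element, so
an interleaved labelling would misrepresent it. Repeat modules keep a
one-pass grammar by suffixing labels (`CaOscS_r2`, ...). A single small
flash still opens a CaOscS segment; module counting, however, requires a
small train followed by a large train, so isolated trains never inflate
the module count.

## Shock quantification

`quantifyShock()` takes the maximum $\Delta F/F_0$ within a 300-s window
after the stimulus (matching 1-s acquisition for 300 s; ties resolve to
the earlier frame) and fits $A e^{-(t-t_p)/\tau} + C$ from the peak to the
window end. The floating plateau $C$ matters: shock responses need not
return to baseline within the window, and fixing $C = 0$ would bias
$\tau$. The decay metric of repeated-challenge experiments is
operationalized as this $\tau$. Desensitization is reported as the vector
of peak ratios to the first challenge; a monotone decline is expected for
a desensitizing channel but deliberately not enforced. Dose–response
tables group peaks by pre-incubation osmolarity and attach the Spearman
rank correlation as a monotone-trend summary.

## The synthetic-data model

The generator renders
$F(t) = F_0\, e^{-\lambda t}\bigl(1 + \textstyle\sum_k s_k(t)\bigr) +
\varepsilon(t)$, with $F_0 = 100$ a.u., bleaching
$\lambda = 2\times10^{-5}\,\mathrm{s}^{-1}$ (≈30 % loss over 300 min),
and $\varepsilon \sim N(0, \sigma^2)$ with a default SNR
($F_0/\sigma$) of 50. Spikes $s_k$ rise linearly over 30 s and decay
exponentially (small events $\tau = 45$ s, large $\tau = 60$ s); true
peaks are sampled uniformly in 2–3× baseline for small events and
log-uniformly in 5–8× for large ones. Germination-mode sampling is 30 s ×
600 frames (300 min); shock mode is 1 s × 350 frames. Event peak times
snap to the acquisition grid, so a noise-free trace attains each true peak
exactly — discretization never erodes an amplitude below its class
boundary.

Within an oscillation phase, inter-spike intervals are a **refractory
renewal process**: a hard refractory gap of one spike duration
(rise + 4 decay constants) plus Gamma-distributed jitter with shape 16
(CV ≈ 6 %, overall interval CV ≈ 10–25 % depending on the period). Real
pollen oscillations are quasi-periodic with fluctuating periods; a
memoryless (Poisson) process was considered and rejected because its
interval variance swamps the osmolarity dependence of periods and counts
at realistic cohort sizes and because its heavy right tail produces
within-train gaps that mimic resting phases. For the same reason intervals
are capped at 560 s, just below the resting-gap criterion, so a train can
never split spuriously.

`osmolarityToParams()` encodes the condition design as strictly monotone
maps over 100–1000 mOsm (writing $u = (1000 - x)/900$): RePh1 duration
$4800 - 3000u$ s, CaOscS duration $2400 + 1800u$ s with period
$440 - 200u$ s, RePh2 fixed at 1500 s, CaOscL duration $2100 + 1500u$ s
with period $500 - 200u$ s, amplitude windows sliding upward as osmolarity
drops. Thus lower osmolarity means earlier, denser, larger spiking —
monotone by construction, which is what cohort round-trip tests check.
The `osca2.1/2.2` preset applies, at every osmolarity: RePh1 × 2.5,
CaOscS duration × 0.6, RePh2 removed, CaOscL duration × $0.4u$ (so large
events nearly vanish at high osmolarity), periods + 150 s, and amplitude
windows compressed toward the class floors. Shock presets map
pre-incubation osmolarity to peak $\Delta F/F_0 = 0.4 + 3(x-100)/900$
(mutant: one quarter of that), decay $\tau = 40$ s, rise 5 s.

The ground truth records, besides every event, both the *planned* phase
boundaries and the *realized* ones (first event onset to last event
offset). Recovery tests compare segmentations against realized
boundaries: the planned end of a phase can trail its last event by up to
one inter-spike period, which no detector observing the trace could know.
A germination label is emitted when a CaOscL train completes with at
least three large events; it is a ground-truth convenience only — aperture
propagation is not modelled.

What the generator does *not* emulate: spatial calcium waves and their
direction, fluorescence-area growth (excluded from quantification on
purpose), movement artifacts, baseline drift other than mono-exponential
bleaching, and amplitudes in the 3–5× gap. Passing round-trip tests
therefore demonstrate the pipeline's correctness under the stated model,
not robustness to every pathology of real microscopy.

## Water-potential arithmetic

`solutePotential()` evaluates the van't Hoff relation
$\Psi_s = -iCRT$ with $R = 0.008314$ L MPa mol$^{-1}$ K$^{-1}$,
osmolarity accepted in mOsm and divided by 1000. The default temperature
is 298.15 K: the printed conversions for the plant range (−4.5 MPa at
1,800 mOsm, −0.03 MPa at 12 mOsm) and the upper mammalian bound
(−0.82 MPa at 330 mOsm) are reproduced exactly at that temperature. The
lower mammalian bound is commonly quoted as −0.66 MPa while 270 mOsm at
298.15 K gives −0.67 MPa; the package does not force agreement there —
the quoted bound presumably reflects rounding at a slightly different
temperature. The van't Hoff factor defaults to $i = 1$ because mOsm
already counts osmotically effective (dissociated) particles.

## Numerical choices and edge cases

* Exponential fits (bleaching, shock decay) use Levenberg–Marquardt with
  log-linear starting values; non-convergence or a negative decay rate
  beyond $10^{-7}$ falls back to the linear model (bleaching) or flags the
  response (`decay_ok = FALSE`).
* Ties: equal-height detection plateaus take the first frame; equal shock
  maxima take the earlier time; greedy acceptance breaks height ties
  toward the earlier peak.
* Degenerate inputs: an event-free trace segments into a single RePh1;
  empty event lists give zero counts with `NA` statistics; a single
  response group gives dispersion 0 at $n = 1$; traces must have at least
  20 frames so the ten-frame baseline rule is meaningful.
* All generation is seeded (`withr::with_seed`), and cohort replicates
  draw per-replicate seeds from the master seed, so datasets are
  byte-reproducible.

## Problem sizes used in the test suite

Recovery suites run 100 seeded traces per noise regime for detection
(precision/recall and class agreement), 100 seeds for shock-decay
recovery at SNR 20, and cohorts of 12 replicates × 4 osmolarities × 2
genotypes for the monotonicity round trip — sizes at which the renewal
model's sampling noise is far smaller than the designed condition
contrasts, while the whole suite stays fast enough to run on every check.

## A worked example

```{r example, eval = FALSE}
p   <- osmolarityToParams(535, "WT", seed = 1)
out <- generateTrace(p)
res <- analyzeTrace(out$trace)
res$metrics[, c("class", "count", "amp_mean", "period_mean")]
res$segments
countModules(res$segments)
```

## Known limitations

Fixed circular ROIs only (no segmentation or registration); no
deconvolution to underlying calcium flux; no subframe peak interpolation;
no mechanistic channel model; statistics beyond descriptive summaries
(ANOVA, t-tests) are intentionally left to external tools, for which
`summarizeCohort()` emits tidy tables.
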