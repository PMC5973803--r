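---
title: "Quantifying after-discharges, suppression and pain behavior in parabrachial recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying after-discharges, suppression and pain behavior in parabrachial recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbspike)
```

# The problem

In trigeminal neuropathic pain models (chronic constriction injury of the
infraorbital nerve, CCI-ION), neurons of the parabrachial complex become
hyperexcitable: a noxious 3 s stimulus to the face or hind paw evokes firing
that can *outlast* the stimulus by seconds (an after-discharge), and a
distinct subset of cells instead *suppresses* firing during the stimulus and
fires a rebound burst at its removal. pbspike turns sorted spike times plus a
stimulus log into the quantities such a study reports: per-unit response
classes, after-discharge and rebound durations, force-normalized response
magnitudes, behavioral withdrawal thresholds, and the nonparametric group
contrasts between sham and injured animals.

# The detection model

## PSTH and baseline band

All detection criteria reference a peristimulus time histogram. Spikes are
aligned to each stimulus onset and binned into half-open bins
(`[edge, edge + w)`; a spike exactly on an edge belongs to the right-hand
bin, so no spike is ever counted twice). The default bin width is
`w = 0.1` s — chosen so the 500 ms after-discharge criterion is exactly 5
bins; any width that divides the criterion is accepted, and the criterion is
snapped to a whole number of bins with a warning otherwise.

The baseline window is the 5 s before onset — the same window the
suppression t-test uses, so one baseline definition serves both criteria.
Baseline mean and SD are computed over the *pooled per-trial bin counts*
(5 trials × 50 bins by default), converted to Hz, and the 99% band is

\[ \mathrm{CI} = \bar r \pm z_{0.995}\, s_r, \]

with the lower edge floored at 0. Two conventions are common for such
bands and the choice is not neutral, so both are implemented:

* `"normal"` (default): mean ± z·sd of pooled baseline bin rates;
* `"poisson_exact"`: the 0.5th/99.5th percentiles of
  Poisson(\(\bar r w\)), converted to Hz.

At well-resolved rates (a few spikes per bin, λ ≳ 5) the two agree within
about 10%. At low rates they genuinely diverge: at a 5 Hz baseline
(λ = 0.5) the integer Poisson quantile sits at 3 counts (30 Hz) while the
normal band is ≈ 23 Hz — a ~23% gap that is a property of discreteness,
not an implementation artifact. Detection uses the normal band by default
and records which method produced every band.

Two asymmetries are worth stating plainly. The band is built from
single-trial dispersion but compared against the *trial-averaged* rate per
bin, which makes the criterion conservative on homogeneous data (the
false-positive test asserts ≤ 2% per-bin exceedance at the nominal 1%
level, and observes far less). And the band is computed per neuron from
pooled trials, not per trial; trial-pooling is how PSTH-based criteria are
usually displayed and applied.

## Response, after-discharge, suppression, rebound

* **Excited**: any in-stimulus bin's mean rate exceeds the band's upper
  edge. One bin suffices; with 30 stimulus bins at a one-sided 0.5% level
  this is permissive by design, matching the practice it reproduces.
* **After-discharge**: the run of consecutive supra-band bins *starting at
  the first post-offset bin*. Continuity with the evoked response is
  required (a gap at offset means no after-discharge; a gap-tolerance knob
  exists, default 0). The run is scanned until activity returns below the
  band or the aligned window ends. Durations below 500 ms are reported as
  0 — non-after-discharge neurons contribute 0 s to group comparisons —
  with the raw run length kept in diagnostics.
* **Suppressed**: two-tailed paired t-test of per-trial pre-stimulus
  (5 s) vs in-stimulus rates at α = 0.05, *plus* the direction requirement
  that the stimulus-period mean is lower. The direction check is not in
  the criterion the t-test came from, but without it a strongly excited
  cell also rejects the null; the label would be absurd. Zero-variance
  differences with nonzero mean report p = 0 with a degenerate-variance
  flag rather than an error.
* **Rebound** (suppressed cells only): the same run rule after offset
  within a 10 s scan window, with *no* minimum duration — any supra-band
  run counts. Sub-bin rebounds are undetectable by construction.
  A suppressed cell's post-offset elevation is scored as rebound, never as
  an after-discharge.

After-discharge presence and excitation are deliberately independent
classifications (a cell can be responsive without an after-discharge), but
suppressed cells never carry after-discharge durations.

# Response magnitudes

Mechanical magnitudes are `(evoked − spontaneous) / ∫F dt` by default.
"Normalized to" is ambiguous between subtraction and ratio; subtraction is
the default because 11–25% of parabrachial neurons have *zero* spontaneous
firing and a pure ratio is undefined there. Ratio mode is available with a
floor of ε = 0.1 Hz (one spike per 10 s) on the denominator; every output
records the mode, and the printed magnitudes of the two modes are not
comparable. The force integral is the trapezoidal integral of the
aesthesiometer trace in g·s. Thermal magnitudes default to the rate ratio
(in-stimulus mean over baseline mean, ε-guarded), which is near 1 for weak
responses; a subtract mode is available. Evoked rate is the mean over the
full 3 s stimulus, not the peak bin.

# Behavioral endpoints

The up-down 50% threshold uses the classical small-sample staircase
estimator on the log10-force axis: `10^(Xf + k·δ)` with `Xf` the final
filament's log force, `δ` the mean log step, and `k` a coefficient of the
terminal response pattern (the trial before the first response change
onward, at most the last six). The `k` values shipped in
`inst/extdata/updown_k_table.tsv` are computed by maximum likelihood under
the model the classical tables assume — a normal tolerance distribution
with SD equal to the step — rather than transcribed, which reproduces the
known anchor values (k = ∓0.5 for the two-trial patterns, i.e. the
midpoint rule) and covers every pattern up to length 6. All-response and
all-non-response sequences pin to the ladder minimum/maximum. The default
ladders (0.4–26 g face, 2–60 g hind paw) are conventional sets; the actual
filaments are always an input.

Grimace scores are means over all non-missing image × action-unit scores
(4 units, scores in {0, 1, 2}); Hargreaves latency is the plain 5-trial
mean.

# Group statistics

The U statistic is `min(U_A, U_B)` from midranks, so complete separation
gives U = 0. The p-value is exact by enumeration for tie-free samples with
n ≤ 20 combined, otherwise normal with tie and continuity corrections
(delegated to `wilcox.test`; an independent full-enumeration oracle checks
it exhaustively for all sizes with n_A + n_B ≤ 10). Median CIs are
distribution-free order-statistic intervals whose ranks are chosen for
achieved coverage ≥ the nominal level (at n = 15 the 95% CI is the 4th and
12th order statistics, achieved coverage 96.5%); with n < 6 no such
interval exists and the data range is returned with a warning. The exact
binomial test two-sides by minimum likelihood (the `binom.test`
convention), with a tail-doubling variant available. The 2×2 chi-square
defaults to Yates correction because the tables here have expected cells
below 5. Cohen's d is computed from means and pooled SD of raw values —
it cannot be derived from published medians, so printed effect sizes are
not comparison targets.

The incidence contrast (`compareAdIncidence`) tests the injured
population's after-discharge count against a reference proportion — either
a stated reference incidence (e.g. 0.136, which is itself the 3/22 sham
proportion) or a reference group's empirical counts with a Haldane 0.5/n
guard when the reference count is zero. With the small reference group
(n = 22), using each replicate's empirical sham proportion costs roughly
ten points of power at the p < 10⁻⁴ level relative to the stated reference
incidence; the pipeline defaults to the stated reference and exposes the
empirical form.

# The simulator and what it does (not) show

Spike trains are inhomogeneous Poisson processes with piecewise-constant
rates: baseline; baseline + gain (excited) or baseline × retained fraction
(suppressed) during stimuli; a rectangular after-discharge segment or
rebound segment after offset. Sampling is exact for piecewise-constant
rates (per-segment Poisson counts with sorted-uniform arrival times, the
order-statistics construction); exactness is what makes moment-based
oracle tests sharp. An exponential-decay after-discharge shape is
available, but recovery tests use the rectangular mode because it gives a
sharply defined ground-truth duration.

Population presets encode the published group structure: after-discharge
incidence 0.136 (sham-like) vs 0.512 (injury-like), silent fractions 0.11
vs 0.25, ground-truth after-discharge durations uniform on 0.5–3 s,
baseline rates log-uniform on 0.3–5 Hz (medians near 1–2 Hz), evoked and
after-discharge rates of 60 Hz, five 3 s stimuli with spacing widened
beyond the 8 s floor so aligned windows never overlap and the longest
after-discharge fits before the next trial. Each simulated unit retains
its generating profile in session metadata, so recovery is directly
assertable.

What passing tests show: the detector recovers rectangular
after-discharges to one bin at high signal-to-noise, stays below 5% false
positives on homogeneous trains, and the full pipeline reproduces the
qualitative incidence contrast. What they cannot show: real PB neurons are
not Poisson (bursting, refractoriness, rate drift), after-discharges decay
rather than end abruptly, and anesthesia state slowly modulates baseline —
so real-data durations near the 500 ms criterion will be noisier than the
simulation suggests. The simulator also draws neurons independently;
correlated population activity is out of scope.

# Numerical choices and degenerate inputs

* Time is seconds from recording start; stimulus windows and bins are
  half-open, with a 10⁻⁹-bin forward tolerance in edge assignment so an
  exactly-on-edge spike lands in its right-hand bin despite floating
  division.
* A silent baseline gives a zero-width band at 0 Hz: any post-stimulus
  spike bin is then supra-band, which is the intended reading of a
  "significant" response in a silent cell.
* Simulation problem sizes in the validation suite — 500 seeds per
  after-discharge duration, 1000 homogeneous neurons for specificity, 200
  paired populations for the contrast, 2000 staircases, 10⁴ replicates for
  CI coverage — were chosen to bound Monte-Carlo error near one percentage
  point on the rates asserted.
* One master seed fans out deterministically (affine map mod 2³¹−1) to
  per-unit and per-stage child seeds; identical seeds reproduce identical
  sessions and byte-identical pipeline tables.
* The command-line layer is a thin script over exported functions
  (`inst/scripts/pbspike.R`); the package API is the primary interface.

# Known limitations

Proprietary acquisition formats are not read (plain-text spike times,
TSV event tables, YAML manifests only). No spike sorting, burst analysis
within spontaneous activity, oscillation measures, kernel rate estimation,
stimulus–response curve fitting, or multiple-comparison correction (none
is part of the analysis this package reproduces). Mann-Whitney exactness
falls back to the corrected normal approximation in the presence of ties.
The up-down estimator assumes an approximately log-uniform ladder; strongly
irregular ladders make the mean log step a poor summary.

# Session info

```{r}
sessionInfo()
```
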