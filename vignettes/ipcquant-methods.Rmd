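---
title: "Quantifying peptide-evoked cAMP and calcium responses, and dormancy assays, with ipcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peptide-evoked cAMP and calcium responses, and dormancy assays, with ipcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcquant)
```

## What the package computes

`ipcquant` implements the quantitative core of a common experimental design
in insect neuropeptide physiology: brain explants expressing a genetically
encoded sensor in a defined cell population (here, the insulin-producing
cells, IPCs) are imaged at low frame rate while candidate neuropeptides are
bath-applied, and the evoked second-messenger responses are scored per
neuron and compared across treatments. The package also covers the
organism-level readout such studies pair with imaging — reproductive
dormancy assays scored as replicate-level proportions of females with
ovarian arrest — and the qPCR expression ratios used to validate genetic
manipulations.

Everything operates downstream of ROI extraction: the input is a tidy table
of per-frame raw channel intensities for regions of interest drawn on single
cell bodies, not images. Pixel-level segmentation and microscope formats are
deliberately out of scope.

## The cAMP (inverse FRET) model

The cAMP sensor is a single-fluorophore-pair FRET construct whose FRET
efficiency *decreases* as cAMP rises. With background-corrected donor (CFP)
and acceptor (YFP) emissions, the readout is the inverse FRET ratio

$$\mathrm{iFRET}(t) = \frac{\mathrm{CFP}(t)}{\mathrm{YFP}(t) - k\,\mathrm{CFP}(t)},$$

which rises with cAMP. The subtraction removes donor bleed-through
(spillover) into the acceptor channel; the default spillover fraction is
`k = 0.357` (35.7% of the CFP signal), a property of the optical setup that
should be re-measured per rig and is therefore a configuration parameter.

Each neuron's iFRET trace is normalized to its own pre-application baseline
by division and expressed as percent change,

$$R(t) = \left(\frac{\mathrm{iFRET}(t)}{\overline{\mathrm{iFRET}}_{\mathrm{baseline}}} - 1\right)\times 100,$$

and scored as the maximum of $R(t)$ inside closed time windows: a *long*
window (default 100–1000 s, capturing slow cAMP accumulation) and a *short*
window (default 100–200 s, capturing the immediate response). Division
rather than subtraction is used because raw iFRET magnitudes differ between
cells; percent change is the scale on which such responses are conventionally
reported. Windows are mapped to frames by time membership, not frame index,
so occasional dropped frames do not shift the analysis.

Numerical policies, all configurable:

* corrected intensities are floored at `eps = 1e-9` channel units; a channel
  that is entirely at the floor is rejected as degenerate;
* frames where the spillover-corrected denominator falls below `eps` are
  marked invalid and excluded from baseline means and maxima; an ROI with
  more than 10% invalid frames is rejected with a reported reason (this
  prevents silent sign flips near a vanishing denominator);
* a baseline needs at least 3 valid frames and a strictly positive mean;
* no smoothing or detrending is applied before taking maxima — scores are
  read off the raw normalized trace;
* no photobleaching correction is applied; shared multiplicative bleaching
  cancels exactly in the ratio, which the test suite verifies.

The calcium arm is the single-channel analogue: $\Delta F/F_0 =
(F_n - F_0)/F_0 \times 100$ with $F_0$ the baseline-window mean, scored over
the same windows (the short window is the conventional one for the small,
fast calcium responses involved).

Treatment summaries average the normalized traces point-wise across neurons
on a common time grid (the intersection of the neurons' time points, with a
warning if truncation occurs) and report SEM across neurons, matching how
figure legends in this literature count n. Brain-level nesting is reported
in the counts but not modeled; a mixed-effects treatment of brain effects is
an explicit non-goal.

## Statistics

Per-neuron windowed maximum scores are compared with the test-selection
logic standard in this literature: Shapiro–Wilk on every group at
`p > 0.05` gates a parametric (ANOVA family) versus nonparametric path. A
group with zero variance routes to the nonparametric path, since normality
is neither testable nor plausible there. Maximum-response scores are
typically non-normal, so the primary path is the Kruskal–Wallis omnibus
test followed by two-sided pairwise Wilcoxon rank-sum tests with Bonferroni
correction over an *explicit* comparison family — the family is stated in
the configuration, never inferred from the data. The exact rank-sum
distribution (equivalent to exhaustive enumeration of group assignments) is
used when both groups have $n \le 8$ and the pooled data are tie-free;
otherwise the normal approximation with tie and continuity correction is
used, and the method chosen is always reported. Significance tiers are the
conventional 0.05 / 0.01 / 0.001.

### The synergy excess

Co-application experiments ask whether the response to two peptides together
exceeds the sum of their separate effects. The qualitative claim ("greater
than the sum") has no standard test, so the package provides a documented
formalization rather than a reproduction of any published procedure:

$$\mathrm{excess} = \mathrm{med}(\mathrm{combined}) -
  \left[\mathrm{med}(A) + \mathrm{med}(B)\right],$$

with a percentile bootstrap (independent resampling of each group) for the
confidence interval and a one-sided bootstrap p-value for excess > 0 — the
direction is one-sided because the scientific claim is directional. The
median is the default central tendency, consistent with the nonparametric
treatment of the scores; a mean-based variant is available. The p-value uses
the add-one rule, so its floor is $1/(n_{\mathrm{boot}}+1)$; fewer than 1000
resamples are refused as unstable, and a seed is a required argument.

### Dormancy assays

Dormancy is scored per replicate vial as the proportion of dissected females
with ovarian arrest. Inference uses the variance-stabilizing arcsine
square-root transform $\arcsin\sqrt{p}$ (radians) — "arcsine transformation"
in the field's shorthand — followed by one-way ANOVA across genotypes with
Tukey HSD contrasts, or the full two-factor genotype × photoperiod model
with interaction. The replicate (vial) is the experimental unit; individual
flies never enter the ANOVA. The two-factor model requires every cell filled
with at least two replicates; balanced designs use the standard
decomposition (all SS types coincide), mildly unbalanced ones use Type-II
sums of squares. Group summaries for display stay on the untransformed
percent scale. A binomial GLM would be a reasonable modern alternative and
is noted as an extension, not implemented.

When every observation is identical the ANOVA F statistic is reported as 0
with p = 1 by convention (there is no variance to partition; the naive ratio
is 0/0).

### Expression ratios

`ddct_ratios()` implements the $2^{-\Delta\Delta C_t}$ method: per sample,
$\Delta C_t$ = target − reference; $\Delta\Delta C_t$ subtracts the
calibrator group's mean $\Delta C_t$; the ratio is $2^{-\Delta\Delta C_t}$.
The calibrator's geometric mean ratio is 1 by construction, which the tests
assert.

## The synthetic-data generator

No raw recordings are deposited for experiments of this kind, so the
package ships a forward simulator rich enough that every analysis stage is
testable by parameter recovery. The latent signal per treatment class is a
phenomenological kinetic model — the field reports trace *shapes*, not
equations, so the functional form is the package's own choice:

* a saturating slow rise $A_{\mathrm{slow}}(1 - e^{-s/\tau_{\mathrm{slow}}})$
  after application (the slow cAMP accumulation single peptides evoke);
* plus a fast alpha-function transient with unit peak (the rapid extra
  response seen on co-application);
* optionally multiplied by a delayed exponential decline after a set time
  (the post-400 s sag seen at half dose);
* a `ttx_blocks_fast` flag removes the fast component only, modeling
  TTX block of action-potential-dependent (indirect) input while the direct
  slow response persists.

The sensor model maps the latent signal $c(t)$ to channels as
$\mathrm{CFP} = C_0(1 + g c)b(t)$ and $\mathrm{YFP} = Y_0(1 - g c)b(t)$
(rising cAMP lowers FRET: donor up, acceptor down), with shared bleaching
$b(t)$, additive background (emitted in the table so the analysis can undo
it), spillover $k\cdot\mathrm{CFP}$ added to the measured YFP, and additive
Gaussian noise per channel. With matched $k$, baseline-normalized iFRET
percent change has the closed form $\left(\frac{1+gc}{1-gc}-1\right)\times
100$, independent of $C_0$, $Y_0$ and $k$; `latent_amplitude_for_peak()`
inverts it so simulations can inject exact peak percentages. The calcium
simulator is linear: $\mathrm{GFP} = G_0(1+c)b(t)$, so a latent peak of
0.034 is exactly a 3.4% $\Delta F/F_0$ peak.

Default generator conditions, chosen once as plausible for bright, binned
CCD recordings of cell-body ROIs and stated here because they define what
the recovery tests mean: baselines $C_0 = 1000$, $Y_0 = G_0 = 1000$–$2000$
a.u., gain $g = 0.05$ per unit latent signal, per-channel noise SD 0.2% of
the channel baseline (ROI means pool many pixels), lognormal neuron-to-neuron
amplitude jitter with mean 1 and CV 0.10, background 50 a.u. with a drift of
0.02 a.u./s, bleaching off by default, 0.2 Hz frames for 1000 s with
application at 100 s, and 5 brains × 4 neurons per treatment. The
demonstration spec labels its classes after the standard bath-application
panel (HL3 vehicle, NKH477 positive control, PDF and sNPF singly and with
TTX, co-application at full and half dose, co-application in TTX) with peak
amplitudes placed near the approximate percentages such experiments report;
these are demonstration settings, not measurements, and the shipped YAML
files make every number explicit.

What the simulator does *not* emulate — and hence what passing recovery
tests do not show about real data: photon shot noise and camera gain
structure, focus drift and motion, within-trace kinetic variability between
neurons (only amplitudes are jittered), receptor-level pharmacology
(dose is a label, not a model input), and correlated noise across neurons of
one brain.

Reproducibility is structural: a seed is a required field of every spec, and
each neuron's random stream is derived deterministically from (seed,
treatment, brain, neuron), so simulations do not depend on iteration order
and identical configurations yield byte-identical output files.

## Problem sizes used by the test suite

The suite verifies the arithmetic chain against an independent
frame-by-frame oracle on 1000 random 20-frame traces (tolerance 1e-12
relative), exact rank-sum p-values against exhaustive enumeration for all
tie-free group sizes up to 8 × 8, type-I error calibration on 1000 all-null
simulated experiments per arm (acceptance band 5% ± 1.5%), and parameter
recovery of injected 0/5/10/15% peaks at 20 neurons per treatment over 200
simulated experiments (within 1.5 percentage points in at least 90% of
replicates). These sizes were chosen to make the checks statistically
meaningful while keeping a full run in the low minutes on a single core.

## Known limitations

* SEM and all tests treat neurons as independent; brains contribute counts
  only. Strong brain-level correlation would make the reported SEMs
  optimistic.
* The windowed maximum is an upward-biased estimator of the true peak in
  the presence of noise (the maximum of noise is positive on average); at
  the default noise level this bias is well under one percentage point, and
  the recovery tests quantify it, but heavier noise would widen it.
* The Bonferroni correction is the only multiplicity method provided, by
  design; with large families it is conservative.
* The synergy bootstrap tests additivity of medians on the percent-change
  scale; synergy on other scales (e.g. multiplicative) is a different
  hypothesis.
* The two-factor ANOVA refuses designs with empty cells rather than
  attempting estimable-function gymnastics.
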