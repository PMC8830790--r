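---
title: "Quantifying olfactory integration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying olfactory integration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfint)
```

## The scientific problem

A worm crawling on an assay plate that carries both an attractive odorant
(such as isoamyl alcohol, IAA, a food signal) and a repulsive one (such as
2-nonanone, a threat signal) must integrate the two cues into a single
behavioral decision. In the standard two-sided plate paradigm, the tested
odorant(s) and a buffer control sit on opposite sides of a 10-cm agar
plate, 3.33 cm from the center, each next to a drop of sodium azide that
immobilizes every worm that reaches it. Worms start at the center; after
one hour the plate is scored by counting worms in three areas: the
odor-side strip, the middle strip, and the control-side strip.

`olfint` implements the complete quantitative pipeline for this paradigm —
behavioral scoring, calcium-trace quantification, the statistical
comparison procedure used in such studies — together with two synthetic
data generators that stand in for raw behavioral and imaging data, so
every stage can be validated against known ground truth.

## Behavioral scoring

**Choice index.** For a plate with counts $n_{toward}$ (odor side),
$n_{away}$ (control side) and $n_{middle}$,
$$CI = \frac{n_{toward} - n_{away}}{n_{toward} + n_{away} + n_{middle}}.$$
$CI = +1$ means every worm chose the odorant, $-1$ every worm avoided it.
The denominator includes middle-area worms by default because all three
areas are counted when a plate is scored; `denominator = "decided_only"`
restricts it to worms that left the middle, for sensitivity analyses.

**Choice classification.** In the attractant assay the odor side is the
correct choice; in the repellent and pairing assays the side away from
the odorant(s) is correct; middle-area worms made no choice. The
*incorrect choice* is the sum of the wrong choice and no choice. These
percentages always total 100 by construction.

**Integration index.** With group choice indices for the attractant alone
($CI_{A}$), the repellent alone ($CI_{R}$) and the pairing ($CI_{P}$),
$$I = 100\,\% \times \frac{CI_{P} - CI_{A}}{CI_{R} - CI_{A}}.$$
$I = 0\%$ means the pairing behaves like the attractant alone (no
blocking); $I = 100\%$ means the repellent completely blocks the
attractant. The formula has no intrinsic bounds — over-shooting repulsion
gives $I > 100\%$ — and values are reported unclamped. The index is
undefined when $CI_{R} \approx CI_{A}$; a tolerance (default $10^{-6}$)
guards the denominator and violations raise an error rather than return
an unstable number.

Because per-assay distributions of the index are built from three
*different* sets of plates, an aggregation rule is needed.
`group_integration()` offers two: `per_plate` (default) computes one
index per pairing plate against the group-mean single-odorant indices,
matching the one-point-per-assay presentation of box plots with plate
counts in parentheses; `point` computes a single index from the three
group means. Both report the per-plate values and their median, so the
choice is transparent.

```{r scoring-example}
classify_choices(2, 46, 2, "pairing")
integration_index(0.95, -0.95, -0.95)
```

## Calcium-trace quantification

Traces are GCaMP intensity series sampled at 5 frames/s with a stimulus
epoch marked by onset and removal times. All quantities are computed on
the frame grid with left-closed, right-open windows — a deterministic,
testable convention for which frame belongs to which window.

* **Baseline** $F_{base}$: mean raw intensity over the 10 s before
  onset. Traces whose baseline is not positive are rejected rather than
  offset — silently shifting raw intensities would corrupt the meaning
  of $\Delta F/F$.
* **dF/F**: $100 \times (F - F_{base})/F_{base}$, in percent. Its mean
  over the baseline window is zero by construction, and any metric built
  on it is invariant to multiplicative rescaling of the raw trace.
* **ON / OFF response**: mean dF/F over a response window after
  onset/removal minus the mean over the 10-s window before that
  transition. Sensory neurons AWB and ASH use 10-s windows; the
  interneurons AVA, AIB and RIM use 5-s windows; AVA additionally has a
  late-ON variant (the 2nd 10-s window after onset) selectable per
  analysis, since its response to odor removal of some stimuli develops
  slowly. Which AVA window applies to a given panel is an analysis
  choice, so it is a config field (`ava_variant`) rather than hard-wired.
* **OFF latency**: the time after removal for the signal to first reach
  the pre-removal mean plus $k \times SD$ ($k = 3$ by default; sample SD
  with $n-1$, the standard convention for a 50-frame window). The removal
  frame itself is the first candidate. If the threshold is never reached
  before the recording ends the latency is reported as the cap — 40 s by
  default, reflecting the recording length of the protocol this analysis
  was built for; other datasets can change it.

Group summaries (`summarize_traces()`) align traces at stimulus onset and
report the per-frame mean and SEM ($SD/\sqrt{n}$), the quantities drawn
as line and ribbon in imaging figures. Grids differing by less than half
a frame are resampled by nearest frame; anything larger is an error, not
a silent interpolation.

## The statistical comparison procedure

Figure-level statistics follow a normality-branched decision tree, the
procedure used by common graphing software:

1. Every group is tested for normality — D'Agostino–Pearson omnibus
   ($K^2$, the default in that software) for $n \ge 8$, Shapiro–Wilk
   below that, where the omnibus kurtosis transformation is unreliable.
   One failing group sends the whole comparison to the nonparametric
   branch (the joint rule matches the binary phrasing of figure
   legends); a pooled-residuals alternative is available via `scope`.
   Zero-variance groups cannot be normality-tested and are treated as
   failing.
2. Two groups: two-tailed unpaired Student's *t*-test, or two-tailed
   Mann–Whitney.
3. Many groups vs a control: one-way ANOVA with Dunnett's multiple
   comparisons test, or Kruskal–Wallis with Dunn's test. Dunn's
   comparisons are two-sided with Bonferroni correction over the
   vs-control family only, mirroring Dunnett's scope.
4. Stars: `****` $p<0.0001$, `***` $p<0.001$, `**` $p<0.01$, `*`
   $p<0.05$, `ns` otherwise, with strict inequalities.

The omnibus test is implemented in the package (no installed R package
provides it) and is verified in the test suite against an independent
reference implementation to ten decimal places. Dunnett's test is
delegated to `multcomp::glht`; because its multivariate-*t* p-values are
computed by quasi-Monte-Carlo integration, the package evaluates them
under a locally fixed RNG substream (restored afterwards) so repeated
calls are bit-identical.

## The plate simulator

The generator is an agent-based biased run-and-tumble walk, the classic
abstraction of worm chemotaxis in which the probability of reorienting
depends on the recent change in perceived odor concentration.

**Odor landscape.** Each odorant contributes a static isotropic Gaussian
kernel $G(p; s) = \exp(-|p-s|^2 / 2\sigma^2)$ centred on its spot, with
$\sigma = 2$ cm; the perceived signal is
$S = g_{att} A_{att} G(p; s_{att}) - g_{rep} A_{rep} G(p; s_{rep})$.
A static field rather than a diffusion PDE: no concentration landscape
is published for this assay, and at desk scale the behaviorally relevant
feature is the gradient structure, which the kernels provide. Amplitudes
$A$ scale with the volume of odorant spotted (1 = the 1-µL reference
dose); in the pairing assay both kernels sit at the odor spot, the
simplest faithful reading of drops placed beside each other.

**Navigation.** Per time step ($\Delta t = 1$ s), a worm tumbles with
probability $1 - e^{-\lambda \Delta t}$ where
$\lambda = \lambda_0 e^{-\beta\, dS/dt}$, clamped to $[0, \lambda_{max}]$
($\lambda_0 = 0.25\,s^{-1}$, $\beta = 10$, $\lambda_{max} = 2\,s^{-1}$).
A tumble redraws the heading uniformly; otherwise the worm advances
$v\Delta t$ ($v = 0.015$ cm/s) along its heading. The plate edge
reflects; entering either 0.5-cm azide disk freezes the worm
permanently. All worms start at the center, as in the real assay, and
run for 3600 s.

**Genotype presets.** The sensory gains are the calibrated, documented
part of the model. `wild_type` ($g_{att} = 45$, $g_{rep} = 180$) makes
the single-odorant assays saturate ($|CI| \gtrsim 0.95$, incorrect
choices well under a few percent) and makes the repulsive drive dominate
the pairing assay, so blocking emerges from linear valence summation
with repellent dominance — no explicit gating term (an intentionally
minimal mechanism; a multiplicative suppression could be added but is
not needed to reproduce the qualitative phenomenology). Scaling the
repellent amplitude through 0.1–2× the reference dose sweeps the pairing
index from attraction to full repulsion, the dose-dependent blocking
pattern. `osm5_like` ($g_{att} = 10$, $g_{rep} = 5$) models a
ciliary-structure mutant: single-odorant chemotaxis keeps its sign
(attraction barely reduced, avoidance clearly weakened), while the
pairing response collapses toward attraction and the integration index
falls far below wild type. `attractant_presets("benzaldehyde")` (0.8)
encodes the slightly weaker but still strongly attractive benzaldehyde
dose used in generalisation experiments.

**Randomness.** One seeded RNG stream drives each plate, with the worm
population stepped as a single vectorized block; plate $i$ of a batch
uses `seed + i`. Given a seed, a plate is bit-reproducible, and the
simulator restores the caller's RNG state. Per-worm substreams were
considered and rejected: the package never executes worms of one plate
concurrently, so substreams would add bookkeeping without adding
reproducibility.

**What the simulator does and does not emulate.** It reproduces the
statistical structure the scoring assumes — near-multinomial area counts
driven by gradient-following with absorbing odor/control spots, dose
dependence, and genotype contrasts. It has no odor diffusion dynamics,
no worm–worm interactions, no feeding state and no body mechanics;
passing tests demonstrate that the *analysis* behaves correctly on data
with this structure, not that real worms follow this navigation law.

## The trace simulator

The deterministic kernel is built from saturating exponentials: baseline
$F_0$; an ON component rising toward `on_amplitude` (signed, % of $F_0$)
with time constant `on_tau` during the stimulus; after removal a small
undershoot (2% of $F_0$, deflecting opposite to a positive OFF
transient — the dip commonly seen at stimulus transitions) followed,
`off_latency_true` seconds after removal, by an OFF component rising
toward `off_amplitude` with constant `off_tau`. I.i.d. Gaussian noise of
SD `noise_sd` (% of $F_0$) is added per frame. Each frame reports the
exponential accumulated by the end of its interval, so in the
fast-kinetics limit the kernel is a clean step at the transition frame —
this makes closed-form expectations exact on the grid and keeps
threshold-crossing latency a well-posed recovery target: without the
undershoot, pre-transient frames sit exactly at the threshold's
reference level and noise alone can trigger spurious crossings.

Epoch defaults (10-s baseline, 30-s stimulus, 40-s post-removal) satisfy
the analysis definitions (10-s reference windows, 40-s latency cap); the
stimulus length itself is a free protocol choice. Kinetic constants are
deliberately fast (`on_tau` 0.3 s, `off_tau` 0.4 s) so that windowed
means recover preset amplitudes to within the saturation deficit —
a fraction of a percentage point at these settings. Saturating
exponentials, not measured GCaMP6 kinetics: no kinetic fits are
published for these panels, and only the sign, amplitude-ordering and
latency structure needs to be emulated. Accordingly the preset library
encodes the qualitative panel patterns — e.g. AWB activated by IAA but
suppressed by 2-nonanone and by the mixture (with a rebound OFF
response), ASH responsive to 2-nonanone but not IAA, AVA/AIB/RIM
suppressed where their panels show suppression, and `osm5_like` variants
with shrunken amplitudes and slower OFF transients — not magnitudes read
off figures.

```{r trace-example}
tr <- simulate_trace(trace_preset("AWB", "nonanone", seed = 7),
                     neuron_class = "AWB")
response_metrics(tr)
```

## Numerical choices and degenerate inputs

* Windows are left-closed, right-open on the frame grid, with a
  $10^{-6}$-frame epsilon absorbing floating-point grid round-off.
* The latency threshold uses the sample SD ($n-1$); the removal frame is
  the first crossing candidate; equality counts as crossing.
* Empty plates, zero/negative baselines, non-uniform sampling, inverted
  stimulus epochs, orphan trace ids, unknown assay types or neuron
  classes, and p-values outside $[0,1]$ all raise immediate errors with
  the offending record named; nothing is silently repaired.
* An integration-index denominator within tolerance of zero errors
  rather than returning an arbitrarily large number.

## Problem sizes used in validation

The shipped test suite validates scoring against a per-worm tally oracle
on 1,000 random plates, latency against an exhaustive frame-scan oracle
on 500 random synthetic traces, amplitude/latency recovery on 50 noisy
traces per preset, wild-type calibration and dose-dependence on 20
simulated plates per condition, and the type-I error of the two-group
branch on 2,000 null replicates — sizes at which the Monte-Carlo bands
asserted by the tests are comfortably wider than sampling noise.

## Known limitations

* The simulator's navigation law is one plausible minimal mechanism; it
  is calibrated to endpoint statistics (area counts), not trajectories.
* The static odor field ignores the hour-long evolution of real
  headspace gradients, so absolute time-to-capture is not meaningful —
  only endpoint distributions are.
* Dunn's test adjusts by Bonferroni over the vs-control family; other
  software may use slightly different familywise schemes.
* The normality branch follows the joint per-group rule; pooled
  testing (`scope = "pooled"`) can disagree near the threshold.
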