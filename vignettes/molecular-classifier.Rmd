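---
title: "Compiling linear classifiers into strand-displacement chemistry"
author: "DNAclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling linear classifiers into strand-displacement chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNAclassify)
```

## The model

DNAclassify simulates a DNA-based molecular classifier: a linear decision
rule over a panel of circulating miRNA biomarkers,

$$\mathrm{score} = \sum_i W_i \, [\mathrm{Input}_i] + b,$$

executed not in software but by a well-mixed strand-displacement reaction
network, with the diagnostic call read out as fluorescence in two channels
(HEX for the positive class, ROX for the negative). The package contains
both halves of that statement: an in-silico training pipeline that produces
the rule from two-class expression data, and a compiler plus mass-action ODE
simulator that turn the rule into chemistry and execute it on per-patient
miRNA concentration panels.

### Weights as concentration ratios

The core primitive is a catalytic amplifier paired with a competitive
inhibitor, both consuming the same input strand at the same rate constant
$k$:

$$\mathrm{Input} + \mathrm{Amplifier} \xrightarrow{k}
  \mathrm{Input} + \mathrm{Output}, \qquad
  \mathrm{Input} + \mathrm{Inhibitor} \xrightarrow{k} \mathrm{Waste}.$$

Dividing the two rate laws eliminates time: the amplifier pool decays as a
power of the inhibitor pool, and in the limit $t \to \infty$, provided
$[\mathrm{Input}]_0 \le [\mathrm{Inhibitor}]_0$ (the linear regime),

$$\lim_{t\to\infty}[\mathrm{Output}](t) =
  [\mathrm{Input}]_0 \,
  \frac{[\mathrm{Amplifier}]_0}{[\mathrm{Inhibitor}]_0}.$$

A signed real weight $W$ is therefore realized by setting
$[\mathrm{Inhibitor}]_0 = [\mathrm{Amplifier}]_0 / |W|$ and routing the
unit's output strand to a shared positive- or negative-channel strand
according to $\mathrm{sign}(W)$. Because shared output strands simply
accumulate, summation is free; subtraction is performed by a
cooperative-hybridization annihilator that consumes one positive and one
negative output strand per event, so only the majority channel survives to
displace its reporter. `closedFormOutput()` and `closedFormSignal()` expose
these limits and serve as independent oracles for the ODE simulator in the
test suite.

### Simulator

`simulateNetwork()` integrates mass-action ODEs with a stiff-capable solver
(deSolve's lsoda) at rtol 1e-8 / atol 1e-10. The weight identity is a
$t\to\infty$ limit, so endpoints matter more than transients: a steady state
is declared when every $|d[s]/dt|$ falls below 1e-6 nM/s, and the horizon is
doubled (up to 8 times the request) until it is reached. Concentrations are
nM, time is seconds, and bimolecular rate constants default to
1e-4 nM^-1 s^-1 (1e5 M^-1 s^-1, a typical toehold-mediated displacement
rate); the absolute rate only sets the time scale — doubling all rate
constants and halving the horizon is exactly neutral, a symmetry the test
suite checks. Solver negatives below 1e-9 nM are clipped to zero; anything
larger raises a warning because it indicates tolerance trouble rather than
round-off.

### Annihilator and reporters

The annihilator is modelled symmetrically: either output strand binds the
gate reversibly through a toehold (`kOn` = 2e-3 nM^-1 s^-1,
`kOff` = 0.05 s^-1), and the bound intermediate collapses irreversibly with
a strand of the opposite channel (`k2` = 1e-2 nM^-1 s^-1). Weak, reversible
single-strand binding matters: a surviving majority is released and
reported rather than sequestered inside the gate. Reporters are
deliberately slow (2e-6 nM^-1 s^-1, a short toehold) so that they read out
the finished subtraction instead of racing it; with these defaults the
premature-reporting leak into the minority channel is below ~0.03 nM on the
validated input range, and the HEX-ROX margin equals the ideal weighted
difference essentially exactly because the leak is symmetric. The
annihilator and reporter pools are sized at twice the corresponding channel
capacity so neither is ever limiting.

A sample is called for a class when the normalized HEX-ROX margin exceeds
the indeterminate threshold $\delta$, set to 5% of the total channel
capacity $\sum_i |W_i| \cdot \mathrm{input}_{\max} + |b|$. Near-tie inputs
annihilate almost completely on both channels, reproducing the
both-channels-low diagonal of the two-input demonstration classifier;
$\delta$ is a documented free parameter because the underlying work never
states a numeric call threshold.

## The front end: from femtomolar RNA to nanomolar inputs

Circulating miRNAs sit far below the concentrations strand-displacement
circuits need, and their sequences are heterogeneous. The front end models
the two wet-lab steps that fix this.

### Asymmetric PCR

`simulatePCR()` runs a discrete per-cycle recurrence with a limiting
(universal) primer at 25 nM and an excess (miRNA-specific) primer at 1 µM.
While the limiting primer lasts, the double-stranded amplicon pool grows by
a factor $1+E$ per cycle ($E = 1$ by default). In the cycle where the
limiting primer runs out, templates it cannot serve are still extended by
the excess primer and become single-stranded product; thereafter every
cycle adds $E \times$ (template pool) of ssDNA until the excess primer is
gone. Because the exhaustion cycle is (log of) the initial template, the
ssDNA at a fixed readout cycle (52 by default) is linear in
$\log_2$ of the starting miRNA concentration — the property that lets a
fixed-cycle readout encode relative abundance. Two modelling commitments
are worth stating explicitly:

* **Switch-cycle overflow.** Extending the unserved templates in the
  exhaustion cycle smooths the phase switch. Without that term the readout
  is a staircase in whole cycles, and the dilution-panel linearity degrades
  well below what is observed experimentally.
* **Template carryover.** `templateDilution` (default 0.1) models the
  protocol step of carrying 2 µL of the RT product into a 20 µL PCR. At
  face-value concentrations the top of the 0.1-10 pM panel would exhaust
  the excess primer before cycle 52 and clip the readout; the tenfold
  carryover dilution keeps the whole validated panel inside the linear
  window. With both commitments the seven-point dilution panel fits
  $\mathrm{ss} \sim \log_2 c$ with $R^2 > 0.999$.

The recurrence quantizes the phase switch to whole cycles, which leaves a
ripple of roughly ±1 nM (about 4% of a tenfold step) around the ideal
log-line; the equal-increment property therefore holds to ~5%, not exactly.

### Associative strand displacement and input calibration

`convertSSDNA()` models sequence conversion as one effective bimolecular
step (ssDNA + Converter -> Input) with a conversion yield γ and an optional
zeroth-order leak; split-position and junction-length optimizations of the
physical design enter only through those two scalars (defaults γ = 1,
leak = 0). Below converter saturation the produced input is γ · ssDNA, so
the conversion preserves the concentration relationships the PCR step
encoded.

The amplified ssDNA is of order 10^2-10^3 nM while the classifier's
validated input window is 1-6 nM, and the log transform leaves a large
additive constant. `calibrateInputMap()` therefore solves for two physical
knobs: a post-PCR dilution (slope) and a threshold sink — a fast
stoichiometric Input + Threshold -> Waste stage run after conversion
(offset) — that together place the 0.1-10 pM panel exactly onto 1-6 nM.
The fitted affine map input = a · log2(conc_pM) + b is stored in the
classifier JSON; it is what makes the molecular margin and the in-silico
score directly comparable, and every concordance statement in the package
is made through it.

## In-silico training

The training pipeline mirrors standard biomarker-panel practice:

1. `differentialExpression()` retains features whose between-class log2
   fold change reaches 2 (fourfold).
2. `rankFeatures()` ranks them by random-forest permutation importance
   (Mean Decrease Accuracy), with Gini impurity as tiebreaker.
3. `trainPanels()` fits linear-kernel SVMs on the top-k features for
   k = 1..10, with the positive-class misclassification penalty twice the
   negative (early diagnosis is worth more than a false alarm), C = 1.
   Features are standardized before fitting and the weight vector is
   unscaled afterwards.
4. `selectClassifier()` takes the highest validation AUC, breaking ties
   toward the smaller panel.

Weights are exported to the nM input space through the stored affine map,
rescaled by a common positive factor so the largest magnitude is 2.5 (a
linear SVM's weight scale is arbitrary; pinning it to the
experimentally-validated weight range keeps the one-decimal grid
meaningful and the inhibitor concentrations in the tens-of-nM window), and
rounded to one decimal. Rounding is applied after model selection and the
validation AUC is re-checked afterwards; on the synthetic study the change
is below 0.001. The split is stratified 50/50 and every stage is
deterministic given its seed — identical seeds serialize to bit-identical
classifier JSON.

## What the synthetic data emulate — and what they do not

`generateExpression()` draws a two-class study shaped like a serum miRNA
profiling cohort: 345 positive and 958 negative samples, 200 features on a
log2 microarray-like scale with baselines in 6-10, five informative
miRNAs with planted effects of 2.3-3.0 log2 units in alternating
directions, and Gaussian within-class noise. Two parameter choices deserve
their rationale:

* **Noise SD 1.4 log2 units.** Chosen so that a five-marker panel separates
  the classes at AUC ≈ 0.99 — the regime reported for real serum miRNA
  panels — meaning single markers are informative but imperfect. Much
  smaller noise makes every sub-panel perfect (and panel-size selection
  meaningless); much larger noise makes the task unrealistically hard.
* **Smallest planted effect 2.3.** The fold-change estimate at these sample
  sizes has a standard error near 0.09, so a planted effect exactly at the
  fourfold screen would fail its own designation half the time; 2.3 puts
  the weakest marker about three standard errors above the screen.

Patient panels are drawn from the same class-conditional model, converted
to plasma concentrations via per-feature offsets (log2 conc_pM =
expression − offset) and clamped to the 0.1-10 pM assay range; draws are
accepted when the in-silico score has the class-consistent sign with a
margin at least 1.2 δ (or below δ in borderline mode, for
indeterminate-call testing).

The generator is Gaussian in log space with independent features; it does
not emulate platform normalization artifacts, feature-feature correlation,
batch structure, or heavy-tailed outliers. Passing tests on these data
show that the pipeline recovers what it was designed to recover under its
own model assumptions — they do not certify performance on any real
cohort, and the package deliberately does not claim to reproduce any
particular study's AUCs or marker identities.

## Numerical choices and degenerate inputs

* Solver: lsoda, rtol 1e-8, atol 1e-10; steady tolerance 1e-6 nM/s;
  auto-extension up to 8×; 201 output points per integration.
* Independent cross-checks in the tests use the radau solver at rtol 1e-10
  with separately hand-coded derivatives.
* Exact score ties in `evaluateInSilico()` return the sentinel
  "indeterminate", as do molecular margins below δ.
* Degenerate fits: constant readouts give slope 0 and R² = 0 by
  convention; log-linear fits require ≥ 3 points and positive
  concentrations.
* Confusion counts are integers and the three fractions exact; percentages
  are rounded half-up to one decimal only when formatted. Indeterminate
  calls count as misclassifications — conservative, since the clinical
  table being mirrored has no indeterminate category.
* Reaction networks are validated structurally (orders 1-3, positive rate
  constants, declared species only, non-negative initials) before any
  integration.

Problem sizes throughout the examples and tests — seven-point dilution
panels, 6×6 input grids, 10+10 patient cohorts, one 345/958 training study
— are the sizes the emulated workflow itself uses.

## Known limitations

* Mass-action, well-mixed, isothermal chemistry only: no stochastic (SSA)
  regime, no spatial effects, no temperature dependence, no sequence-level
  kinetics or cross-talk between imperfectly orthogonal strands.
* The absolute rate constant is a free parameter (a calibration hook, not
  a fitted value); only endpoint properties are quantitatively meaningful,
  not transient time courses.
* The bias term's molecular realization (a constant auxiliary input on a
  weight-1 unit) is a model commitment; the underlying experimental work
  does not describe one.
* The entropy-driven amplifier is abstracted to a single effective
  catalytic step; intermediate complexes are not resolved.
* The PCR model ignores sequence-specific priming efficiency, primer
  dimers and late-cycle efficiency decay; efficiency is constant across
  cycles.
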