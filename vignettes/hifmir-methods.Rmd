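---
title: "Methods: the hifmir kinetic model of microRNA control of HIF-VEGF signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hifmir kinetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological system and the model

`hifmir` implements a deterministic, two-compartment (cytoplasm/nucleus)
ordinary-differential-equation model of how hypoxia-responsive microRNAs
shape VEGF output in endothelial cells. Four functional sub-networks are
wired together:

1. **Oxygen sensing.** PHD2 and FIH assemble with Fe(II) and
   2-oxoglutarate into holoenzymes that load molecular oxygen; the
   O2-loaded holoenzymes hydroxylate cytoplasmic HIF-1a, which pVHL then
   commits to degradation. At 21% ambient O2 (209 uM dissolved) this
   keeps HIF-1a near-undetectable; as O2 falls the hydroxylation flux
   collapses and HIF-1a escapes.
2. **HIF-dependent transcription.** Stabilised HIF-1a shuttles
   reversibly into the nucleus, dimerises with HIF-1b (coactivator
   recruitment is folded into the dimerisation step), and the HIF-1
   complex drives Hill-type transcription of VEGF mRNA, pri-let-7 and
   the mRNA-destabilising protein TTP. TTP closes a delayed negative
   feedback loop by destabilising HIF-1a mRNA (and VEGF mRNA), which
   produces the characteristic overshoot in the hypoxic HIF-1a time
   course.
3. **let-7 biogenesis and targeting.** pri-let-7 processing (Drosha
   cleavage and nuclear export combined into one step) feeds Dicer
   maturation into mature let-7, which reversibly associates with AGO1
   to form RISC. Nuclear let-7:AGO1 stimulates pri-let-7 processing (a
   positive auto-regulatory loop). let-7 RISC routes the AGO1 and Dicer
   mRNAs into p-bodies, where they are translation-silent, decay slowly
   and leak back only weakly -- so hypoxia-induced let-7 suppresses its
   own loading machinery (mutual negative feedback).
4. **miR-15a repression of VEGF.** A lumped VEGF-targeting miR
   ("miR-15a", standing in for the family of such miRs) is produced
   constitutively -- its transcription is O2-independent -- matured by
   Dicer, loaded on AGO1, and its RISC captures VEGF mRNA into a bound
   intermediate that transfers to p-bodies. Free miRs decay much faster
   than RISC-bound miRs, and AGO1 is protected from degradation while in
   a RISC, so AGO1 abundance controls both miR stability and silencing
   capacity.

The hypoxic VEGF response is therefore a sum of a fast transcriptional
component (HIF-1 drive) and a slower *desuppression* component: falling
AGO1 and Dicer drain the miR-15a RISC pool, releasing VEGF mRNA for
translation. The slow component dominates, which is why AGO1
overexpression or let-7 antagonism are effective in-silico
anti-angiogenic levers, and why miR-15a mimics -- which still need Dicer
processing and AGO1 loading at the time both are scarce -- do little.

Out of scope by design: ascorbate binding, nuclear HIF stabilisation,
reactive-oxygen-species and succinate effects, an explicit HIF/PHD
feedback loop, a distinct HIF-2a species (lumped into HIF-1a), explicit
Drosha/XPO-5/CBP/p300/GW182 species, stochastic simulation, and
tissue-level angiogenesis.

## Units, dimensions and rate laws

Concentrations are micromolar, time is minutes. The canonical instance
has 47 species, 57 reactions and 91 kinetic parameters; a reversible
binding or transport step is a single reaction carrying a forward and a
reverse constant (net flux `kf*prod(reactants) - kr*prod(products)`), so
47 reactions are pure mass action and 10 use saturating kinetics
(Michaelis-Menten forms, including enzyme-scaled variants
`kcat*[E]*[S]/(Km+[S])`, and Hill activation
`k0 + Vm*[X]^n/(K^n+[X]^n)`). Zero-order synthesis is mass action with
an empty reactant list; translation reads its template mRNA as a
modifier. Dissolved O2 is a *clamped boundary species*: a protocol sets
its concentration and the integrator holds it constant, because the
experimental setting regulates ambient oxygen rather than letting the
cell consume it down. The clamp can be dropped by removing `"O2"` from
the model's `clamped` field.

Ambient-percent to dissolved-concentration conversion is linear through
the anchor 21% = 209 uM, so 2% = 19.9 uM and 1% = 9.95 uM. Copy numbers
convert to concentration through a 1-pL cell volume (about 602,214
copies per uM).

## Parameter provenance and calibration

The registry's starting scaffold is a set of class medians from
large-scale quantification studies, normalised to a 1-pL cell: mRNA
decay 1.2e-3 min^-1, miRNA decay 1e-4 min^-1, protein decay 2.5e-4
min^-1, translation 3 min^-1 per mRNA, normoxic mRNA level 2.8e-5 uM and
protein level 0.08 uM, with calibration bounds two orders of magnitude
either side (`default_priors()`).

No reference reaction/parameter listing for this pathway is distributed
with the package. The shipped registry is therefore the package's own
calibrated instance: rate constants were tuned, by
bounded Levenberg-Marquardt refinement and targeted manual balancing of
the module time-scales, so that the model reproduces the quantitative
anchors reported for this system --

* 3.5-fold intracellular VEGF after 24 h at 2% O2 (achieved: 3.60),
* 2-fold VEGF after 8 h at 1% O2 (achieved: 1.77),
* a total-HIF-1a overshoot peaking near 10 h at 2% O2 with a decline to
  an elevated plateau (achieved: 6.9-fold peak at 8.9 h, plateau
  3.1-fold),
* a relative AGO1 decline to roughly half its normoxic level by 24-48 h
  (achieved: 0.55 at 24 h, 0.42 at 48 h),
* a 48-h total-HIF-1a level that decreases monotonically across 0.5, 1,
  2, 5 and 21% O2.

These anchors are **calibration constraints, not blind predictions**;
the registry records this per parameter through its provenance tags
(`fitted` for tuned values, `default_median` for values kept at their
class median, `user` for perturbation-layer constants), and
`fit_parameters()` results carry the same note in their provenance
field. Species initial concentrations in the registry are the computed
normoxic steady state, so pre-equilibration from a cold start converges
in a fraction of a second.

Two placements deserve comment. The PAD (peripheral arterial disease)
variant raises the let-7 transcription constant `kp21` -- the HIF-1
half-saturation of pri-let-7 transcription, in uM -- to 0.464 uM, which
moves the Hill midpoint far above any attainable HIF-1 level and so
cripples hypoxic let-7 induction while leaving everything else intact.
Second, Dicer processing of pre-miR-15a is parameterised close to
saturation (`kcat_dicer_mir15a * [Dicer]` just above the constitutive
production flux), making mature miR-15a output Dicer-limited: this is
what lets Dicer scarcity in hypoxia curtail miR-15a, gives Dicer
overexpression its (small) effect on top of AGO1 overexpression, and
makes miR-15a mimics inefficient. A side effect is that the hypoxic
pre-miR-15a pool relaxes extremely slowly, which the steady-state
finder accommodates (see below).

## Numerical choices

* **Integration.** deSolve's `lsoda` with `rtol = 1e-8`,
  `atol = 1e-12` uM; output stored at >= 1-min resolution by default so
  flux integrals (total VEGF produced) are accurate. Halving the
  tolerances moves every reported readout by far less than 0.1%.
* **Negative concentrations.** Values below -1e-9 uM abort with an
  integrator error; small negative round-off is clipped to zero for
  reporting only.
* **Steady states.** `find_normoxic_steady_state()` integrates in
  growing chunks until `max |dX/dt| / max(X, 1e-9)` < 1e-8 min^-1, with
  a Newton polish step (pseudo-inverse of a finite-difference Jacobian,
  so conserved-pool null directions are harmless) when integration
  alone stalls near the tolerance. States are memoised per parameter
  set.
* **Perturbations** are declarative and applied at t = 0 on top of the
  pre-equilibrated state: overexpression bumps an initial mRNA
  concentration, mimics bump the precursor pool, siRNAs and miR
  antagonists dose dormant perturbant species already wired into the
  canonical network (siRNA Kd defaults to 1e-3 uM and is honoured by
  adjusting the off-rate; antagonist binding releases the AGO1 from the
  inactivated RISC, as the antagonist duplexes with the miR). A dose of
  zero is an exact no-op. CoCl2 is modelled as stoichiometric
  sequestration of the PHD2/FIH holoenzymes, preventing O2 loading --
  the kinetic form is a modelling choice (only the fact of
  hydroxylation inhibition is established) calibrated to reproduce the
  qualitative normoxic VEGF induction by 200 uM CoCl2.
* **Onset delay** is operationalised as the first time a rising species
  gains 5% of its 120-min increase; the metric is an artifact of this
  package and should be read qualitatively.
* **Sensitivities.** The complex-step route integrates the system with
  the parameter at `p*(1+i*h)` through `zvode` and takes
  `Im([A](t))/(p*h)`. The default `h = 1e-7` (not the arbitrarily small
  steps exact-arithmetic complex-step allows) keeps the imaginary
  component safely above the solver's absolute-error floor; since
  complex-step has no subtractive cancellation the truncation error at
  this step is ~1e-14 relative. Central differences (relative step
  1e-4) are the documented fallback and agree to better than 1e-3.
  Shares follow the non-dimensionalise (`(p/[A]) * dA/dp`), integrate
  (|.|, trapezoid), normalise-to-sum pipeline; absolute values are
  taken before integration so shares are non-negative (a pie-chart
  representation forces this; whether signed sensitivities were
  integrated in the original analysis is not determinable, and the
  absolute-value choice is recorded here as ours). A 1e-12 uM floor
  guards the `[A]` denominator. The let-7:AGO1 stimulation of pri-let-7
  processing enters as a linear velocity multiplier rather than a
  saturating activator -- the simplest form consistent with a positive
  loop, and exposed as an ordinary parameter (`kf_drosha_fb`) so the
  saturating alternative can be emulated by refitting.
* **Screens** pre-equilibrate the *untreated* model at normoxia, dose
  at t = 0 of the test condition, and integrate the VEGF translation
  flux `kt_vegf * [free VEGF mRNA]` over 24 h ("total VEGF produced" is
  a production quantity, independent of VEGF decay; the end-point VEGF
  level is attached as an attribute for cross-checks). Saturating doses
  are 10x the normoxic binding-partner pool for antagonists and
  siRNAs, and the top of the 0.01-0.08 uM transfection scale for mRNA
  overexpression and miR mimics.

## What the synthetic fixtures emulate -- and what they do not

`generate_western_fixture()` produces normalised time-course datasets
the way densitometry-quantified Western blots are reported: sampled at a
few time points, strictly positive, normalised to the t = 0 lane, with
multiplicative log-normal noise of a chosen coefficient of variation
(default 0.15) and `sd = cv * value` attached. The t = 0 anchor is
noise-free because it is the normalisation reference. Real blot data
additionally carry antibody nonlinearity, saturation, background
subtraction artefacts and between-gel batch effects that this generator
does not emulate -- so a passing calibration round-trip demonstrates
that the optimiser and objective are wired correctly and that the freed
parameters are identifiable from this data shape, not that the model
would calibrate cleanly against raw laboratory blots.

Calibration itself is bounded Levenberg-Marquardt (`minpack.lm`) on
log10-parameter scale with optional multistart (log-uniform draws inside
the prior bounds, seeded). Only a declared free subset is fitted:
fitting all 91 parameters to a couple of normalised curves is hopelessly
non-identifiable. The shipped tests free the let-7/RISC axis pair
(`kf_ago1_pb`, `Vm_let7`) against AGO1 and let-7 relative time courses;
with both datasets the pair is well identified (recovery to ~0.3% from
noise-free fixtures), while single-curve fits leave a compensated ridge
-- readouts, not parameters, are then the recoverable quantities.

## Problem sizes used by the shipped tests

The default test-suite and acceptance runs use 24-48 h protocols on
1-60-min output grids, screens over one saturating dose per strategy at
1-2% O2, sensitivity spans of 4-12 h, and two 8-point calibration
fixtures -- sizes chosen so the full suite exercises every module while a complete
run stays in the minutes range on a single core.

## Known limitations

* The registry is a calibrated reconstruction, not a transcription of
  a measured parameter table; individual rate constants should be
  treated as effective values (the anchors above, and the
  qualitative behaviours tested in `tests/testthat/`, are what is
  pinned down).
* The relative magnitude of the fast (transcriptional) and slow
  (desuppression) VEGF components is constrained only by the 8-h and
  24-h anchors; intermediate-time behaviour is interpolation.
* CoCl2 produces a much stronger HIF-1a stabilisation than hypoxia
  (hydroxylation is almost fully blocked at 200 uM); only the direction
  of its VEGF effect is validated.
* let-7 antagonism in this parameterisation suppresses 24-h VEGF
  production ~1.6-fold, less than AGO1 overexpression (~14-fold at the
  0.08 uM dose); the ordering between these two strategies depends on
  dose scales that are not pinned by any quantitative anchor.
* No pharmacokinetics: doses are intracellular initial-condition bumps;
  all treatments are applied at t = 0.
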