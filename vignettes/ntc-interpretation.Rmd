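---
title: "Methods: NtC-based interpretation of 31P NMR parameters in B-DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NtC-based interpretation of 31P NMR parameters in B-DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcnmr)
library(dplyr)
```

## The model

A B-DNA duplex in solution populates, at every dinucleotide step, a
mixture of discrete backbone conformers. `ntcnmr` represents a step's
conformational state by the nine torsions
(δ₅, χ₅, ε, ζ, α₃, β₃, γ₃, δ₃, χ₃), all in degrees on [0, 360), and a
conformer class (an NtC letter such as BB00) by its class-defining
torsion vector plus class-specific NMR parameters: the ³¹P shielding
σᵢ (ppm) and the coupling Jᵢ = ³J(P,H3′) (Hz), optionally with
geometric dependences — a shielding surface over the (α₃, ζ) plane and
a coupling curve over ε, both piecewise-constant on 10° bins.

The observable model is a mixture average. With per-step class weights
wᵢ (relative occurrences in the ensemble, Σwᵢ = 1):

* population weighting: σ = Σᵢ wᵢ σᵢ and J = Σᵢ wᵢ Jᵢ;
* probability averaging: for the BI-family (BB00, BB01) and BII-family
  (BB04, BB07) classes the scalars are replaced by expectations of the
  class's surface/curve under the class-conditional torsion
  distributions observed at that step,
  σᵢ → Σₖⱼ Pᵢ(αₖ, ζⱼ) σᵢ(αₖ, ζⱼ) and Jᵢ → Σₖ Pᵢ(εₖ) Jᵢ(εₖ);
  all other classes are treated by their scalars.

Chemical shifts are reported against the duplex-internal A6pT7
phosphate, δ = σ(A6pT7) − σ, which makes calculated and measured shifts
directly comparable and cancels any constant offset in the shielding
scale. Experimental shifts recorded against an external standard are
re-referenced by δ = δ′ − δ′(A6pT7).

### Assumptions

* Snapshots are classified hard (each frame belongs to exactly one
  class); populations are occupation frequencies, not Boltzmann
  weights.
* Class NMR parameters are transferable across steps: the same σᵢ/Jᵢ
  (or surface/curve) applies at every phosphate. Sequence-specific
  electronic effects beyond the backbone geometry are not modelled.
* Probability averaging assumes the geometric dependence of σ is
  captured by (α₃, ζ) and that of J by ε; the remaining torsions enter
  only through classification.

## Classification

A frame is assigned to the class minimizing Σₜ d(t_class, t_frame)²
where d is the signed minimal-arc difference in (−180°, 180°]. Two
deliberate choices:

* **Circular differences.** Torsions are periodic: 359° and 1° are 2°
  apart. A plain difference would misclassify conformations near the
  0/360 branch cut, where B-DNA α and ζ commonly sit.
* **No square root, no 1/n.** Ranking by squared distance preserves
  the argmin of an RMSD ranking (monotone transform) and avoids
  needless arithmetic.

Ties are broken by the lexicographically smallest class id — they have
measure zero for continuous data, but determinism matters for
reproducibility. All nine torsions are weighted equally, including the
glycosidic χ angles; the classification metric gives no reason to
privilege a subset, and equal weighting keeps the metric interpretable
as a plain torsion-space distance. An optional squared-distance cutoff
can leave far-from-everything frames unassigned; it is off by default,
so every frame is assigned to its nearest class.

## Histograms and bin conventions

Torsion distributions are discretized with a fixed 10° step: bin k
covers [10(k−1), 10k)°, k = 1..36. The convention is half-open, and a
value of exactly 360° normalizes to 0° and lands in bin 1. Class
histograms are conditional on the class *and* the step (the quantity a
step-resolved observable needs); they are computed by counting, never
smoothed — the piecewise-constant 10° discretization is part of the
model, and kernel estimates would silently change the averaging
results. The joint (α₃, ζ) histogram is used for the shielding
expectation; a product-of-marginals variant is available behind the
`product_marginals` flag for comparison, since with strongly correlated
α/ζ fluctuations the two differ, and the joint form is the default
because it makes strictly fewer independence assumptions.

## Agreement metric

Agreement between calculated and measured per-step values is
summarised by the root-mean-square deviation
`sqrt(mean((calc − exp)²))`. Parts of the ³¹P literature print this
quantity under the name "mean absolute deviation"; recomputing the
published benchmark tables shipped with the package
(`dd_shift_benchmark()`, `dd_coupling_benchmark()`) settles the
reading: the RMS form reproduces the printed 1.16 ppm / 2.46 Hz /
2.61 Hz, while mean(|dev|) would give ≈ 0.54 ppm for the first of
these. The package therefore implements the RMS form and documents the
naming discrepancy rather than inheriting it: the function is called
`rms_deviation()`. One printed value (0.27 ppm for NMR-structure
shifts) recomputes to 0.28 from the rounded printed columns; tests
treat it at ±0.01, an input-rounding sensitivity, not a defect of the
metric.

## Population fitting

Roughly 60–80% of the phosphate population falls into BB00, BB01,
BB04, BB07. For fitting, BB00+BB01 form BI′ and BB04+BB07 BII′, with
within-group ratios frozen at their input values and every class
outside the pool left bit-identical. The only free parameter per step
is the BII′ fraction x of the pooled mass, which makes each observable
an affine function of x; fitting is an exact scalar solve, clamped to
[0, 1] (with a flag) when noise pushes the solution outside the
physical simplex. Clamping rather than failing is deliberate: for an
affine map the clamped boundary value is still the best achievable
within the simplex. If BI′ and BII′ predict the same observable the
step carries no information; the step is reported degenerate and keeps
its incoming weights.

The two-stage procedure fits x per step to experimental ³J first.
Because the reference phosphate is itself refitted, the reference
shielding σ(A6pT7) is refreshed from the J-stage result before the δ
stage converts shift targets into shielding targets,
σ_target = σ(A6pT7) − δ_exp, and refits each step. The δ stage
*overwrites* the J-stage split rather than compromising between the
two — the simplest semantics consistent with a stagewise description;
a regularized joint fit is a possible extension, not implemented
because no weighting between the two observables is defined. Fitting
always uses population averaging (scalars), matching how fitted
observable columns are defined; surfaces enter only the forward
probability-averaging mode.

## Temperature series

For a series of per-temperature observables and populations, the
package computes raw differentials against a 20 °C baseline:
Δδ = δ(T) − δ(20 °C) per step, and sectional population differentials
for BI = BB00+BB01, BII = BB04+BB07, and "rest" (configurable). No
smoothing or van 't Hoff modelling is applied — the differentials are
the result, and monotonicity or thermodynamic interpretation is left
to the user. Two invariants are enforced by construction and tested:
baseline rows are exactly zero, and the three sectional differentials
sum to zero at every (step, T) because populations are conserved.

## The synthetic generator

The generator emulates the structure of the data the pipeline is
designed for, at study conditions fixed once:

* **Duplex.** The 11 internucleotide steps of the self-complementary
  dodecamer CGCGAATTCGCG (C1pG2 … C11pG12), with A6pT7 present as the
  reference.
* **Mixtures.** BI-dominated stem steps (A5pA6 … T8pC9; w(BB00) =
  0.65), tail steps with elevated BII-family weight (C1pG2, G4pA5,
  C9pG10 … C11pG12; w(BB04)+w(BB07) = 0.45), and intermediate
  near-terminal steps — echoing the qualitative stem/tail contrast
  seen in B-DNA crystal ensembles.
* **Noise.** Independent wrapped-Gaussian torsion noise, default
  sd = 8°, around the class-defining torsions; 2000 frames per step by
  default (20 ns at a 10 ps frame spacing). Class centers are
  realistic B-form torsion values, jittered by ±2° per seed while
  preserving ≥ 40° pairwise separation in at least one torsion, which
  keeps the sd = 8° misassignment rate below 1%.
* **Parameters.** Synthetic class scalars reproduce the magnitude
  ordering of B-DNA phosphates (canonical BII deshielded by ~4.2 ppm
  relative to canonical BI, the bridging BB04 intermediate between
  them). Coupling curves follow the standard empirical Karplus
  parameterization for ³J(H3′,P), 15.3 cos²θ − 6.2 cosθ + 1.5 Hz with
  θ = ε − 120°; shielding surfaces are smooth low-order periodic
  functions of (α₃, ζ) with ~1 ppm amplitude. Both are shifted
  per class so the grid value at the class-defining bin equals the
  class scalar — the consistency invariant the validator enforces.
  These grids are synthetic stand-ins for quantum-chemically computed
  dependences and carry no claim of matching any published surface.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: correlated multi-torsion motions (noise is
independent per torsion), sequence-dependent class parameters,
solvation/Mg²⁺ electronic effects (these enter only by supplying an
alternative class table), slow conformational kinetics (frames are
i.i.d. draws), and experimental artefacts beyond additive Gaussian
noise on the observables.

## Numerical choices

* Weights are exact ratios of integer counts, so Σw = 1 is testable at
  1e-12 rather than a loose tolerance; histogram normalizations
  likewise.
* Fit degeneracy threshold: 1e-9 on the BI′-vs-BII′ observable
  contrast.
* Zero-noise end-to-end recovery (generate → classify → populations →
  average → reference → fit) is required to 1e-10, the solver's
  round-off envelope.
* Grid consistency (surface/curve vs class scalar at the defining bin)
  is validated at 1e-9.
* Degenerate inputs: empty class tables, absent reference steps,
  zero-frame steps, mismatched step sets, and family classes without
  grids in probability mode are all hard errors naming the offender;
  a class with zero assigned frames yields an all-zero histogram (an
  explicit empty signal, not an error).

Test problem sizes are chosen to exercise the statistics without
waste: 300 frames/step for the shared classified run, 10⁴ frames for
multinomial-recovery checks, 10⁵ draws for uniform-histogram checks,
200 replicates for the noisy-fit bound, and 1000 random frames for the
classification oracle comparison.

## Limitations

* The class inventory is data, not code: the six-class synthetic table
  spans the dominant B-DNA conformers, but real analyses should supply
  the full NtC table with quantum-chemical parameters as input files.
* Scalar per-class parameters ignore within-class geometry except
  through the (α₃, ζ) and ε dependences of probability averaging.
* The fit adjusts one degree of freedom per step; it cannot repair
  populations of classes outside the BI′/BII′ pool, and steps dominated
  by such classes will keep systematic residuals.
* Internal referencing ties every shift to the A6pT7 phosphate; any
  error in the reference's own description propagates to all steps
  (the J-stage reference refresh mitigates, but does not remove, this).
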