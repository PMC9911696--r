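---
title: "Recovering RNA 3D topology from AFM molecular surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering RNA 3D topology from AFM molecular surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatopo)
```

## Why topology is recoverable from a height image

A liquid-cell AFM image of a folded RNA is a single 2-D height map, yet
folded RNA is built almost entirely from A-form duplexes whose width
(~25 Å) and pitch (~30 Å) sit right at the resolution of a sharp tip.
Because secondary structure is usually known beforehand, the unknowns
reduce to how a handful of rigid helices are arranged around flexible
junctions — a low-dimensional problem that a single molecular surface can
constrain.  `rnatopo` implements that reconstruction at coarse-grained
resolution and stops there: converting the result to all-atom coordinates
and refining it is a separate (external) modelling step, out of scope here.

## The coarse-grained model

Two beads per nucleotide: a backbone bead (rendering radius 4.0 Å) and a
base bead (3.5 Å).  Duplexes are ideal A-form helices with 11 bp/turn and a
2.73 Å rise (pitch 30.0 Å).  Backbone beads sit 12.5 Å from the helix axis
so that the conventional width measure — twice the maximal radial backbone
distance — reads 25 Å.  One consequence worth knowing: with beads at the
duplex envelope, a flat-lying duplex renders ~3.3 nm tall, somewhat above
the ~2.5 nm apparent height a real instrument reports; the width convention
was kept because downstream geometry (junction spacing, clash distances,
image footprints) is anchored to it.  The inter-strand azimuthal offset is
−140°, which merges the two backbone ridges under a 1-nm tip so a duplex
corrugates at its pitch (~3.0 nm), the behaviour seen on real duplexes.

`assemble_topology()` lays helix axes flat in the xy-plane (molecules
adsorb flat on mica), fans junction arms at preset or seeded angles and
threads unpaired nucleotides along circular arcs between their anchors.
Builds are audited — bonds within [2, 12] Å, non-bonded beads at least 6 Å
apart — and retried with fresh jitter before failing.  Pseudoknots are
rejected: the builder handles nested structure; tertiary contacts are the
fitting's job (declared kissing-loop partners become inter-chain pairing
restraints).

## Scoring and dynamic fitting

The simulated surface is a hard spherical tip (nominal radius 1 nm) resting
on the bead spheres: the height at a pixel is the lowest apex position at
which the tip touches any bead, i.e. a grey-scale dilation of the bead
cloud; the molecule first drops so its lowest bead touches the mica plane.
Image agreement is the uncentered cross-correlation `C_AFM` evaluated over
the union of pixels where either image exceeds 0.1 nm — whole-frame sums
would be dominated by the empty background and flatten the score.

`C_AFM` enters the energy as `V_AFM = θ^AFM N k_BT (1 − C_AFM)`.  Covalent
terms are harmonic about references taken from a fresh deterministic
assembly of the same secondary structure: bond lengths everywhere, angles
and dihedrals only within helices (weak angle terms along linkers), so
junction geometry — the quantity being inferred — is deliberately
unrestrained.  Pairing and stacking are flat-bottom wells (half-widths 1.0
and 0.75 Å) about A-form separations; contacts combine a finite soft-core
repulsion (2000 k_BT at zero separation, so clashes are expensive but never
singular) with a screened-charge backbone repulsion (amplitude 0.5 k_BT,
screening length 10 Å).

The optimizer is Metropolis Monte-Carlo with geometric cooling (default
3 → 0.3 k_BT over 20 000 steps), chosen because the dilation-rendered image
has no useful analytic gradient.  Moves: rigid rotation of a helix subtree
about its junction pivot (8° in-plane spread, occasional 2.5° out-of-plane
tilt), Gaussian displacement of an unpaired nucleotide (1 Å), and global
pose moves.  Every proposal re-renders the simulated image.  The reported
structure operationalizes "lowest energy among the best-correlated": of all
frames within 0.002 of the maximal `C_AFM`, the one with minimal `E_total`.

The weights default to `θ^AFM = 3` with unit covalent/secondary weights and
`θ^contact = 0.5`.  They are empirical; 3 is the value at which the image
term reliably out-pulls the junction arms on an 80-nt phantom while leaving
helices ideal.  All of them, and every geometric constant above, live in
`cg_config()` / `fit_weights()` rather than in code.

## What the synthetic data emulate — and what they do not

`make_phantom()` provides an 82-nt three-helix junction (10-bp closing
helix, two 9-bp arms with tetraloops, 5-nt junction linkers) in three
junction geometries — Y (±75°), candy (0°/−90°), compact (+100°/0°) — that
are pairwise >10 Å apart in backbone RMSD, plus a 14-nt hairpin for cheap
tests.  Noise ladders add per-pixel Gaussian perturbations whose 2σ
amplitude is the stated percentage of the image's highest point, clipped at
±2σ; the twelve standard levels are ±5…±100%.  The percentage-as-amplitude
reading keeps the ladder interpretable and the clipped SD stays within ~2%
of σ.

SAXS mixtures attach a Poisson-like error model `σ(q) = f·(√(I·I₀) +
0.001·I₀)` with `f = 0.001`, emulating heavily averaged synchrotron frames
(hundreds of 1-s exposures); Gaussian noise of exactly that σ is added, so
the generating truth scores χ² ≈ 1 by construction.  The ITC generator sums
two physically motivated components — an exothermic one-site binder and an
endothermic-then-exothermic two-site binder (induced-fit-like) — rendered
as Gaussian power pulses of different kinetics (fast/narrow vs slow/broad),
which is what makes the two components separable rank-1 terms for the SVD.

What passing these tests does **not** show: real AFM images carry tip-shape
asymmetry, adsorption-induced flattening, drift and line noise that the
ladder's white noise does not emulate; real scattering has inter-particle
and hydration contributions absent from the uniform-bead Debye model; real
thermograms have instrument response functions rather than clean Gaussians.
The synthetic environment validates the inference machinery, not the
instrument physics.

## Numerical choices

* Helix axes are measured by a cylinder fit (principal component refined to
  minimize the variance of radial distances, with a vanishing radius
  penalty to break degenerate ties); plain PCA is biased by partial turns.
* The corrugation period is the first autocorrelation maximum of the
  centreline profile restricted to the high plateau — FFT bins are too
  coarse on a ~25-pixel window, and raw peak spacing is confused by the
  partially resolved double ridge within one turn.
* The ensemble χ² uses the published closed-form scale
  `a = ΣI_saxs·I_syn / ΣI_saxs·I_saxs` verbatim as the default; note this
  expression is not the least-squares scale (for `I_syn = I_saxs/c` it
  returns `c`, not `1/c`), so the exact scale/offset-closure identities
  hold only under the alternative joint convention (`convention = "lsq"`).
  Both are provided; the offset `b` is always the χ²-minimizing background
  given `a`.
* Volume fractions are optimized in softmax coordinates by BFGS with a
  Nelder-Mead polish — the iterate cannot leave the simplex; an optional
  seeded multistart guards against local minima; collinear conformer curves
  raise a degeneracy warning.
* P(r) is a second-derivative-regularized indirect Fourier transform with
  zero endpoints; λ sits at the L-curve corner; negative nodes are pinned
  to zero by a short active-set loop; Dmax is the smallest candidate whose
  misfit is within 10% of the scan optimum (misfit falls steeply while
  Dmax is too small and plateaus beyond the true dimension).
* The one-site isotherm is the exact quadratic mass-balance solution over
  finite injections with perfusion displacement correction; an ODE
  integration of the classical Wiseman form is provided as a cross-check
  and agrees to <1%.  Multi-site free-ligand concentrations come from a
  vectorized safeguarded Newton solve.  The two-site fit runs a small
  deterministic multistart (four starts bracketing the cell concentration)
  because the six-parameter surface has genuine local minima.
* SVD component selection takes "normalized autocorrelation" as the lag-1
  autocorrelation of each left singular vector — a scalar singular value
  has no autocorrelation, so the filter must act on the component's time
  course; eigenvalue fractions are reported as σᵢ/Σσ (first power).
  Rank-1 reconstructions σ·u·vᵀ are sign-unambiguous.
* The F-test uses α = 0.05 with (3, n−6) degrees of freedom and falls back
  to the one-site model whenever the larger model fails to reduce the
  residual sum of squares.

## Problem sizes used in the shipped tests

The validation suite runs the 82-nt phantom with 15 000-step fits for
recovery (5 seeds) and 2 500-step fits across the twelve-level noise
ladder (3 seeds); SAXS calibration uses 200-point q grids with 50 noise
replicates; ITC model selection uses 50 replicate isotherms of 25
injections.  These sizes make the whole suite run in a few minutes on one
CPU while leaving each statistical check comfortably powered; all of them
scale up through function arguments.

## Known limitations

A single top-down height image cannot distinguish a molecule from its
vertical mirror image; the fitting explores in-plane rearrangements and
mild tilts, so enantiomeric ambiguity is resolved only by prior knowledge.
Helices are rigid ideal duplexes — internal loops, bulges and non-canonical
pairs are representable only through the flexible-linker machinery.  The
Debye calculator omits hydration-layer and excluded-volume terms, so
absolute intensities are arbitrary (the χ² scale `a` absorbs this).  The
baseline model in peak integration is local-linear; strongly overlapping
injections are rejected rather than deconvoluted.
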