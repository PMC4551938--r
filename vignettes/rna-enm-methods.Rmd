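---
title: "Elastic network models of RNA: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic network models of RNA: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaenm)
```

## The model and its assumptions

An elastic network model replaces the full energy landscape of a folded RNA
by a single quadratic basin around a reference structure.  Each nucleotide
contributes up to three interaction centers — the phosphorus atom (P) for
the phosphate, C1' for the sugar and C2 for the base — or, in the all-atom
variant, every heavy atom.  Any pair of beads whose *reference* distance is
below a cutoff $R_c$ is joined by a harmonic spring penalizing deviations of
their distance from its reference value; all springs share one master
constant $k$.  The model therefore assumes:

- fluctuations are small enough that a second-order expansion is adequate
  (no unfolding, no large-scale rearrangements);
- the reference structure is representative of the basin (for ensembles we
  provide `centroid_of_ensemble()`, the conformer with the lowest mean
  square distance to all others after superposition);
- interactions are pairwise, isotropic in the spring sense, and
  distance-selected — chemistry enters only through the bead geometry.

Expanding to second order gives $U = \tfrac12\,\delta r^\top M\,\delta r$
with the standard pairwise-harmonic Hessian: the off-diagonal $3\times3$
block of a springed pair is $-k_{ij}\,\hat u\hat u^\top$ with $\hat u$ the
unit reference separation; diagonal blocks are minus the sum of the bead's
off-diagonal blocks.  This construction makes $M$ symmetric, positive
semi-definite and translation-invariant by construction, and every
`enm_hessian()` output is validated against these invariants in the test
suite, including a full finite-difference check of the underlying energy.

The equilibrium covariance is $C = k_BT\,\tilde M^{-1}$, the pseudoinverse
over the complement of the rigid-body modes.  We set $k_BT = k = 1$: every
quantity the package compares (Pearson correlations of MSF profiles, RWSIP,
correlation with SHAPE reactivities) is invariant under a global scale of
$C$, so the physical constants never matter in practice.  Absolute values
reported in Å² are therefore in units of $k_BT/k$.

## Zero modes and connectivity

A connected, non-collinear network has exactly six zero-energy modes (three
translations, three rotations).  `zero_modes()` counts eigenvalues below a
*relative* tolerance, $10^{-10}\lambda_{\max}$; the tolerance is relative
because the spectrum scale is arbitrary.  Two special cases shape the
contracts:

- a two-bead network has only five rigid modes (rotation about its own axis
  acts trivially), so `covariance_from_hessian()` accepts up to six zero
  modes and refuses only networks with *more* — those are disconnected or
  geometrically degenerate, which we treat as a modelling error rather than
  silently discarding additional modes;
- collinear bead sets always carry at least seven zero modes and can never
  pass the six-mode test, so `enm()` rejects them up front.

`min_viable_cutoff()` scans the standard grid (3–30 Å in 1 Å steps by
default) for the smallest cutoff whose network passes the six-mode test —
the left end of the physically meaningful cutoff range, and in practice
close to the cutoff of best agreement with reference ensembles.

## Coarse-graining and marginalization in a degenerate Gaussian

To compare models built on different bead sets one reduces the Hessian to
the shared beads with the Schur complement
$M^{\mathrm{eff}}_a = M_a - W M_b^{+} W^\top$.  Two numerical points deserve
care, and both follow from the Hessian being *singular*:

1. **The discarded block may be singular even in a connected network.**  Any
   discarded bead holding fewer than three springs leaves a locally soft
   direction in $M_b$ (e.g. the middle bead of a three-bead chain is free,
   to second order, to move perpendicular to its two springs).  Because the
   full Hessian is positive semi-definite, the coupling block always lies in
   the range of $M_b$, and the generalized complement with the pseudoinverse
   $M_b^{+}$ (cut at $10^{-12}\lambda_{\max}$, with the range condition
   verified explicitly) is the correct energy minimization over the
   discarded coordinates.  A *disconnected* network, by contrast, makes the
   reduction ill-posed; it is detected from the full spectrum and refused.

2. **The marginal covariance is not the raw covariance sub-block.**  For a
   Gaussian with singular precision, the sub-block of the full pseudoinverse
   covariance retains fluctuation components that look like rigid motions of
   the subsystem but are internal motions of the whole network; the
   covariance obtained from $M^{\mathrm{eff}}_a$ has exactly those inherited
   rigid modes removed.  The exact identity — verified to $10^{-8}$ relative
   over random networks and subsets in the tests — is
   $P\,C_{aa}\,P = (M^{\mathrm{eff}}_a)^{+}$ with $P$ the projector onto the
   range of $M^{\mathrm{eff}}_a$.

The same physics dictates the comparison protocol of `cutoff_scan()`: the
ensemble-side covariance for a bead role is computed after re-superposing
the frames *on that role's beads alone*, which removes the subsystem's
rigid-body content from the ensemble side just as the effective matrix
removes it from the model side.  Without this, the scan systematically
misranks cutoffs.

## Essential-space similarity

`rwsip()` implements the eigenvalue-weighted overlap
$\mathrm{RWSIP} = \sqrt{\sum_{ij}\lambda_{Ai}\lambda_{Bj}(v_{Ai}\cdot v_{Bj})^2 \,/\, \sum_i \lambda_{Ai}\lambda_{Bi}}$
over the full ranked spectra.  Conventions: spectra of different rank are
zero-padded (zero eigenvalues contribute to neither sum); the denominator
pairs eigenvalues by rank; a zero denominator (no shared spectral weight) is
an error rather than a silent 0/0.  The measure is symmetric, lies in
$[0,1]$, and is invariant under rotations that mix only degenerate
eigenspaces — all verified numerically in the suite.

Ensemble covariances use the divisor-$n$ (time-average) definition; at
realistic frame counts the distinction from $n-1$ is immaterial.  Residual
rigid-body modes left in an aligned ensemble's covariance are kept, not
projected out: superposition makes them small, and removing them would hide
alignment problems from the user.

Two references calibrate significance in scans: the **split-half**
self-agreement of the ensemble (RWSIP between covariances of the first and
second halves of the frame sequence — an upper reference), and the
**random-network null** (the fully connected network with spring constants
drawn uniformly from $[0,1]$, which encodes no structure-specific
information beyond the reference geometry — a lower reference, averaged over
10 seeds by default and reported with its spread).

## The SHAPE-reactivity proxy

SHAPE probing reports per-nucleotide backbone flexibility.  Within the
linear regime of the model, the variance of the distance between any two
beads follows analytically from the covariance,
$\sigma^2_d = \sum_{\mu\nu} (\tilde d^\mu \tilde d^\nu/\tilde d^2)\,
(C_{ii} + C_{jj} - C_{ij} - C_{ji})_{\mu\nu}$,
and the profile of variances of *consecutive base-base (C2–C2) distances*
serves as a structure-based reactivity proxy.  `c2c2_profile()` computes one
value per consecutive intra-chain residue pair and maps pairs to nucleotides
by the `mean_flank` rule (each nucleotide averages its flanking pairs; chain
ends keep their single flank); `five_prime` and `three_prime` assignments
are exposed because the bookkeeping choice is not dictated by the physics.
`shape_correlation()` matches residues by key, drops missing *and negative*
reactivities (the conventional "no data" encoding in published profiles) and
reports the dropped count alongside the correlation.

Angle variances (e.g. the O2'–P–O5' angle) are computed from ensembles only;
no analytic propagation is provided because the arccosine derivative is
singular near straight angles and, empirically, angle fluctuations carry
little signal for reactivity.

## Synthetic fixtures: what they emulate and what they do not

`generate_duplex()` builds an ideal two-strand helix with A-form-like
parameters (rise 2.81 Å, twist 32.7°, sugar/base/phosphate radii
9.4/5.0/9.9 Å).  The second strand is the exact two-fold rotation image of
the first about an in-plane dyad axis whose azimuth is chosen so that paired
base beads sit ≈3 Å apart — the strands genuinely interact at realistic
cutoffs (minimum viable cutoff 6 Å at every length), and the structure is
*exactly* palindromic under the end-to-end relabeling, which turns MSF
symmetry into a machine-precision test.  `sample_ensemble()` draws frames
from the model's Gaussian through the eigendecomposition square root, so
rank-deficient covariances are sampled exactly within their image;
`random_cloud()` supplies seeded, well-separated random geometries.

These fixtures validate the *mathematics* of the pipeline.  They do not
emulate real RNA: no sequence effects, no non-Watson–Crick pairs, junctions
or tertiary contacts, no anharmonicity, and the sampled ensembles are
exactly Gaussian — so passing tests certify the estimators and identities,
not the biological accuracy of any particular ENM on any particular
molecule.

## Numerical choices and defaults

| choice | value | rationale |
|---|---|---|
| cutoff comparison | strict `<` | immaterial off a measure-zero set; fixed for bit-reproducibility |
| zero-mode tolerance | $10^{-10}\lambda_{\max}$, relative | spectrum scale is arbitrary |
| $M_b$ pseudoinverse cut | $10^{-12}\lambda_{\max}$ | separates soft modes from noise |
| covariance scale | $k_BT = k = 1$ | all comparisons scale-free |
| ensemble covariance divisor | $n$ | time-average definition |
| default scheme | SBP | best accuracy/complexity balance among coarse models |
| default scan grid | 3–30 Å, step 1 | standard assessment range |
| pair→nucleotide rule | `mean_flank` | symmetric, length-preserving |
| alt-loc rule | highest occupancy, tie → file order | crystallographic convention |
| 5'-terminal missing P | omit bead + warn | preserves one bead = one chemical group |
| negative variances | clipped at $-10^{-12}$, error below | floating-point guard only |

Validation problem sizes: random networks up to 30 beads (50 trials per
identity), the 16-nt duplex (48 SBP beads) as the standing fixture, $10^4$
frames for parameter-recovery checks and $10^5$ draws for Monte-Carlo
validation of the analytic distance variance.  Recovery ensembles use
amplitude 0.1: the sampled Gaussian is exact at any amplitude, and a small
one keeps superposition strictly in the linear regime the model describes.
Two statistical conventions are worth noting.  Entrywise Monte-Carlo checks
of covariance recovery are asserted jointly (≥99% of entries within 3
standard errors, all within 6): with thousands of entries, demanding every
entry within 3 SE would fail with probability near one for a correct
sampler.  And linear-regime convergence of the analytic distance variance is
measured against the *same-draw linearized* variance, so the fixed
Monte-Carlo realization cancels and the remaining deviation — the genuine
nonlinearity — decreases monotonically as the amplitude shrinks.

## Known limitations

- Harmonic, single-basin physics: no anharmonicity, no barrier crossing, no
  time scales (covariances only, no dynamics).
- No electrostatics or ion effects; the cutoff/spring scheme is blind to
  charge.
- PDB input only (no mmCIF); no structure repair or missing-residue
  modelling — residues lacking a representative atom simply contribute no
  bead for that role.
- Distance-dependent spring constants are exposed only as a user hook
  (`spring_fun`); no default functional form is shipped.
- SHAPE profiles are used as given: no normalization pipeline is included,
  and negative/missing reactivities are dropped rather than modelled.
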