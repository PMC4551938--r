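# rnaenm

Elastic network models (ENMs) for RNA structural flexibility, in R.

RNA molecules fluctuate around their folded structures, and much of that
motion is captured by a remarkably simple harmonic model: reduce the
structure to beads, connect every bead pair closer than a cutoff `R_c` by a
spring of constant `k`, and read equilibrium fluctuations off the resulting
quadratic energy.  `rnaenm` implements this model at eight bead
granularities — every combination of the phosphate (P atom), sugar (C1') and
base (C2) interaction centers, plus an all-heavy-atom variant — together
with the full toolkit needed to assess such models against conformer
ensembles (e.g. MD trajectories or NMR bundles) and against SHAPE
chemical-probing data.  It is aimed at structural bioinformaticians who want
RNA flexibility estimates orders of magnitude cheaper than simulation, and
at method developers who need a reference implementation of the ENM
assessment machinery.

## The model

For bead deviations `δr` from the reference structure, the energy is the
second-order expansion

    U = 1/2 δrᵀ M δr

where the 3N×3N Hessian `M` has off-diagonal 3×3 blocks `−k_ij (û ⊗ û)` for
each springed pair (û the unit reference separation) and diagonal blocks
that enforce translation invariance.  The equilibrium covariance is the
pseudoinverse over the non-rigid modes,

    C = k_B T · M̃⁻¹ ,

with the six roto-translational zero modes removed (`k_B T = k = 1`
throughout: every comparison made here is invariant to that global scale).
On top of this the package provides:

- **MSF profiles** — per-bead mean square fluctuation, the trace of the
  diagonal covariance blocks;
- **effective interaction matrices** — the (generalized) Schur complement
  `M_a − W M_b⁺ Wᵀ` that integrates out discarded beads, so models of
  different granularity are compared on common degrees of freedom;
- **RWSIP** — the root weighted square inner product between two essential
  dynamical spaces `{λ, v}`,
  `RWSIP = sqrt( Σ_ij λ_Ai λ_Bj (v_Ai · v_Bj)² / Σ_i λ_Ai λ_Bi )`,
  1 for coinciding ranked spaces, 0 for orthogonal ones;
- **ensemble-side machinery** — Kabsch superposition, divisor-n ensemble
  covariances, centroid selection, cutoff scans with a fully connected
  uniform-random-spring null network and split-half self-agreement as
  significance references;
- **a SHAPE-reactivity proxy** — the analytic variance of the distance
  between consecutive base (C2) beads, computable directly from the
  covariance, plus correlation against measured SHAPE profiles;
- **synthetic fixtures** — deterministic ideal duplexes and seeded Gaussian
  conformer ensembles, so the whole pipeline is testable offline.

## Worked example

```r
library(rnaenm)

dup <- generate_duplex(n_bp = 8)          # 16-nt ideal duplex, SBP beads
fit <- enm(dup, cutoff = 9)               # sharp-cutoff ENM, k = 1
summary(fit)
#> RNA elastic network model
#>   beads:           48 (scheme SBP)
#>   cutoff R_c:      9 A
#>   springs:         399 (mean neighbors 16.62)
#>   total MSF:       168.5 A^2 (per-bead range 1.82 - 10.7)

ens <- simulate(fit, nsim = 2000, seed = 1, amplitude = 0.1)
est <- ensemble_covariance(ens)
rwsip(fit$model, est)                     # 0.9993
msf_correlation(msf(fit), msf(est))       # 0.9995

head(c2c2_profile(fit), 4)                # SHAPE proxy per nucleotide (A^2)
#>   chain resid role     value
#> 1     A     1    B 0.2529386
#> 2     A     2    B 0.2352863
#> 3     A     3    B 0.2165713
#> 4     A     4    B 0.2154784

null_reference_rwsip(dup, ens, n_seeds = 10, seed = 1)$mean   # 0.785
```

The fitted object carries the network, Hessian and Gaussian model; the
2000-frame ensemble simulated from it recovers the model's essential space
to RWSIP 0.999 and its MSF profile to Pearson r 0.9995, while the
random-spring null network floors out near 0.79 — the gap between those
numbers is what makes an ENM informative.  For real structures, replace the
generator with `read_bead_structure("file.pdb", scheme = "SBP")`, and use
`cutoff_scan()` to profile agreement with an ensemble across the standard
3–30 Å cutoff grid.

A command-line tool wrapping the same functions ships in `inst/exec/rnaenm`
(subcommands `build`, `scan`, `shape`, `fixtures`).

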