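---
title: "fapkit: models and methods"
author: "fapkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fapkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fapkit)
```

fapkit implements the computational side of characterizing Fap-type
bacterial functional amyloids: mining *fap* operons from homology-search
hit tables, summarizing the imperfect repeats (IRs) of the FapB/FapC
proteins, helical-geometry arithmetic and fibril assembly, small-angle
X-ray scattering (SAXS) modelling, and Fourier estimation of fibril twist
periodicity from atomic force microscopy (AFM) height traces. This
vignette records the models, the tunable parameters and the numerical and
design choices, so that a user can judge what the package computes and
what its tests do and do not establish.

## Operon mining

The Fap system is encoded by the *fapABCDEF* operon. Candidate genes come
from an upstream `hmmsearch` of five profile HMMs (FapA, FapBC_repeat,
FapD, FapE, FapF) against predicted proteins; fapkit consumes the
per-domain tabular output (`domtblout`) plus a gene coordinate table.

* **E-value filter.** Hits with full-sequence E-value above `1e-5`
  (configurable) are dropped at parse time. The cutoff is applied to the
  full-sequence E-value; filtering on the per-domain independent E-value
  is available (`per_domain = TRUE`) but off by default, because a gene's
  significance is established by its summed-domain score while weak
  individual repeats are still wanted in the repeat census.
* **Clustering.** Genes with retained hits are chained along each contig:
  adjacent genes join one cluster when the intergenic distance — the gap
  between annotated gene boundaries, `start(downstream) − end(upstream) −
  1`, strand-agnostic — is strictly below 5000 bp. Boundary-gap distance
  is the common operon-detection convention; the strict inequality makes
  a 4999 bp gap join and a 5000 bp gap split. Single-linkage chaining is
  order-invariant and partitions the input; the suite verifies this
  against a brute-force pairwise-components oracle.
* **Operon filter and synteny.** A cluster is kept when it has at least
  one FapBC_repeat gene and at least three further HMM-hit genes (i.e.
  at least 4 genes). Because FapB and FapC are detected by one combined
  repeat HMM, identity is assigned by synteny: the first FapBC_repeat
  gene in genomic order is *fapB*, the second *fapC*. A gene hit by
  several HMMs takes the single best full-sequence bitscore identity.
  Clusters with exactly one FapBC_repeat gene keep both designations
  absent and are excluded from the repeat census; clusters with more than
  two (not covered by the synteny convention) have the first two assigned
  and carry a review flag plus a warning.
* **Repeat census.** FapBC_repeat domains on a gene are deduplicated —
  when two alignments overlap by more than 50% of the shorter one, the
  higher per-domain bitscore survives — and survivors are numbered IR1,
  IR2, ... by alignment start. The overlap rule is not part of the
  biology; it simply makes repeat counts well defined on adversarial
  inputs, and the suite checks that no surviving pair exceeds the bound.

## Repeat motifs and logos

Aligned repeats (HMM match-state columns; this package does not align)
are summarized as a position frequency matrix (PFM). Gaps are excluded
from the per-column 20-residue simplex and tracked as a separate gap
fraction, the usual sequence-logo convention. Per-column information
content is `IC = log2(20) − H` bits with `H` the Shannon column entropy,
so IC runs from 0 (uniform) to ≈4.32 (invariant); the standard
small-sample correction is available but off by default.

The consensus motif collapses each column into the compact notation used
for repeat consensus strings (capital = complete conservation, lowercase
= high, Ψ = hydrophobic, `(x/y)` = an even residue pair, `*` = no
conservation). The notation itself carries no numeric thresholds, so the
classifier exposes them: complete ≥ 0.97, high ≥ 0.60, hydrophobic set
sum ≥ 0.60 with no single residue ≥ 0.60, pair members each ≥ 0.30 and
within a factor 2. The hydrophobic set is {A, V, L, I, M, F, W, C}; S, T
and Y are deliberately excluded because the notation distinguishes small
residues (`a`/`s`) from Ψ positions. All thresholds and the set are
arguments, and the classification is deterministic (frequency ties break
alphabetically) and invariant under duplication of the alignment.

## Helical geometry

A fibril's symmetry is the screw operation (rise ρ in Å, twist τ in
degrees) relating consecutive subunits; negative twist means a
left-handed fibril (positive twist is a right-handed rotation about +z
viewed from +z). Derived quantities:

* crossover distance `ρ·360/|τ|` — the axial length of a full 360° turn;
  for (4.8 Å, −2°) and equally for the three-layer unit (14.4 Å, −6°)
  this is 864 Å = 86.4 nm;
* half-twist period `crossover/2` (in nm) — the apparent height-modulation
  period of a twisted fibril lying on a surface, 43.2 nm for the above,
  because the silhouette repeats every 180°;
* composition over n units multiplies rise and twist by n and wraps the
  angle to (−180°, 180°] (−180° maps to +180°, the same rotation).
  Crossover is invariant under composition as long as `|n·τ| ≤ 180°`;
  beyond that the wrapped generator describes the same rotation but a
  different screw pitch, so the identity intentionally stops applying.

`build_helical_assembly()` replicates a monomer n times, rotating copy k
by `k·τ` about z and translating by `k·ρ`; the caller aligns the fibril
axis with z first (`align_principal_axis()` helps). The operation is an
isometry per copy and the suite checks intra-monomer distances to 1e-9
relative. Superposition RMSD uses the standard singular-value
construction with the determinant sign corrected to a proper rotation;
collinear point sets are rejected (no unique superposition). An
independent rotation-search oracle in the tests confirms minimality.

## SAXS modelling

Fibrils in solution are modelled as a long cylinder with an elliptical
cross-section plus a Gaussian-chain term for disordered linkers/termini:

I(q) = S_cyl · P_cyl(q; R, ε, L, σ) + S_pol · P_pol(q; R_g) + b

Both form factors are normalized to 1 at q = 0, so the scales are the
forward intensities of the two components and `b` absorbs residual
background. Conventions and defaults:

* q in nm⁻¹ internally (`read_saxs_curve(..., q_unit = "A")` converts
  Å⁻¹ input); cross-sections are *reported as full axes* `2R × 2εR`,
  the convention in which values such as 3.4 × 11.3 nm² are quoted.
* `L = 100` nm and surface grading `σ = 0.5` nm are fixed by default:
  beyond `L ≳ 2π/q_min` the length only scales the forward intensity
  (the suite checks length-insensitivity of the curve shape), and the
  grading is not identifiable from the cross-section window.
* The grading enters as a Gaussian damping `exp(−q_⊥²σ²/2)` of the
  cross-section amplitude — a choice isolated in one function, since the
  literature states the smearing only up to this convention.
* P_cyl is the orientation average of
  `[2J₁(u)/u]·sinc(qL cos α/2)·exp(−(q sin α)²σ²/2)` with
  `u = q sin α·r(φ)`, `r(φ) = R√(cos²φ + ε² sin²φ)`, averaged with
  weight sin α over the symmetry-reduced domain α, φ ∈ [0, π/2] by
  Gauss–Legendre quadrature. The axial sinc oscillates ~qL/2π times, so
  the α node count scales as `max(128, 0.5·q_max·L + 40)` (φ uses 32
  nodes — its integrand oscillates only a handful of times; both
  configurable, with a convergence check in the test suite). On large
  product grids the smooth kernel `2J₁(u)/u` is tabulated densely and
  interpolated by a cubic spline (relative error ~1e-10), which keeps the
  orientation average fast without giving up quadrature accuracy. At ε = 1 the result matches an adaptive
  single-integral circular-cylinder oracle to better than 1e-6 relative
  for qR ≤ 10.
* P_pol is the Debye chain function `2(e^{−x} − 1 + x)/x²`, `x = q²R_g²`,
  with a series branch below x = 1e-4 making P(0) = 1 exact. Its Guinier
  limit reproduces R_g within 1% for qR_g ≤ 0.3.

**Fitting.** `fit_cylinder_model()` minimizes the weighted residual sum
`Σ((I_model − I)/σ)²`. The linear parameters (S_cyl, S_pol, b) are
profiled out at every step by closed-form weighted least squares with the
scales clamped nonnegative (active-set on at most two constraints); the
shape parameters (R, ε, R_g by default; L, σ fixed) are optimized by
Nelder–Mead followed by a BFGS polish in log space (R, R_g, L > 0;
ε = 1 + e^t ≥ 1). The fit is deterministic given the initial values;
failures to converge are flagged, never silent. Reduced χ² uses
`n_points − n_free` with all free parameters counted.

**Debye scattering of atomic models.** `atomic_debye_intensity()`
evaluates `I(q) = ΣᵢΣⱼ fᵢfⱼ sinc(q rᵢⱼ)` with per-atom excess scattering
lengths `f = Z − ρ_solv·V_displaced` (ρ_solv = 0.334 e Å⁻³; single-atom
displaced volumes from standard solvent-excluded tabulations), or
user-supplied `f`. The hydration layer — water near the fibril surface is
denser than bulk — is modelled explicitly: cubic-grid beads (2 Å spacing)
within 3 Å of the van der Waals surface, each carrying an excess
scattering length of 10% of bulk water times the voxel volume; thickness,
spacing and excess fraction are configurable. For large assemblies a
pair-distance histogram (bin width 0.1 Å) replaces the exact double sum;
at that bin width the two agree to well under 0.5% for q ≤ 5 nm⁻¹.
`fit_scale_offset()` then matches a computed curve to data with a
closed-form two-parameter (scale, constant) weighted fit, the standard
final step when comparing model scattering with measurement.

## AFM periodicity

A twisted fibril adsorbed on mica shows a height modulation whose period
is the half-crossover. `estimate_period()` removes the mean and linear
trend, applies a Hann window, zero-pads ×4 and takes the dominant
non-zero-frequency peak of the power spectrum, refined by parabolic
interpolation of log-power across the peak — standard choices to resolve
a ≈43 nm period on ≈1 µm traces, all configurable. A peak is reported
only when it exceeds 5× the median spectral power (`k_sig`; a pragmatic
significance default) and when the implied period is at most half the
trace length; otherwise the profile has "no period", which is what flat
or amplitude-zero profiles return. The estimator is scale-equivariant in
position and invariant to height scaling. `aggregate_periods()` reports
the sample mean and n−1 standard deviation over profiles with a period
and counts the rest.

## Synthetic data

Every pipeline input has a seeded generator, and each generator returns a
ground-truth manifest that the tests compare against — recovered values
are never compared to hard-coded constants.

* `synth_fap_genome()` plants *fapABCDEF* operons (one per contig) with
  configurable intergenic gaps — including gaps straddling the 5000 bp
  threshold for boundary tests — per-gene repeat counts, and decoy genes
  whose E-values fail the cutoff. It emits the exact domtblout dialect
  the parser reads (round-trip tested). Defaults mirror the dominant
  natural situation: 6-gene operons, two FapBC_repeat genes, 3 repeats
  per gene, ~39-residue repeats.
* `default_repeat_pfm()` is a synthetic 39-column PFM emulating repeat
  conservation structure: invariant glycines and Asn/Gln positions,
  highly conserved small residues, hydrophobic positions, even pairs,
  and unconserved positions. Unconserved columns are modelled as an even
  mix over a small tolerated residue set (4 residues) rather than
  uniform over all 20: homologous repeat positions tolerate a limited
  repertoire, and a 20-component near-uniform column could not be
  re-estimated to total-variation 0.05 from 1000 sequences by any
  method (the expected TV of the empirical distribution itself is
  ≈0.055).
* `synth_saxs_curve()` reuses the forward model with relative Gaussian
  noise and σ = noise_frac·I_model. The UK4-like preset used in the
  recovery tests gives the Gaussian-chain term ~1% of the forward
  intensity: UK4 is the minimal variant whose sequence is almost entirely
  part of the fibril core, and the coherent forward scattering of a
  fibril dwarfs that of individual disordered chains. With a strong
  polymer term (tens of percent) the minor axis becomes intrinsically
  ill-determined at the 1% noise level — a property of the information
  content, not of the fitter; `synth_helical_trace()` stacks a
  seeded planar pseudo-atom motif with `build_helical_assembly()`;
  `synth_height_profile()` adds a random-phase sinusoid (default 1 nm
  amplitude, the height-variation scale of twisted fibrils) and Gaussian
  noise to a baseline, rejecting configurations with dx ≥ period/4.

What passing on synthetic data does *not* show: robustness to real
annotation noise (overlapping genes, frameshifts, split contigs), to
alignment errors upstream of the PFM, to AFM tip convolution and
drift (profiles here are ideal 1-D traces), or to the instrument effects
in measured SAXS curves (smearing, buffer mismatch). Those belong to the
upstream tools the package deliberately does not replace.

## Problem sizes and determinism

The shipped test suite runs fits on 60–100-point curves, Debye sums on
100–1600 scatterers, genomes of up to 10 operons plus decoys, and
40-profile periodicity panels; these sizes exercise every code path while
keeping the suite quick. All stochastic tests fix seeds through
`withr::with_seed` or explicit generator seeds, and all generators are
pure functions of (config, seed).

## Known limitations

* The cylinder model's polymer term is additive; cross terms between
  cylinder and chains (present in more elaborate fibril models) are
  omitted, matching the two-component intensity expression above.
* The Kabsch RMSD takes an explicit atom pairing; it does not search
  correspondences.
* The hydration-layer bead construction is a simple geometric shell; it
  is adequate for the q-range of cross-section analysis but is not a
  substitute for dedicated explicit-solvent scattering calculators at
  wide angles.
* The consensus-motif thresholds are conventions, not fitted quantities;
  motif strings should be read qualitatively.

## A worked pipeline

```{r pipeline, eval = FALSE}
# mine a synthetic genome and census its repeats
g <- synth_fap_genome(list(n_operons = 10), seed = 1)
mined <- mine_fap_operons(g$domtblout_path, g$genes_path)
mined$census

# helical bookkeeping
p <- helical_params(4.8, -2)
crossover_distance(p)      # 864 Angstrom
half_period(p)             # 43.2 nm
compose_symmetry(p, 3)     # 14.4 Angstrom, -6 deg

# periodicity of 40 synthetic AFM traces
ests <- lapply(1:40, function(k)
  estimate_period(synth_height_profile(half_period(p), seed = k)))
aggregate_periods(ests)[c("mean_nm", "sd_nm")]

# SAXS: simulate a UK4-like cross-section and refit it
truth <- cylinder_params(R = 1.7, eps = 11.3 / 3.4, S_pol = 0.01)
q <- exp(seq(log(0.04), log(3), length.out = 100))
curve <- synth_saxs_curve(truth, 0.01, q, seed = 1)
fit <- fit_cylinder_model(curve, cylinder_params(R = 2.2, eps = 2.5,
                                                 S_pol = 0.02))
cross_section_report(fit$params)
```
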