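# fapkit

Computational characterization of Fap-type bacterial functional amyloids
in R.

Biofilm-forming *Pseudomonas* species build extracellular amyloid fibrils
from the secreted protein FapC (with its nucleator FapB), encoded in the
*fapABCDEF* operon. Each FapC monomer carries ~39-residue imperfect
repeats (IRs) that stack into cross-beta layers of a twisted fibril.
Characterizing such a system computationally spans several scales, and
fapkit implements the analysis layer for all of them:

* **Operon mining** — parse HMMER3 `domtblout` homology hits (E-value
  cutoff 1e-5), chain genes into clusters at < 5000 bp intergenic
  distance, keep clusters with FapBC_repeat homology plus ≥ 3 further
  Fap-HMM genes, designate *fapB*/*fapC* by synteny (first/second
  FapBC_repeat gene), and census repeats per gene (IR1, IR2, ...).
* **Repeat motifs** — position frequency matrices from aligned repeats,
  per-column information content `IC = log2(20) − H` bits, and compact
  consensus motifs (capital/lowercase = complete/high conservation, Ψ =
  hydrophobic, `(x/y)` = even pair, `*` = unconserved).
* **Helical geometry** — for a fibril with rise ρ and twist τ per
  subunit: crossover distance `ρ·360/|τ|`, surface half-twist period
  `crossover/2`, n-fold symmetry composition, helical assembly of atomic
  models, and Kabsch superposition RMSD.
* **SAXS modelling** — the two-component fibril intensity
  `I(q) = S_cyl·P_cyl(q; R, ε, L, σ) + S_pol·P_pol(q; R_g) + b`
  (elliptical-cylinder form factor with graded surface, Gaussian-chain
  term, background; L = 100 nm and σ = 0.5 nm fixed by default), weighted
  reduced-χ² fitting, Debye-equation scattering of atomic models with an
  explicit hydration layer, and closed-form scale/offset matching.
* **AFM periodicity** — FFT estimation (detrend, Hann window, 4× zero
  padding, parabolic peak refinement) of the height-modulation period of
  twisted fibrils, aggregated over fibrils as mean ± sd.
* **Synthetic data** — seeded generators for every input (planted
  operons with HMMER-dialect hit tables, repeat sets from a PFM, noisy
  model SAXS curves, helical pseudo-atom traces, sinusoidal height
  profiles), each returning a ground-truth manifest, so the entire
  pipeline is testable offline.

## Worked example

```r
library(fapkit)

## helical bookkeeping for a twisted fibril
p <- helical_params(4.8, -2)       # rise 4.8 A, twist -2 deg per layer
print(p)
#> helical symmetry: rise 4.800 Angstrom, twist -2.000 deg (left-handed)
#>   crossover 864.00 Angstrom (86.40 nm), half-period 43.20 nm
```

A fibril gaining 4.8 Å and −2° per subunit completes a full 360° turn
every 864 Å (86.4 nm); lying on a surface it shows a height modulation
every half turn, 43.2 nm.

```r
## mine a synthetic genome with 10 planted operons
g <- synth_fap_genome(list(n_operons = 10), seed = 1)
mined <- mine_fap_operons(g$domtblout_path, g$genes_path)
print(mined$census)
#> fap operon census over 10 operons
#> genes per cluster:
#> n_genes
#>  6
#> 10
#> repeats per fapC gene:
#> nC
#>  3
#> 10
```

All 10 planted 6-gene operons are recovered, each fapC gene with its 3
planted imperfect repeats.

```r
## AFM-style periodicity of 40 synthetic fibril height traces
ests <- lapply(1:40, function(k)
  estimate_period(synth_height_profile(half_period(p), seed = k)))
agg <- aggregate_periods(ests)
sprintf("periodicity: %.2f +/- %.2f nm over %d fibrils", agg$mean_nm, agg$sd_nm, agg$n)
#> "periodicity: 43.20 +/- 0.02 nm over 40 fibrils"

## SAXS: simulate a 3.4 x 11.3 nm cross-section and refit it at 1% noise
truth <- cylinder_params(R = 1.7, eps = 11.3 / 3.4, S_pol = 0.01)
q <- exp(seq(log(0.04), log(3), length.out = 100))
curve <- synth_saxs_curve(truth, 0.01, q, seed = 1)
fit <- fit_cylinder_model(curve, cylinder_params(R = 2.2, eps = 2.5, S_pol = 0.02))
print(fit)
#> cylinder-model fit: chi2_red = 0.7975 (100 points, 6 free)
#> cylinder model: cross-section 3.50 x 11.35 nm (R 1.752, eps 3.240), L 100 nm, grading 0.50 nm
#>   S_cyl 0.9987, S_pol 0.0108, Rg 2.063 nm, b -1.294e-05
```

The fitted full axes (3.50 × 11.35 nm) recover the generating
cross-section within a few percent at 1% noise, with a reduced χ² near 1.

A thin command-line front end over the same functions ships at
`system.file("cli", "fapkit.R", package = "fapkit")` with `helix`,
`mine`, `assemble`, `period` and `logo` subcommands.

The methods vignette (`vignettes/fapkit-methods.Rmd`) documents the
models, parameter conventions, numerical choices and limitations.

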