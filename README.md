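# nucarray

Quantitative analysis of nucleosome-array architecture from 3D nucleosome
pose models, and mesoscale Monte Carlo simulation of chromatin fibers with
irregular linker-length profiles.

Cryo-electron tomography of native chromatin yields, after density
fitting, one pose per nucleosome: a centroid, a fitted-plane normal, and a
chain index within its array. `nucarray` turns such pose models into the
field's standard descriptors and simulates the fibers they imply:

* **Stereology** — center-to-center distance to the next nucleosome in
  the chain (*D*), distance to the nearest nucleosome in 3D (*N*), the
  chain bend angle at each nucleosome (*α* ∈ [0°, 180°]), and the folded
  plane angles between consecutive (*β*) and spatially nearest (*para*)
  nucleosomes; boundary and missing-linker exclusion rules; stacked-
  nucleosome detection (*para* < 25°, *N* near 6.5 nm).
* **Linker calculus** — traced open-DNA lengths *O* (0.34 nm/bp),
  peel-corrected signed linker lengths *L* = *O* − *S* − *E* (negative
  *L* = partially overlapping cores), constrained core lengths
  *C* = 146 − *S* − *E*, per-array averages and nucleosome repeat length
  NRL = 146 + mean *L*.
* **Contact capture** — classification of nearest-neighbor contacts
  (*N* < 11 nm) into *i±k* and *trans* categories with a 28-nm
  trans-confirmation rule, and crosslinked-vs-control fold changes.
* **Mesoscale simulation** — a coarse-grained fiber model (8.8 bp/linker
  bead, rigid cores with surface pseudo-charges, flexible histone tails,
  linker histone, Debye–Hückel electrostatics, soft excluded volume)
  sampled by Metropolis Monte Carlo, with packing ratio (nucleosomes per
  11 nm), *i±k* interaction patterns, linker-stem indices (< 2.5 nm
  paired-bead criterion, both linkers > 26 bp), fan plots and
  tail-interaction fractions.
* **Synthetic data** — calibrated generators reproducing the immature
  (PN1) and mature (PN56) mouse-retina chromatin statistics (linker mean
  30.7/42.6 bp, 10.7%/3.2% negative linkers, mean *D* 20.0/22.3 nm, mean
  *C* 132.0 bp, ...), so the entire pipeline is testable offline.

## Worked example

```r
library(nucarray)

# a synthetic mature-retina scene: 60 arrays of 10-12 nucleosomes
sc  <- build_scene(linker_preset("PN56"), geometry_preset("PN56"),
                   n_arrays = 60, seed = 11)
rec <- apply_exclusions(compute_geometry(sc))$records
mean(rec$D, na.rm = TRUE)
#> [1] 21.84439

m <- linker_measurements(sc)
nrl_estimate(mean(m$L[m$resolved]))
#> [1] 186.6855

# immature profile for comparison: shorter linkers, more overlap
x <- sample_linker_lengths(linker_preset("PN1"), 1e5, seed = 42)
c(mean = mean(x), negative = 100 * mean(x < 0))
#>     mean negative
#> 30.64389 10.82300
```

The mean *D* of ~22 nm and the NRL of ~187 bp sit at the mature-stage
calibration targets (22.3 nm, 188.6 bp) to within this scene's sampling
error; the immature preset shows the shorter (30.7 bp) and frequently
negative (10.7%) linkers that distinguish unfolded immature chromatin.

Simulating the two fiber types (scaled-down example):

```r
tpl <- build_fiber_template(linker_preset("PN56"), 23, lh_per_nucleosome = 1,
                            seed = 203)
ens <- run_mc(tpl, set_conditions(energy_params(), NaCl_mM = 150),
              mc_settings(burnin_sweeps = 5500, n_frames = 50,
                          sweep_interval = 10), seed = 204203)
packing_ratio(ens)$mean          # nucleosomes per 11 nm of fiber axis
which.max(interaction_pattern(ens)$frequency)  # dominant i±k (2 = zigzag)
```

At 150 mM NaCl with one linker histone per nucleosome, the PN56 linker
profile folds into a two-start zigzag (dominant *i±2*, higher packing)
while the PN1 profile stays dominated by *i±1* neighbor contacts — the
orderings checked by the acceptance suite.

## Command line

```sh
inst/cli/nucarray synth --config run.yaml --out-dir out/
inst/cli/nucarray stereology --in out/PN56 --out-dir out/
```

Subcommands: `synth`, `stereology`, `linkers`, `contacts`, `simulate`,
`analyze-sim`; tables are TSV, summaries JSON, ensembles multi-model PDB.

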