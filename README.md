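# tomospat

Spatial and orientational statistics for subtomogram particle tables.

In-cell cryo-electron tomography, after template matching and subtomogram
averaging, reduces each tomogram to a particle table: one row per detected
macromolecule with its centre position, Euler orientation and
conformational class. `tomospat` analyses such tables the way chaperonin
(TRiC/CCT) duty-cycle studies do, asking where particles sit relative to
each other and to ribosomes, and how the population divides among
functional states:

- **Cluster tracing.** A cluster is ≥2 particles in one tomogram connected
  under a centre-to-centre distance rule. With a plain cut-off *t*
  (default 20 nm), membership is the single-linkage connected components
  of the graph with an edge wherever *d(i,j) ≤ t*; a threshold sweep
  re-traces at every grid value *t ∈ {15, …, 40}* nm with a closed window
  *d ∈ [t − 0.5, t + 0.5]*. Link spacings are summarised per cluster
  length (mean ± sample s.d. over links in 15–20 nm), and topology is
  labelled circular (the ring-closing link exists), linear (end-to-end
  distance ≥ 0.8 × summed links) or other.
- **Relative orientation.** For each cluster member with nearest
  in-cluster neighbour, the relative rotation
  *R<sub>rel</sub> = R(ref)<sup>−1</sup> R(nb)* (ZYZ Euler convention,
  *R = R<sub>z</sub>(φ) R<sub>y</sub>(θ) R<sub>z</sub>(ψ)*) is applied to
  the pole (0, 0, 1) and projected stereographically onto a northern
  (*z* > 0) or southern (*z* ≤ 0) disc. Uniformity of the pole directions
  — "no preferred neighbour interface" — is tested with a Monte-Carlo
  Rayleigh statistic, the resultant length of the mean pole vector.
- **Ribosome exit-tunnel side (ETS).** Each chaperonin pairs with its
  nearest ribosome (directed, within 100 nm), is transformed into that
  ribosome's exit-tunnel frame
  (*R(rib)<sup>−1</sup>(x − x<sub>tunnel</sub>)*), and is classified ETS
  vs non-ETS by the half-space through the ribosome centre facing the
  tunnel. Per-state ETS fractions carry seeded bootstrap CIs.
- **Duty-cycle accounting.** Per-class counts become percentages over all
  particles (open split by prefoldin occupancy, plus closed), with
  two-proportion comparisons between datasets.
- **Synthetic generator.** Seeded hard-core (15 nm) particle fields with
  injected clusters (link spacing Normal(17.35, 1.18) nm truncated to
  [15, 20]), uniform or concentrated orientations, and ribosome scenes
  with a tunable ETS placement bias — ground truth included, so every
  stage is testable without external data.

## Worked example

```r
library(tomospat)

report <- run_pipeline(run_config(preset = "untreated",
                                  n_tomograms = 60, seed = 1))
print(report)
#> pipeline report
#>   seed                     1
#>   n_particles              1239
#>   n_clusters               78
#>   frac_clustered           0.295352
#>   spacing_mean             17.3874
#>   spacing_sd               1.00948
#>   sweep_peak_threshold     18
#>   orientation_resultant    0.083757
#>   orientation_p            0.251748
#>   ets_fraction             0.556911
#>   ets_n_pairs              1230
#>   open_percent             46.2
#>   closed_percent           53.8
```

Reading the output: 29.5% of closed particles fall in clusters at the
20 nm cut-off (the scenario injected 30%); their link spacing is
17.39 ± 1.01 nm; the sweep peaks near the injected 17–18 nm spacing; the
orientation test does not reject uniformity (p = 0.25), as expected for
Haar-random orientations; 55.7% of chaperonins sit on the exit-tunnel
side of their nearest ribosome (the scenario's placement bias is 0.551);
and the state split of this draw is 46.2% open / 53.8% closed.

On real data, ingest tables instead of simulating:

```r
ps  <- read_particle_table("particles.star", dialect = "star",
                           pixel_size = 0.9504)   # voxels -> nm
cl  <- trace_clusters(ps, threshold = 20, state_filter = "closed")
cluster_summary(cl)
```

A thin command-line wrapper with subcommands `convert`, `simulate`,
`clusters`, `sweep`, `orientations`, `ribo-context`, `states` and `run`
lives at `inst/cli/tomospat.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the installed package's full pipeline on
the untreated scenario preset from scratch (simulation, cluster tracing,
sweep, orientation test, ETS enrichment, state accounting) under the
given seed and writes the machine-readable result set to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
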