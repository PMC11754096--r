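---
title: "Methods: spatial and orientational statistics for subtomogram particle tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial and orientational statistics for subtomogram particle tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomospat)
```

# The setting

Cryo-electron tomography of intact cells, followed by template matching
and subtomogram averaging, yields per-particle annotations: a tomogram
identifier, a 3D centre in the tomogram frame, an orientation as a ZYZ
Euler triplet, and a class label assigned by 3D classification. For the
chaperonin TRiC/CCT — two stacked 8-subunit rings cycling between an
open, substrate-accepting conformation and a closed, folding-active one —
such annotations support three spatial questions this package answers:
do closed particles cluster, do in-cluster neighbours adopt preferred
relative orientations, and are particles enriched on the exit-tunnel side
(ETS) of nearby ribosomes? A fourth, non-spatial question — how the
population splits among duty-cycle states — is plain count arithmetic.

All positions are handled in nanometres; voxel-unit tables are converted
exactly once, on ingest, with an explicit pixel size. Because only
pairwise distances and relative rotations enter any statistic, no pixel
origin convention is needed.

# Cluster tracing

A *cluster* is ≥2 particles of the filtered state (default: closed) in
one tomogram connected under a centre-to-centre distance rule; clusters
never span tomograms, since coordinates live in per-tomogram frames.

Two rules are exposed. The plain cut-off rule places an edge wherever
$d_{ij} \le t$ (default $t = 20$ nm) and takes single-linkage connected
components of size ≥2. The windowed rule, used by the threshold sweep,
requires $d_{ij} \in [t - w,\, t + w]$ with $w = 0.5$ nm, both ends
closed — for $t = 17$ the permissible distance runs from 16.5 to
17.5 nm, and a distance landing exactly on a boundary belongs to both
adjacent sweep bins. The sweep grid defaults to 15–40 nm: 15 nm is the
physical minimum centre-to-centre distance between two chaperonin
particles, set by their own diameter.

Connected components give an order-independent partition (the greedy
"trailing particle" chain description and the component view coincide at
the sparse densities involved, which the union-find equivalence tests
exercise directly); the greedy closest-unvisited chaining from the
lowest member id is kept as the *ordering* rule within a component, so
consecutive-link distances are well defined for spacing statistics.
Spacing summaries pool links inside [15, 20] nm, report mean ± sample
(n−1) standard deviation per cluster length, and flag single-link groups
with `n_links = 1` and `sd = 0` rather than emitting `NaN`.

Topology is labelled per cluster: *circular* when the two chain
endpoints satisfy the active link rule (the ring-closing link exists),
*linear* when the straightness ratio — end-to-end distance over summed
link lengths — is at least 0.8, *other* otherwise; pairs are linear by
convention. The 0.8 threshold is this package's own quantitative choice:
the source imagery shows circular and linear arrangements but states no
rule, and 0.8 cleanly separates a straight chain (ratio 1) from a
right-angle bend (ratio ≈ 0.7 at five members).

Filament proximity uses the any-member rule: a cluster is proximal to a
track (e.g. actin dimer centres) when any member lies within 20 nm of
any track point in the same tomogram. Whether published proximity
figures counted cluster-level or member-level distances was not fully
specified; any-member is the more inclusive reading and is documented
here once.

# Relative orientation and the hemisphere map

Orientations follow the RELION rot/tilt/psi composition, realised here
as intrinsic ZYZ acting on column vectors:
$R(\phi, \theta, \psi) = R_z(\phi) R_y(\theta) R_z(\psi)$. The source
tables never print the matrix; any consistent convention leaves the
statistics below invariant because only *relative* rotations and
hemisphere symmetry are reported. Matrix-to-Euler extraction is
canonical ($\theta \in [0, 180]$); at gimbal degeneracy
($\sin\theta \approx 0$) the decomposition is not unique, so $\psi = 0$
is imposed and a flag is set — a deterministic tie-break chosen for
testability.

For each cluster member, the relative rotation against its nearest
in-cluster neighbour is $R_\mathrm{rel} = R_\mathrm{ref}^{-1}
R_\mathrm{nb}$. The published phrasing ("multiplied by the inverse
rotations") is ambiguous about operand order; this order is fixed here
and is immaterial to the uniformity conclusion, since the inverse of a
Haar-uniform rotation is Haar-uniform. $R_\mathrm{rel}$ is applied to
the pole $(0,0,1)$ and projected stereographically: $z > 0$ to the
northern disc via $(x, y)/(1 + z)$, $z \le 0$ to the southern disc via
$(x, y)/(1 - z)$ — the equator belongs to the southern map, and the
north pole, i.e. zero relative rotation, maps to the disc centre. Each
member contributes one sample, so mutual pairs count once per direction;
a `dedup` flag collapses them. No symmetry reduction (the particle's
pseudo-D8) is applied, matching the published analysis as far as it is
stated.

*Uniformity test.* The published claim is qualitative ("random
orientation to its nearest neighbours"); no named test is given, so the
package constructs one: the Rayleigh-type resultant length
$\bar R = \lVert n^{-1} \sum_i \mathbf{p}_i \rVert \in [0, 1]$, with a
Monte-Carlo null of `n_boot` uniform-sphere samples of the same $n$ and
the add-one p-value $(1 + \#\{\bar R_0 \ge \bar R\})/(n_\mathrm{boot}+1)$,
deterministic given a seed. The resultant is invariant under any global
rotation of all frames. A resultant-based test has power against
unimodal concentration — the alternative a specific binding interface
would produce — but not against antipodally symmetric departures; that
limitation is accepted and documented, as the scientific alternative of
interest is unimodal. Hemisphere report plots bin the disc into
equal-area annular sectors (default ≈48 cells over 4 rings), reported as
densities per equal solid-angle cell, since the published figure's
normalisation is not stated.

# Ribosome exit-tunnel-side enrichment

Ribosomes outnumber chaperonins in cells, so pairing is directed: each
chaperonin takes its nearest ribosome within `pairing_max_dist`
(default 100 nm — the published cut-off is not printed; the default is
configurable and the per-distance-bin breakdown shows sensitivity).
Positions are expressed in the paired ribosome's exit-tunnel frame,
$R_\mathrm{rib}^{-1}(\mathbf{x} - \mathbf{x}_\mathrm{tunnel})$ with
$\mathbf{x}_\mathrm{tunnel} = \mathbf{x}_\mathrm{rib} + R_\mathrm{rib}
\mathbf{v}_\mathrm{offset}$: a rigid motion, hence an isometry. The
tunnel offset used in the original study came from a prior ribosome
average and is not printed; the default $(0, 0, -25)$ nm stands in for a
60S exit-tunnel position and is a required, overridable configuration
value — only its direction matters for the side call.

The ETS/non-ETS boundary is the plane through the ribosome centre
orthogonal to the centre-to-tunnel direction, with the plane itself
non-ETS; the published results report a binary split without defining
the surface, and a half-space is the minimal construction whose 50/50
null is exact for isotropic positions. Per-state ETS fractions carry
seeded percentile bootstrap CIs over chaperonin-pair resampling —
the chaperonin pair, not the ribosome, is the unit of analysis.

# Duty-cycle accounting

Percentages are computed over *all* particles in a tally (open classes
plus closed): the published arithmetic forces this base (875 of 7,407 ≈
12% for single-prefoldin particles, phrased as a fraction of all
chaperonin). The open/closed split is reported at one decimal, prefoldin
classes also as nearest integers, mirroring the printed precisions.
Dataset comparisons use pooled two-proportion z statistics with no
multiplicity correction by default (a handful of pre-registered states;
documented). `reference_counts()` ships the printed tallies so the
published percentages are reproducible by exact arithmetic.

# The synthetic generator: a stated world

`scenario_config()` defaults *are* the study's stated conditions:
per-tomogram box 800 × 800 × 150 nm (a lamella tomogram's analyzable
volume — absolute size only matters through density, which is anchored
to the printed totals of 4,054 closed / 3,353 open particles over 360
tomograms, and 3,418 / 3,785 over 352 treated); a 15 nm hard core;
injected clusters covering 30% (untreated) or 19% (treated) of closed
particles; link spacings Normal(17.35, 1.18) nm truncated to [15, 20] —
truncated because pair statistics were restricted to that interval and
15 nm is physical; a geometric cluster-length law over 2–7 with decay
0.45, matching the printed per-length profile (326, 218, 74, 35, 16, 4);
uniform orientations; and ETS placement bias 0.551.

Where the study is silent, one value was chosen and is not revisited:
topology mix 0.8 linear / 0.2 circular (both occur in the imagery,
chains dominating); ribosome density 55 per box (ribosomes "more
abundant" than the ~20 chaperonins); associated chaperonins placed
20–60 nm from their ribosome. Chains draw a fresh uniformly random
direction per link (turning angles unconstrained), reflecting the absence
of preferred inter-particle orientation; rings are regular polygons with
one drawn side length. A leftover singleton in a tomogram's clustered
quota is absorbed into the preceding cluster so the realised clustered
fraction tracks the configured one. In ribosome scenes, a placement is
rejected unless the host is the chaperonin's nearest ribosome; otherwise
directed pairing at analysis time would re-pair some chaperonins and
dilute the injected bias. The rejection is symmetric about the tunnel
direction (ribosome orientations are Haar-uniform), so it does not bias
the side draw.

What the generator does *not* emulate — and hence what a green test does
not establish: membranes, organelles and polysome geometry (excluded
volume is a uniform hard core only); localisation and angular
assignment error of real subtomogram averaging; missing-wedge anisotropy
in detection; false positives/negatives of template matching. Edge
effects are deliberately shared between generator and analyzer: points
may sit anywhere in the box and no boundary correction is applied on
either side, matching the published analysis practice, so near-boundary
density is biased identically in both.

# Numerical choices

- Rotation validation at 1e-6 (input) and guarantees at 1e-9 (output);
  round-trips tested to 1e-9.
- Closed intervals throughout the sweep; ties on the boundary belong to
  both neighbouring bins by construction.
- Seeded randomness is scoped: seeded functions save and restore the
  caller's RNG state, and the pipeline derives fixed per-stage child
  seeds from one global seed, so toggling a stage leaves other stages'
  draws unchanged.
- Monte-Carlo p-values use the add-one estimator, which is slightly
  conservative and never exactly zero.
- Degenerate inputs error loudly and specifically: empty tables on
  write, zero totals in percentages, <10 orientation samples, zero
  pairs in enrichment, packing failure at infeasible densities.

# Test-suite scaling

Stochastic calibration checks run at sizes chosen to finish within a
desk-scale budget while keeping their stated statistical power: the
uniformity size check uses 200 replicates of n = 100 with a 500-draw
null; coverage uses 100 scenes of ≈150 pairs with 200 bootstrap
replicates; bias recovery uses ≈3,000 pairs. Fixed seeds make every
stochastic assertion reproducible; tolerances are 3σ binomial bounds
derived from the stated parameters, not fitted to observed outcomes.

# Known limitations

- Single-linkage membership means one bridging particle can merge two
  visually distinct groups; at the study's densities this is rare (the
  CSR leakage measured by the `csr_null` preset quantifies it).
- The resultant-based uniformity test is blind to antipodally symmetric
  concentration.
- The ETS half-space is a coarse stand-in for the true tunnel-proximal
  surface; only relative enrichment between conditions is meaningful.
- STAR I/O covers the single-block RELION-3 particle dialect only; no
  Warp XML, Dynamo or EMAN metadata.
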