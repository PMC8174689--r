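# nucbreathe

Quantitative analysis of **nucleosome breathing** — the spontaneous
detachment and re-attachment of the DNA ends from the histone core — and of
its coupling to **histone tail configurations** in molecular dynamics
trajectories. The package is aimed at people analyzing atomistic or
coarse-grained nucleosome simulations (PDB topology + DCD or multi-model PDB
trajectories) who want the standard breathing observables and tail-DNA
interaction statistics as reusable, tested R functions rather than ad hoc
scripts.

## What it computes

Geometry, in a coordinate frame anchored on the dyad base pair (origin at
the dyad, X along the dyad axis, S the superhelical axis from the inner-gyre
plane fit, Y = unit(X × S), Z = X × Y):

* per-arm opening angles — **γ₁**, the signed angle between the arm vector's
  XZ-projection and Z (out-of-plane), and **γ₂**, between its XY-projection
  and Y (in-plane) — plus 2D γ-histograms with occupied area and mode;
* DNA **radius of gyration** R_g = sqrt(Σ wᵢ |rᵢ − r̄|² / Σ wᵢ);
* least-squares (Kabsch) **superposition** onto a reference over the
  histone-core heavy atoms.

Interactions, split by DNA gyre (outer gyres = terminal 40 bp of each end,
inner gyre = the rest):

* heavy-atom **contact counts** (pairs closer than 4.5 Å, strict);
* **inverse-power weighted mean distances**
  d₁,₂[n] = ((1/(N₁N₂)) Σᵢⱼ (1/‖dᵢⱼ‖)ⁿ)^(−1/n) with n = 10 (δ, mean-like)
  and n = 100 (δ_min, minimum-like), evaluated in a factored form that is
  stable at n = 100;
* per-tail configuration series (δ to the L-DNA and dyad segments, contacts
  to both gyres, tail R_g) and per-residue δ_min profiles for the
  epigenetically modifiable H3 tail residues (tip R2/K4 … anchor
  K36/K37/R40/R42).

Conformations:

* k-means clustering (k-means++ seeding, deterministic under a seed, labels
  ranked by size) of superposed DNA / H3 / H2A-without-N-tail coordinates;
* DNA-to-tail cluster **co-occupancy matrices** (rows are DNA clusters and
  sum to 100%), cluster positions in the (γ₁, γ₂) plane, per-cluster median
  δ_min heatmaps, and 5–95 percentile summaries.

A **synthetic nucleosome generator** builds an idealized 147 + 2×11 bp
nucleosome (DNA beads on a superhelix, straight linker arms, histone-core
bead ring, one bead per tail residue) and trajectories with prescribed
per-arm opening angles and per-frame tail modes (`bridge`,
`dyad_collapsed`, `detached`, `absent`), returning exact ground truth so
every estimator is testable without MD data.

## Worked example

A 120-frame scenario in which the H3/H2AC tails on the 3' side release their
gyre-bridging contacts at frame 55 and the 3' arm then opens in-plane by 35°
at frame 61:

```r
library(nucbreathe)

spec <- synthetic_spec(seed = 7)
sc <- breathing_scenario("coupled_opening", n_frames = 120, arm = "3p",
                         amplitude = 35, tail_detach_frame = 55,
                         dna_open_frame = 61)
gen <- make_breathing_trajectory(spec, sc$angles, sc$tails, seed = 7)
traj <- gen$trajectory; ann <- gen$annotation
ann
#> <nuc_annotation> profile synthetic: 169 bp (dyad 85), outer gyres 80 bp,
#>                  inner 89 bp, 10 tail segment(s)

obs <- breathing_series(traj, ann)
round(obs[c(1, 60, 61, 120), ], 2)
#>     frame time_ps gamma1_3p gamma2_3p gamma1_5p gamma2_5p    rg
#> 1       1       0     -0.46      0.27      0.38     -0.22 44.93
#> 60     60    1180      0.44     -0.26      0.12     -0.07 44.95
#> 61     61    1200    -44.83     35.00      1.40     -0.82 49.08
#> 120   120    2380    -44.70     34.73      0.07     -0.04 49.09
```

The 3' arm's γ₂ jumps to the prescribed 35° at frame 61 and the DNA R_g
rises from ~44.9 Å (closed) to ~49.1 Å (open); γ₁ moves too because the two
angles are projections of the same arm vector. The tail series shows the
release six frames earlier — contacts with both gyres drop to zero and the
mean distance to the L-DNA jumps from ~25 Å to >100 Å:

```r
tail_configuration_series(traj, ann, "H3_3p", stride = 5)[c(1, 12, 24), ]
#>    frame time_ps delta_ldna delta_dyad nc_inner nc_outer tail_rg
#> 1      1       0      24.97      68.13       10        9    6.43
#> 12    56    1100     109.65     126.15        0        0   39.03
#> 24   116    2300     105.27     130.46        0        0   39.00
```

Clustering the DNA and H3 coordinates (k = 2 for this two-regime scenario)
and cross-tabulating links the open DNA conformations to the released tail
cluster:

```r
dna_m <- kmeans_cluster(build_feature_matrix(traj, ann, "dna"), k = 2,
                        seed = 7, selection_tag = "dna")
h3_m  <- kmeans_cluster(build_feature_matrix(traj, ann, "h3"), k = 2,
                        seed = 7, selection_tag = "h3")
cross_tabulate(dna_m, h3_m)
#> <nuc_crosstab> row percentages (rows sum to 100):
#>    col
#> row   1   2
#>   1  10  90
#>   2 100   0

percentile_summary(obs$rg, label = "dna_rg")
#>    label     p_lo     p_hi
#> 1 dna_rg 44.92311 49.12974
```

Every frame of the open DNA cluster (row 2) lies in the released-tail
cluster, while the closed DNA cluster is 90% bridged — tail release precedes
and accompanies opening by construction, and the pipeline recovers it.

`run_analysis(config)` chains all stages (generate/load → observables →
tails → cluster → crosstab → report) into a directory of deterministic
CSV/JSON outputs plus a manifest; `exec/nucbreathe` exposes the same stages
as a command line (`nucbreathe run --config demo.yml --out out/`).

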