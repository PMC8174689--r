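---
title: "Quantifying nucleosome breathing and histone tail-DNA coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome breathing and histone tail-DNA coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbreathe)
```

## The problem

A nucleosome wraps about 147 bp of DNA in ~1.65 left-handed superhelical
turns around a histone octamer (two copies each of H3, H4, H2A, H2B), with
linker DNA (L-DNA) arms extending beyond the wrapped core. The DNA ends
spontaneously detach and re-attach — *nucleosome breathing* — and the
disordered histone tails, whose lysines and arginines carry the epigenetic
modifications that mark active and silent chromatin, modulate these motions
by bridging the DNA gyres. `nucbreathe` implements the geometric and
interaction observables used to quantify breathing in molecular dynamics
(MD) trajectories, the conformational clustering that links DNA opening to
tail configuration, and a synthetic nucleosome generator that provides exact
ground truth for every stage.

## The dyad frame and the opening angles

All breathing observables are expressed in a coordinate frame anchored on
the dyad (the central base pair):

* **origin**: centroid of the dyad base pair's C1' atoms;
* **X**: unit vector from the inner-gyre centroid to the origin (the dyad
  axis);
* **S**: normal of the best-fit plane through the inner-gyre base-pair
  centers — the superhelical axis. Its sign is fixed by the winding
  direction of the inner-gyre path, which is deterministic, continuous
  across frames, and invariant under rigid motions;
* **Y** = unit(X × S), **Z** = X × Y (right-handed, orthonormal).

The XY plane is then the nucleosome disc plane. For each arm, a vector *v*
is fitted through the arm's base-pair centers (total least squares; an
endpoint mode is available), oriented from the hinge side to the terminal
base pair. The opening angles are

* **γ₁** = signed angle between the XZ-projection of *v* and Z (out-of-plane
  opening; sign right-handed about +Y),
* **γ₂** = signed angle between the XY-projection of *v* and Y (in-plane
  opening; sign right-handed about +Z).

Both angles are functions of the same vector, so they are **coupled through
its X component**: a pair (γ₁, γ₂) cannot be prescribed independently. The
generator therefore records, besides the prescribed rotation angles, the
exact analytic (γ₁, γ₂) of the rotated arm; whenever one prescribed angle is
zero the other equals its γ exactly. Recovery tests compare estimates
against these analytic values. A projection with near-zero norm yields `NA`
rather than a fabricated angle.

Which *sign* of each angle moves an arm away from the histone core depends
on the arm and the geometry (as in real nucleosomes, where a γ₁ increase
opens one arm and closes the other). In the generator's geometry, positive
in-plane rotation of the 3' arm swings it outward and increases the DNA
radius of gyration; the coupled-opening scenario uses that direction.

## Regions of the nucleosome

Roles are assigned by `annotate_nucleosome()` from counts, not absolute
positions, so any construct length works:

| region | definition | default |
|---|---|---|
| outer gyres | terminal stretch at each DNA end | 40 bp each |
| inner gyre | all remaining base pairs | complement |
| L-DNA reference | terminal segment of each arm | 15 bp |
| dyad segment (per side) | dyad bp + `dyad_half_width` bp toward that arm | 5 bp |
| arm vector bp | base pairs the arm vector is fitted through | terminal 15 bp (generator: the straight linker bp) |

Base pairs are indexed 1..L along the sense strand 5'→3'; base pair *i*
pairs the *i*-th sense residue with the (L+1−i)-th antisense residue.
Histone tails come from species profiles (`human`, `drosophila`,
`tailless`, YAML under `extdata/profiles`): H3 1–45, H4 1–32, H2B 1–33,
H2A 1–18 plus a C-terminal tail. The published human H2A core exclusion
ends at residue 129 without stating where the C-tail begins; the default
profile uses 119–129 (mirroring the fly profile's 10-residue C-tail) and
the range is configurable.

## Contacts and inverse-power weighted distances

Contacts are heavy-atom pairs closer than 4.5 Å (strict `<`). Pair counting
was chosen over distinct-atom counting because it is exactly checkable
against an exhaustive oracle; a `unit = "atoms"` switch is provided.

Tail positions are summarized with the inverse-power weighted mean distance

d₁,₂[n] = ( (1/(N₁N₂)) Σᵢⱼ (1/‖dᵢⱼ‖)ⁿ )^(−1/n), n even,

with n = 10 (δ, mean-like) for tail–L-DNA and tail–dyad distances and
n = 100 (δ_min, minimum-like) for per-residue–gyre profiles. Evaluation
factors out the minimum distance so that (d_min/dᵢⱼ)ⁿ ∈ (0, 1]; naive
evaluation of (1/d)¹⁰⁰ would overflow. Exact bounds follow from the
factored form:

d_min ≤ d[n] ≤ d_min · (N₁N₂)^(1/n),

and d[n] is non-increasing in n. Note the upper envelope is *generically
nearly attained* for n = 100, because only pairs within ~0.1% of the
minimum contribute to the sum: for 20×20 atom groups d[100] can sit ~6%
above the true minimum. Claims that d[100] is "within 2%" of the minimum
hold unconditionally only when N₁N₂ ≤ 7; the tests therefore verify the 2%
agreement on small groups and the exact envelope elsewhere. For one
residue against a whole gyre δ_min is a smooth upper bound on the contact
distance, which is what makes it useful as a collective variable.

The default H3 residue groups for per-residue profiles are tip (R2, K4),
center-tip (R8, K9, K14), center-anchor (R26, K27) and anchor (K36, K37,
R40, R42); the synthetic H3 tail carries the real H3 sequence so these
labels resolve on generated structures.

## Conformational clustering and co-occupancy

Frames are superposed onto a reference over the histone-core heavy atoms,
then k-means (default k = 8, matching the analysis the package implements)
is run on flattened coordinates of three selections: DNA backbone of the
inner gyre plus the *opening* outer gyre (the quiet arm is excluded so it
does not dominate the variance), whole H3 chains, and H2A without its
N-tail ("H2AC"). k-means++ seeding with `n_init = 10` restarts under a
fixed seed and Lloyd iterations (cap 500) make runs deterministic; labels
are then ranked by size (ties keep the lower original label). Cluster
co-occupancy matrices give, per DNA cluster, the percentage of its frames
in each tail cluster (rows sum to 100). Summaries use linear-interpolation
percentiles at 5 and 95.

## The synthetic generator

`make_ideal_nucleosome()` lays DNA bead pairs on a superhelix (defaults:
radius 41.9 Å, pitch 25.9 Å, 1.65 turns — canonical nucleosome-like
dimensions chosen for the generator, not measured values) with straight
B-DNA-like linkers (3.3 Å rise), a histone-core bead ring, and one
pseudo-heavy bead per tail residue (unit mass). The closed linkers run in
the frame's YZ plane, so both opening angles are exactly zero by
construction. `make_breathing_trajectory()` rotates each linker +
outer-gyre arm rigidly about its hinge (the base pair at the inner edge of
the outer gyre, consistent with opening motions that carry the outer gyre
along) by prescribed per-frame angles, repositions tails by mode, and adds
Gaussian jitter (default σ = 0.3 Å, a deliberately conservative stand-in
for thermal coordinate noise at the bead scale).

Tail modes are geometric idealizations of the configurations the analysis
distinguishes:

* `bridge`: beads laid between an inner-gyre bead and the outer-gyre bead
  one superhelical turn away, within contact range of both gyres;
* `dyad_collapsed`: a compact blob on the same-side dyad segment, far from
  the L-DNA;
* `detached`: beads walked outward at least 10 Å from all DNA;
* `absent`: the tail is not built (the tail-less construct).

What the generator does *not* emulate: thermal DNA elasticity, sequence
effects, tail conformational entropy, solvent, or any energetics — motion
is prescribed, never simulated. Passing recovery tests therefore
demonstrates that the estimators are correct and noise-robust, not that
they have been validated against experimental nucleosome dynamics.

## Numerical choices and degenerate inputs

* Superposition is the SVD (Kabsch) solution with the reflection branch
  excluded; fewer than 3 atoms or collinear selections are rejected.
* Plane fits reject collinear base-pair centers; the frame's S sign uses
  the winding normal, avoiding per-frame sign flips near planarity.
* Rg is mass-weighted by default (`mass_weighted = FALSE` matches the
  generator's unit-mass beads; for beads both agree anyway).
* Histograms default to 2.5° bins with a 1-frame occupancy threshold; both
  are parameters since sensible values depend on sampling depth.
* Strides are per-observable (`angles` default 1, `contacts` default 5
  frames), mirroring workflows that evaluate geometry more often than
  interaction sums; with 20 ps frames the defaults correspond to 20 ps and
  100 ps cadences.
* One global seed fans out to fixed per-stage seeds, so any stage can be
  replayed in isolation with identical results.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on generated
data at desk scale, chosen to keep the whole suite in minutes while still
exercising every code path: 147 + 2×11 bp constructs, 50–300-frame
trajectories, two-regime clustering with k = 2 on scenario data and k = 3
on planted blobs, 100-configuration distance sweeps, and 50 random contact
fixtures of 100 + 100 atoms. The co-occupancy scenario couples tail
release (frame 141) to in-plane arm opening (frame 151) over 300 frames,
so the expected mechanism signature — the most-open DNA cluster co-occupying
the lowest-contact tail cluster, with tail release leading by 10 frames —
is known exactly.

## Known limitations

* The dyad-frame construction assumes an intact, roughly planar inner
  gyre; constructs unwrapped past the outer gyres would need a different
  reference.
* γ angles are undefined (returned `NA`) when an arm vector is parallel to
  the X axis.
* Cluster features use globally superposed coordinates (no per-pair
  refit), i.e. Euclidean distance after a single core fit; pairwise-RMSD
  medoid clustering is out of scope.
* The DCD writer/reader stores single-precision coordinates (~1e-4 Å).
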