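---
title: "Methods: loop-RMSD ensemble reduction and docking-model evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-RMSD ensemble reduction and docking-model evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrclust)
```

## Overview

`cdrclust` prepares docking-ready antibody ensembles from large sets of
generated heavy-chain models and evaluates the docking poses that come back.
This vignette documents the methods, the tunable parameters, the numerical
conventions, and the design decisions taken where more than one reasonable
convention exists. It states no empirical result beyond what the package's
own tests and `scripts/acceptance.R` compute.

## The loop-RMSD metric

All distances between antibody models are **framework-aligned loop backbone
RMSDs**. Given a region definition that partitions a chain (by author
residue numbering) into framework ranges and named CDR loops, the metric

1. pairs framework backbone atoms (N, CA, C, O) between the two structures
   by `(chain, residue number, insertion code, atom name)`,
2. computes the least-squares rigid superposition (Kabsch algorithm, SVD of
   the 3×3 covariance with reflection correction, so the rotation always
   has determinant +1),
3. applies that transform to the model's loop backbone atoms and reports
   their RMSD against the reference loop **without refitting on the loop**.

The no-refit choice is deliberate: a loop-local fit would hide a loop that
is internally correct but points the wrong way relative to the framework,
which is exactly the failure mode that matters for docking. The metric is
symmetric in its arguments and invariant under rigid transforms of either
structure (both properties are asserted in the test suite at 1e-6 Å).

**Backbone atom set.** The default is the 4-atom backbone {N, CA, C, O};
`atom_set = c("N","CA","C")` drops the carbonyl oxygen. Published loop
benchmarks use both conventions and rarely say which; the 4-atom set is the
more common in antibody loop work, so it is the default, and the choice is
a visible argument rather than a constant.

**Residue pairing.** Structures are paired by author numbering, never by
serial position, so region definitions survive numbering gaps. Within an
ensemble all members must share residue identities — this is validated at
construction. Any atom-set mismatch between two structures is a hard error:
silently skipping atoms would change the metric. Loop ranges must be fully
populated (a loop is a contiguous range by definition); framework ranges
select the residues present, and cross-structure comparison errors on any
disagreement. This permits legitimate author-numbering gaps inside
framework ranges while still refusing to compare structures with different
residue content.

**Degenerate inputs.** Superposition needs ≥ 3 point pairs (error below
that) and warns on collinear point sets, where the rotation about the line
is undetermined; the fit is still returned. `fit_rmsd` can never exceed the
unfitted RMSD.

## Agglomerative clustering and medoid centers

Ensembles are reduced by bottom-up hierarchical clustering of the pairwise
loop-RMSD matrix: start from singletons, repeatedly merge the two clusters
with the smallest inter-cluster distance, stop at *K* clusters.
Inter-cluster distance is the linkage: `single` (minimum pairwise member
distance), `complete` (maximum; the default), or `average` (unweighted mean,
UPGMA). The implementation maintains distances by Lance–Williams updates;
the test suite checks it against a deliberately naive reference that
recomputes every inter-cluster distance from the raw matrix at each step,
and against `stats::hclust`/`cutree` on tie-free random matrices.

Determinism required three conventions the underlying mathematics does not
fix:

* **Merge ties** (two candidate pairs at exactly equal distance) are broken
  by the smallest pair of cluster labels, a cluster's label being the
  smallest original member index it contains.
* **Cluster center = medoid by summed distance**: the member minimising the
  sum of distances to its cluster mates, ties to the member earliest in
  ensemble order. Alternatives (medoid by maximum distance, a constructed
  mean structure) exist; medoid-by-sum is the common choice and is
  computable from the distance matrix alone, with no averaging artefacts.
* **Cluster indices** are ordered by decreasing size, ties by smallest
  member label, so output ensembles are stable across runs.

`reduce_ensemble()` composes distance computation, clustering and medoid
extraction; its defaults (*K* = 20 on the first 100 members, complete
linkage, loop H3) are the pipeline's production operating point — a
five-fold reduction. The preset `"af2-baseline"` (25 models to 5 clusters)
covers the analogous reduction of a predictor's own 25-model output.

`sweep_reduction()` tabulates the best center-to-reference loop RMSD over a
grid of (ensemble size *n*, cluster count *k*, linkage), next to the
pre-clustering minimum over the first *n* members ("first *n*" means
ensemble order). Two exact facts hold and are tested: the best-center RMSD
can never beat the ensemble minimum, and at *k = n* the two coincide. The
best-center RMSD also *tends* to fall as *k* grows, but this is not a
theorem for medoid centers: splitting a cluster can move a medoid and raise
the value by an amount on the order of the intra-cluster spread. The test
suite therefore asserts the decreasing trend at the planted-separation
scale rather than exact monotonicity. Combinations with *k > n* are
dropped from the sweep table.

## Chain assembly and the backbone clash filter

`merge_chains()` concatenates one chain from each of two structures under
new chain ids (default H and L) without touching coordinates. The clash
filter then guards against generated H3 loops that collide with the light
chain:

* a **clash** is an unordered pair of backbone heavy atoms whose distance
  is *strictly below* `fraction × (r_a + r_b)`, with `fraction = 0.63` and
  element van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å (a standard
  set; the table is fully overridable because no single canonical source
  exists);
* pairs within one residue, and between sequence-adjacent residues of the
  same chain, are excluded so covalent geometry is never counted;
* in the assembly pipeline only inter-chain (H, L) pairs are tested,
  matching the failure mode the filter exists for;
* models with **more than one** clash are removed (`max_clashes = 1`), so
  a single marginal contact does not cost a conformation.

The strict inequality at the threshold and the keep-at-one boundary are
both asserted in tests, and every planted-clash fixture is recounted by an
independent all-pairs brute force. Clash counts are invariant under rigid
transforms and chain relabeling. An ensemble in which every member fails
the filter yields an empty result with a warning at the filter level, and
an explicit stage error in the `prepare` pipeline.

Energy minimization of the assembled models is deliberately out of scope:
the manifest records `minimization: "external"` and the output PDB is
written for the docking engine's own refinement module.

## pLDDT triage

Per-residue pLDDT is read from the B-factor column (CA atom's value, or the
residue mean if CA is absent); a loop's confidence is the unweighted mean
over its residues, and values outside [0, 100] trigger a warning since the
column then likely holds real B-factors. Models at or above the threshold
(default 80) are *confident*; strictly below is *difficult* — the boundary
value itself counts as confident, mirroring the "below 80" wording that
defines the difficult regime. Thresholds above 100 are allowed (everything
difficult). The companion split of targets by best loop RMSD uses a default
of 3.0 Å with the boundary in the *wrong* set (right means "< 3.0 Å").
`plddt_rmsd_correlation()` is the standard Pearson coefficient
(`stats::cor`) with explicit errors for fewer than 3 pairs or zero
variance; on real antibody data, loop pLDDT and loop RMSD are strongly
anti-correlated, which is the empirical justification for triage.

## CAPRI evaluation

* **fnat**: residue–residue contacts at a 5 Å heavy-atom cutoff (the CAPRI
  convention; a flag), fraction of reference contacts reproduced by the
  model. Undefined (error) when the reference has no contacts.
* **L-RMSD**: backbone RMSD over ligand chains after superposing on the
  receptor backbone, no refit.
* **i-RMSD**: interface residues are reference residues of either side with
  any heavy atom within 10 Å of the partner; superposition and RMSD are
  both over those residues' backbone atoms.
* **Quality classes**, evaluated in order high → medium → acceptable:
  high requires fnat ≥ 0.5 and (L-RMSD ≤ 1 or i-RMSD ≤ 1); medium
  fnat ≥ 0.3 and (L-RMSD ≤ 5 or i-RMSD ≤ 2); acceptable fnat ≥ 0.1 and
  (L-RMSD ≤ 10 or i-RMSD ≤ 4); otherwise incorrect.

The published form of the *incorrect* clause ("fnat < 0.1 or L-RMSD > 10
and i-RMSD > 2") contradicts the acceptable bound (i-RMSD ≤ 4) printed next
to it: a pose with fnat 0.2, L-RMSD 11, i-RMSD 3 satisfies the acceptable
rule yet also the literal incorrect clause. The default here
(`rule = "consistent"`) defines incorrect as the complement of acceptable,
which is self-consistent; `rule = "printed"` applies the literal clause
first for comparison. The discrepancy is surfaced, not silently corrected.

`success_rate()` reports the fraction of targets with a model at or above a
quality class within the top *N* ranked poses (incorrect < acceptable <
medium < high); it is non-decreasing in *N* and non-increasing in the
quality bar.

## The synthetic fixture generator

Tests and the acceptance script run entirely on generated structures: toy
poly-alanine backbones with ~3.8 Å CA–CA spacing and fixed local geometry,
a rigid framework identical across conformations, and a loop displaced by a
fixed shift per planted conformation plus seeded Gaussian noise. This
emulates precisely the features the pipeline consumes — framework rigidity,
loop conformational clusters, per-residue confidence in the B-factor
column, steric overlap, interface contacts — and nothing else. Planted
clashes and planted contacts are re-verified inside the generator by brute
force before a fixture is handed to a test, so a generator bug cannot
silently become a test input. Every generator is a pure function of its
spec and seed (byte-identical on repeat, caller's RNG state untouched).

What the fixtures do **not** emulate: real amino-acid geometry and side
chains, the statistics of generative samplers, real pLDDT calibration, or
crystallographic artefacts (altlocs, gaps, waters — the reader handles
them, but fixtures don't exercise them at scale). Passing tests therefore
demonstrate the correctness of the geometry, clustering, filtering and
scoring machinery — not the biological performance of ensemble docking,
which can only be established on real antibody–antigen data with external
prediction and docking tools.

Default fixture parameters: framework 20 residues, loop 8, inter-conformation
shift 6 Å, intra-conformation noise 0.1–0.3 Å (tests use shift/noise ratios
of 20–60, comfortably above the ratio ≥ 10 regime where planted-partition
recovery is expected), loop pLDDT 75 vs framework 92. Test problem sizes —
ensembles of 15–100 members, distance matrices up to N = 12 for oracle
equivalence, a ~5,000-point CAPRI score lattice, 20 random rigid
transforms — were chosen so the full suite exercises every code path while
completing in about a minute on a laptop core.

## Numerical conventions

* Symmetry of distance matrices validated at 1e-6; diagonals at 1e-9.
* Rotation determinant checked to 1e-6; rigid-copy fits recover RMSD ≤ 1e-9.
* PDB coordinates carry three decimals, so write→read round-trips are exact
  to 5e-4 Å and idempotent afterwards.
* Altlocs keep the highest-occupancy conformer (ties by altloc letter);
  hydrogens are dropped everywhere (predictions lack them; all metrics are
  heavy-atom).
* Contact cutoffs use ≤ (a residue pair exactly at 5 Å is a contact);
  the clash rule uses strict < (a pair exactly at the threshold is clean);
  triage uses ≥ for confident; the accuracy split uses < for right. Each
  boundary mirrors the wording that defines it and is pinned by a test.

## Known limitations

* No sequence-based CDR annotation or antibody numbering scheme: region
  definitions are caller-supplied ranges, by design.
* No structure repair, protonation, or missing-atom rebuilding; incomplete
  backbones are hard errors rather than silently patched inputs.
* The clustering is O(N²) in memory and O(N³) worst-case in time via the
  pairwise matrix; intended for N up to a few hundred models, which covers
  the 100-model operating point with large headroom.
* Medoid centers are one of several defensible "center" definitions; see
  the clustering section for the tie-break and ordering conventions that
  make the choice reproducible.
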