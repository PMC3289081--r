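---
title: "Sphere-based protein structure similarity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-based protein structure similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprot)
```

This vignette documents the models behind the package: the local aa-sphere
similarity, its empirical calibration, the global alignment and TM-score,
the approximate nearest-neighbour access method, and the synthetic data
generator the tests rely on. It also records the numerical conventions and
the design choices made where the method leaves room.

## The aa-sphere representation

A protein chain is reduced to its residues; each residue sits at its
α-carbon but carries all of its heavy atoms. The *aa-sphere* of residue `A`
is the set of residues with at least one heavy atom inside the closed
Euclidean ball of radius `r` (default **9 Å**) around `A`'s α-carbon.
Measuring membership over heavy atoms rather than α-carbons lets a residue
whose side chain reaches into the ball count as a neighbour even when its
backbone is far away. Membership is measured from the centre's α-carbon
only; whether the original method also tested the centre's side-chain atoms
is not recoverable, so this convention is fixed and documented here.

Sphere members split into four ordered categories. The *spherical backbone*
is the maximal sequence-contiguous run of members containing the centre,
divided into an upstream and a downstream part; all remaining members form
the upstream and downstream *neighbourhoods*. The four member counts
`(q_ub, q_db, q_un, q_dn)` are the sphere's *quantity characteristics*.
Sequence adjacency means consecutive internal indices: residues are densely
renumbered at parse time, so chain breaks in the author numbering are
invisible to the contiguity rule (the simplest convention consistent with
treating the file order as the sequence).

## Local similarity: SM-raw and SM-score

Two aa-spheres `x`, `y` are compared in five steps:

1. **Seed alignment.** The backbones are aligned gaplessly outward from the
   two centres, truncated to the shorter side in each direction. This
   alignment is unique.
2. **Superposition.** The Kabsch algorithm superposes the seed pairs
   (proper rotation only; reflections excluded).
3. **Neighbourhood alignment.** Under that superposition, global dynamic
   programming aligns the upstream neighbourhoods against each other, and
   likewise the downstream ones, with match score
   `s(i, j) = 1 / (1 + (d_ij / d_s)^2)` on post-superposition α-carbon
   distances and **zero gap cost**. Because the match scores are positive
   and bounded by 1, zero-cost gaps make this a maximum-weight
   order-preserving matching; the method itself specifies no gap penalty at
   this step.
4. **SM-raw.** The distance scores of all aligned pairs are summed and
   normalized by `max_norm = 1 + Σ_c min(q_c(x), q_c(y))`, the largest sum
   attainable for spheres with these quantity characteristics. SM-raw lies
   in (0, 1] and equals 1 for identical spheres.
5. **SM-score.** A raw value is meaningful only relative to what chance
   produces for spheres of that size, so SM-raw is passed through an
   empirical cumulative distribution (below) specific to the pair of
   downsampled quantity characteristics, then multiplied by a factor
   `f = Π_c (1 + min(q_c)) / (1 + max(q_c))` that penalizes count
   mismatches — without it, a sphere obtained by deleting members from
   another would score maximally.

The scale parameter `d_s` is a **constant 2 Å**: spheres are far smaller
than whole proteins, so a fixed scale in the tradition of the older
whole-protein scores (3.5 Å and 5 Å in the ancestors of the TM-score
family) is appropriate, shrunk to the sphere scale.

Two conventions here are package choices, flagged prominently because the
method's own algebra for them is not uniquely determined: the exact form of
the factor `f` (any form that is 1 on identical characteristics and
strictly decreasing in divergence would do; the product-of-ratios form is
isolated in `quantity_factor()` so it can be swapped), and the combination
of ECDF value and `f` (realized as their product).

## Calibration

`build_ecdf_table()` pools SM-raw values from cross-protein sphere
comparisons over a calibration set, keyed by the ordered pair of
*downsampled* quantity characteristics: neighbourhood counts are halved,
backbone counts 0 and 1 share a bin (both map to 1), and every component is
capped at 7. The order of operations — halve, merge, cap — is fixed here;
SM-raw is symmetric in its arguments, so each evaluated pair contributes
its value under both key orderings. The key is *not* symmetrized beyond
that: the measure downstream is asymmetric and no symmetrization is
assumed.

Evaluation is the plain right-continuous empirical fraction
`P(X ≤ v)` with no plotting-position correction; a value at or above the
bucket maximum yields 1, so identical spheres always reach SM-score 1.
Requests for unpopulated buckets fall back to the nearest populated bucket
by L1 distance on the eight components (ties to the lexicographically
smallest key). Buckets are capped (default 50 000 samples) by seeded
subsampling — the empirical distributions converge long before that — and
the build is deterministic given the seed. Tables serialize to a versioned
plain-text container with 17-significant-digit values so the round-trip is
bit-exact.

## Global alignment and TM-score

The global residue pairing of two structures maximizes the sum of
`log(SM-score)` match scores under a linear gap model with **gap penalty
log 0.75** per gap position: maximizing summed log-probabilities maximizes
the probability that the alignment is significant, and the penalty is low
enough that only genuinely similar sphere pairs get matched. SM-scores can
be exactly 0 (a bottom-ranked ECDF value), so scores are floored at `1e-8`
before the logarithm to keep the dynamic programming finite. Traceback is
deterministic: match, then gap-in-query, then gap-in-target.

The pairing is then scored by the TM-score heuristic: over all rigid
superpositions visited, the score `(1/L_T) Σ_i 1/(1 + (d_i/d_0(L_T))^2)`
is evaluated on **all** aligned pairs, where `L_T` is the *query* length
and `d_0(L) = 1.24 (L − 15)^{1/3} − 1.8`, clamped below at 0.5 Å (the
constants are the established external convention of the TM-score, not a
contribution of this method). The search seeds Kabsch superpositions on
contiguous windows of the pairing at lengths `L_A`, `L_A/2` and `L_A/4`
(minimum 4) and refines each by iterating keep-pairs-closer-than-a-cutoff /
re-superpose to a fixed point, for cutoffs `d_0, d_0+1, …, 8 Å`. The
published search schedule has many micro-variants; this one is fixed and
deterministic, and agreement with other implementations is expected only to
about the third decimal. The distance between structures is
`d(x, y) = 1 − TM-score(x, y)`; it is asymmetric because `L_T` is the
query's length, but both directions share one residue pairing
(`sprot_distance_pair()`), which is why the reverse direction is nearly
free — the alignment dominates the cost.

`tm_optimize()` iterates re-alignment and re-superposition: a zero-gap
global alignment with match score `1/(1 + (d_ij/d_0)^2)`, matches beyond
`3 d_0` forbidden (which implements the distance threshold without a tuned
gap parameter), then the TM-score search on the new pairing, repeated while
the score improves by more than `1e-6` (at most 20 rounds, best-so-far
returned, so the reported score is non-decreasing). This raises cover and
TM-score substantially at extra cost and is off by default.

## The access method

Searching a database with an expensive distance calls for a pivot index.
For each pivot `p` and object `o` both directed distances `d(p, o)` and
`d(o, p)` are precomputed, because the measure is not symmetric and the
lower bound needs both:

```
lb(q, o | p) = max( d(q, p) − d(o, p),  d(p, o) − d(p, q),  0 )
```

which reduces to the classical `|d(q, p) − d(p, o)|` when the distance is
symmetric. The search follows the approximate-and-eliminate scheme:
maintain lower-bound estimations `e(o)` (monotonically tightened as pivots
are processed), a running k-best result set `R`, and a candidate set `S`;
repeatedly process the unprocessed pivot (then object) with the smallest
estimation, and eliminate objects whose estimation exceeds the k-th best
distance `θ`.

The measure also violates the triangle inequality on a small fraction of
triplets, and a single overvalued bound corrupts an estimation — with 1000
pivots and a per-triplet violation rate of `10^-4`, an estimation is wrong
with probability `1 − (1 − 10^-4)^1000 ≈ 9.5%`. Three guards make the
search robust: objects are eliminated only when `e(o) > θ (1 + v/100)`
(*approximation error tolerance*, default `v = 2.5`); pivots are protected
from elimination during the first `⌈#pivots/2⌉` iterations (the published
fraction of the protection span is typographically lost in the source
text; one half is this package's documented default); and after `S`
empties, up to `r` eliminated objects with the smallest estimations are
re-examined, counted since the last change of `R` (*order error
tolerance*, default 128). Ties — the first pivot, equal estimations, equal
distances at rank k — always resolve to the smallest identifier, so
results are independent of internal execution order.

Because most distances crowd the upper end of [0, 1], elimination is
starved: `θ` sits in the crowded band and no bound can exceed it. A
*similarity-preserving modifier* — here the rational quadratic Bézier curve
through (0,0), (0.7, 0.15), (1,1) with weight `w` — expands the crowded
band at the expense of the sparse one. It is strictly increasing, so
orderings are preserved; it is applied consistently to stored and
query-time distances, and `θ` and `v` operate in modified space. `w = 0`
degenerates to the identity. The curve parameter is inverted by bisection
to below `1e-12`, well inside every tolerance used here.

## The synthetic generator

`make_backbone()` builds α-carbon traces from pseudo-bond internal
coordinates (bond length 3.8 ± 0.05 Å; helix geometry ≈ 1.5 Å rise and
≈ 100°/residue, strand extended, mixed = helix–turn–strand) and attaches
one pseudo side-chain centroid per residue, offset 1.5–2.5 Å from the CA,
so heavy-atom sphere membership genuinely differs from a CA-only test.
`make_family_dataset()` derives family members from a template by Gaussian
coordinate noise (σ, applied before a random rigid motion so it is
structural rather than positional noise; rotations uniform, translations in
a 50 Å box) and labels them hierarchically (families pairwise into
superfamilies, templates into folds).

What the generator emulates: labelled families with tunable within-family
geometric divergence, enough for membership, calibration, alignment and
retrieval mechanics to be exercised end to end. What it does not emulate:
real side chains and rotamers, Ramachandran-valid dihedrals, domain
architecture, or the length and fold diversity of curated structure
collections — so passing tests demonstrate the correctness of the
machinery, not headline retrieval numbers on real databases.

Two benchmark configurations are fixed package-wide:

* **Classification benchmark** — 3 families × 4 members, σ = 0.5 Å,
  lengths 25–40: leave-one-out 1-NN family classification is expected at
  ≥ 90 %. This checks the generator's separation contract, not any
  real-data accuracy.
* **Search database** — 5 families × 20 members, σ = 0.3 Å, one pivot per
  family, queried with `k = 10`, `v = 2.5`, `r = 16` and the identity
  modifier. The tighter σ is deliberate: an index-fidelity check needs a
  database with genuine cluster structure in which a query's ten true
  neighbours are its family and cluster diameters sit clearly below the
  separation between clusters (raw distances ≈ 0.2–0.4 within versus
  ≈ 0.9 between). In that regime the pivot bounds eliminate about half of
  the database at zero retrieval error. At σ = 0.5 with small families the
  k-th neighbour distance lands in the crowded cross-family band and no
  triangle bound can reach it — precisely the indexability starvation the
  modifier exists to fix — so an identity-modifier fidelity check would be
  vacuous there.

The calibration set used by the tests and the acceptance script is a
separate synthetic collection (4 families × 2 members, σ = 1.0 Å), kept
disjoint from the benchmark so scores are never calibrated on the
structures being compared.

## Numerical conventions, degenerate inputs, limitations

* Closed-ball membership (`≤ radius`): the boundary has measure zero but a
  deterministic rule is needed.
* Kabsch on coincident or single points returns the identity rotation with
  centroid-matching translation; reflections are always excluded.
* Alternate locations: highest occupancy wins, ties to file order; NMR
  ensembles: first model only; MSE and similar modified residues map to
  their parent amino acid; unknown types become `X` (the measure never
  reads residue identity, only geometry).
* All dynamic programming tie-breaks and all ranking ties are fixed
  (documented above), so every pipeline output is reproducible bit-for-bit
  given seeds.
* Problem sizes in the tests (chains of 25–40 residues, a 100-structure
  database, 200-point metric toys, 2°-rotation-grid and exhaustive
  alignment oracles at small n) were chosen so the whole suite documents
  the method at desk scale; they are generator settings, not method
  limits.
* Known limitations: no sequence-order-independent alignment, no multiple
  alignment, no mmCIF input, and no claim that synthetic-benchmark metrics
  transfer to curated structure collections.
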