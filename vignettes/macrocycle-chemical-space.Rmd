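---
title: "Mapping macrocycle chemical space with mcspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping macrocycle chemical space with mcspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcspace)
```

## The problem

Macrocycles — organic compounds with a ring of roughly twelve or more
heavy atoms — are an increasingly important chemotype for targets that
conventional small molecules cannot address. Classic druglikeness
descriptors (the Lipinski and Veber properties) were designed for small
molecules and are highly collinear on macrocycle collections, so they
discriminate poorly between macrocyclic chemotypes. `mcspace` implements
a descriptor set and analysis pipeline built around features specific to
this compound class: which atoms form the macrocycle ring, which are
single-heavy-atom *peripheral* groups appended to it (methyl, hydroxyl,
carbonyl oxygen, halogen), and which belong to *substituents* (attached
groups of two or more heavy atoms, including fused and spiro rings); how
substituents are distributed around the ring (gap sizes); and how rigid
the ring is (double bonds, amide bonds, ring fusions).

## The decomposition model

Every heavy atom is assigned to exactly one positional class: ring,
peripheral, or substituent. The macrocycle ring itself is chosen by a
two-stage policy:

1. Compute a minimum cycle basis of the molecule's ring system. If the
   largest basis ring qualifies (>= `min_ring_size`, default 11), it is
   the macrocycle ring. This keeps a benzo-fused 12-ring a 12-ring: the
   16-atom envelope cycle around the fused pair is a sum of smaller
   rings, not a ring a chemist would name.
2. Otherwise, simple cycles are enumerated (under a configurable node
   budget) and the largest cycle that does not fully contain a basis
   ring is taken. This recovers bridged (ansa-type) macrocycles, whose
   large ring never appears in a minimal basis.

Ties among equal-sized rings are broken deterministically (smallest
lexicographic atom tuple). The original method's tie-breaking is
unknown; any fixed deterministic rule is equally defensible, and this
one is reproducible across platforms.

Peri-fused systems — two or more rings fused to the macrocycle ring and
to each other — are *multi-fusion* exceptions: no decomposition into
independent substituents is well defined. They are detected two ways
(a biconnected-block analysis of each substituent's attachment subgraph,
and a cycle-basis test), and either merged into a single fused
substituent (`policy = "merge"`) or routed to an exceptions output
(`policy = "exception"`). The basis test also flags transannular
bridges; such structures are genuinely ambiguous for gap and fusion
counting, and excluding them mirrors how the reference method handled
its own exceptions.

## Gap sizes

A *gap* is the number of ring atoms between the attachment points of a
pair of adjacent substituents, walking the ring once. Conventions chosen
where the source material is silent:

* attachment points are ring atoms bonded to substituents only;
  peripheral groups do not delimit gaps (an optional mode includes them,
  used by the ring-complexity descriptor);
* adjacent attachment points contribute a gap of zero, so
  `sum(gaps) + n_attachment == N` always holds;
* one attachment point gives the single gap `N - 1`; none gives
  max = min = mean = `N` with zero spread (an undecorated ring is
  maximally sparse);
* the spread statistic is the population standard deviation.

## The 90 descriptors

The registry holds 90 descriptors: 32 classic (MW, clogP, tPSA, H-bond
donors/acceptors, rotatable bonds, Fsp3, ...), 12 embodying earlier
macrocycle design guidelines (class sizes and peripheral composition
ratios), and 46 macrocycle-specific ones (per-class elemental
composition, gap statistics raw and ring-size-normalized, rigidity
measures, spiro/fused ring counts). Only 2-D structure is used; no
conformational analysis is attempted. Number of rotatable bonds
excludes all ring sigma bonds — macrocycle ring bonds are never counted
— while substituent rotatables are.

Numerical conventions worth knowing:

* ratio descriptors with an empty denominator (e.g. peripheral O /
  peripheral heavy atoms on a ring with no peripheral groups) evaluate
  to 0 and are flagged as exceptions, so a constant column cannot poison
  the PCA while the event remains visible;
* the peptide character index is `min(1, 3 * ring amide bonds / N)`:
  a pure cyclic peptide backbone (one amide per residue, three ring
  atoms per residue) scores exactly 1, an amide-free macrolide 0. The
  formula is this package's reconstruction — the source names the
  descriptor but not its form — and is configurable in spirit: the raw
  amide count is also exported;
* ring complexity is the fraction of ring atoms bearing any peripheral
  group or substituent, treating the two as equivalent;
* clogP uses a reduced Crippen-type atomic contribution scheme and tPSA
  an Ertl-type fragment sum; tPSA agrees with standard implementations
  on the tested panel, clogP tracks them to within a few tenths of a
  log unit. Absolute agreement with any commercial calculator is
  explicitly not a goal;
* chiral centers count assigned stereocenters plus potential ones
  (sp3 carbons whose neighbors receive pairwise-distinct Morgan
  extended-connectivity ranks) — a first-order CIP surrogate.

## Scaling, PCA and the space metrics

Descriptors are scaled to a common 0-100 frame before PCA. Discrete
properties (everything except MW, tPSA, clogP) scale as
`100 * x / p_max` with `p_max` the training maximum; the three
continuous properties scale as `100 * (x - p_min) / (4 * sigma)` with
`p_min = mu - 2 * sigma`, so the training mean maps to 50, `mu + 2
sigma` to exactly 100, and values outside the window pass through
unclipped (> 100 or < 0). Training parameters are stored and reused for
projecting new designs, never refit.

PCA is plain SVD of the column-centered scaled matrix, no Z-scoring (the
scaling already equalizes ranges), with loading signs fixed by making
each column's largest-magnitude coefficient positive. Set diversity is
an axis-aligned hyperellipsoid over the leading 10 PCs whose per-axis
range spans the middle 95% of compound scores (linear-interpolation
quantiles; coverage 1.0 for the all-compound "universe"):
`V = pi^5/120 * prod(R_i) / 2^10` for d = 10, with the 10th root
reported as an average radius. Distances between set centroids (and
from a compound to a set centroid) are Euclidean over the same PCs,
normalized by the universe's PC1 semi-axis; because the source is
ambiguous about whether its normalizer is a radius or a full range,
both modes are exposed (`normalize = "semi_axis"` default, `"range"`
alternative, exactly a factor 2 apart).

Descriptor importance is `I_p = V_p * sum_i c_pi^2` over the first 10
PCs, with `V_p` the population variance of the scaled column (dividing
by n, following the source). Redundancy pruning clusters the top 20 on
`|r| >= 0.8` (connected components) and keeps each cluster's most
important member; 0.8 is this package's choice — the source states no
threshold — and is a parameter. The number of survivors is
data-dependent and deliberately not forced to 13.

## The druglikeness filter

The packaged reference ranges are the 13 key properties with the value
windows that encompass 80% of oral macrocycle drugs (spiro rings
exactly 0; peripheral O fraction 0.30-0.67; tPSA 50-230; clogP
2.40-6.00; substituent Fsp3 0.22-1.00; min/max/st.dev gap per ring atom
0-0.13 / 0.24-0.64 / 0.06-0.26; (PeriphN+1)/(PeriphO+1) 0.13-0.50;
peptide character 0-0.44; restricted fraction 0-0.42; chiral centers
per heavy atom 0.02-0.33; ring heteroatom fraction 0.06-0.31). Range
bounds are inclusive (a value on the boundary complies). A compound
with at most 4 of 13 values out of range is classified "within" oral
macrocycle druglike property space. Deriving fresh ranges from your own
reference set uses the distribution-modality rules: middle 80% for
normal (A) and multimodal (C) distributions, an 80% span anchored at
the biased extreme for asymmetric unimodal (B) ones. Modality is a user
annotation, as in the source (classified by eye there); no automatic
classifier is silently applied. The filter is a property-space
surrogate for proximity to oral macrocycle drugs — it does not predict
oral bioavailability.

## The synthetic generator: what a green test establishes

There is no packaged compound collection: the drug sets and commercial
libraries the method was developed on are proprietary. Instead,
`generate_macrocycle()` builds molecules from explicit construction
plans whose ground truth (atom classes, gaps, rigidity, composition) is
known *by construction*, independent of the decomposition code — so
decomposition and descriptor tests compare two genuinely independent
routes. `generate_library()` wraps this with profiles:

* **oral-like** samples its features inside the 13 packaged ranges:
  rings of 12-18 atoms with 1-3 ether/amide heteroatoms, two or three
  mostly-sp3 chain substituents placed with one tight gap and the rest
  spread, and peripheral decoration dominated by oxygen (hydroxyl,
  carbonyl) with some methyls. These choices are the stated world of
  the profile, fixed before any acceptance measurement;
* **sparse** is the structural opposite (bare carbocycles, one sp2
  substituent, occasional spiro rings and polyene rigidity);
* **kinase-like** gives small rings with fused aromatics;
* **random** mixes the three.

Generated libraries are plain organic matter with legal valences, but
they are *not* realistic natural products: no stereochemical
annotation, no sulfur, limited functional-group variety, and substituent
chains rather than decorated sugars. A green decomposition oracle
establishes that the implementation agrees with construction-time
ground truth on this vocabulary — not that it handles every natural
product; multi-fusion systems are deliberately excluded from the
generator and tested through the exception path instead.

## Degenerate inputs and numerical choices

* Quantiles are always R type 7 (linear interpolation), stated wherever
  a percentile matters.
* Zero-variance descriptor columns: flagged `constant` by the scaling
  (discrete columns with `p_max = 0` scale to 0), receive zero
  importance, and are dropped (with a message) before k-medoids
  Z-scoring.
* An axis with zero score spread gives a zero hyperellipsoid volume, by
  design.
* Cycle enumeration carries a node budget; exceeding it raises a typed
  condition and the compound is routed to the exceptions report rather
  than stalling a batch.
* k-medoids is PAM with BUILD initialization and steepest-descent
  swaps; the swap trace is exposed and asserted non-increasing. The
  seed only breaks exact ties, so results are reproducible.

## Known limitations

* The SMILES/SDF support covers the organic subset this pipeline
  analyses (B, C, N, O, P, S, halogens; aromatic lowercase; charges;
  ring closures; V2000). It is not a general-purpose chemistry toolkit:
  no kekulization, no aromaticity perception beyond input flags, no
  stereo-aware canonicalization.
* clogP is an approximation; workflows needing publication-grade logP
  should recompute that single column externally and feed it in via the
  descriptor matrix.
* MolD identifiers outside the ones fixed by the reference material are
  this package's own block assignment; the registry documents each
  formula so external numbering can be mapped.
* The ring-selection policy can prefer a large basis ring over a larger
  bridged cycle when a bridge splits the macrocycle into two rings that
  are themselves above the threshold; such structures are rare and land
  in the exceptions stream via the multi-fusion detectors.
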