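# mcspace

Macrocycle-specific molecular descriptors and chemical-space analysis in R.

## What it is for

Macrocycles (compounds with a ring of ≥ 11–12 heavy atoms) sit outside the
territory that classic druglikeness descriptors were built for: on macrocycle
collections the Lipinski/Veber properties are so collinear that two principal
components capture nearly all of their variance, and they say nothing about
the features peculiar to this chemotype — how the ring is decorated, how
substituents are distributed around it, how rigid it is. `mcspace` is for
chemists and cheminformaticians who want to

* compute a 90-descriptor profile of macrocyclic structures from 2-D
  structure alone (SMILES or SDF input),
* map compound collections into a PCA chemical space and quantify each set's
  diversity (10-D hyperellipsoid volume and average radius) and its proximity
  to a reference region (normalized centroid distances),
* score individual designs against 13 key property ranges characteristic of
  oral macrocycle drugs (≤ 4 violations ⇒ "within" oral-macrocycle-druglike
  property space),
* select k representative compounds per collection (PAM k-medoids, k = 42 by
  default, on Z-scored descriptors).

## The model in brief

Each molecule's heavy atoms are partitioned into the **macrocycle ring**
(largest qualifying ring under a deterministic two-stage selection policy),
**peripheral atoms** (single heavy atoms appended to the ring: methyl C,
hydroxyl/carbonyl O, halogen) and **substituents** (attached groups of ≥ 2
atoms, including fused and spiro rings). From this decomposition come gap
statistics (ring atoms between adjacent substituent attachment points,
`Σ gaps + #attachments = N`), the restricted fraction (ring bonds rigidified
by a π bond, an amide bond, or a ring fusion), per-class elemental
composition, and ring-size-normalized variants — alongside the classic MW,
clogP, tPSA, HBD/HBA, rotatable bonds (macrocycle ring σ-bonds never count)
and Fsp3.

Descriptors are scaled to a 0–100 frame — discrete ones as `100·x/p_max`,
the continuous trio (MW, tPSA, clogP) as `100·(x − p_min)/(4σ)` with
`p_min = μ − 2σ` — then analysed by SVD PCA without Z-scoring. Set volume is
`V = π^5/120 · Π R_i / 2^10` over the middle-95% score ranges of PCs 1–10;
distances are Euclidean over the same PCs divided by the PC1 semi-axis of
the all-compound "universe" ellipsoid. Descriptor importance is
`I_p = V_p · Σ_i c_pi²` (population variance × squared loadings over 10 PCs),
pruned for redundancy at |r| ≥ 0.8.

## Worked example

```r
library(mcspace)

# one 14-atom macrolactam with an ester, two methyls and a hydroxymethyl arm
mol <- parse_smiles("CC1CC(C)C(=O)NC(CO)CCCOC(=O)C1", id = "example")
dv  <- compute_descriptor_vector(mol)
v   <- dv$values
sprintf("N=%d  RingHet/N=%.2f  restricted=%.2f  tPSA=%.1f  clogP=%.2f",
        v[["mold_37"]], v[["mold_22"]], v[["mold_82"]], v[["mold_8"]], v[["mold_6"]])
#> "N=12  RingHet/N=0.17  restricted=0.08  tPSA=75.6  clogP=1.12"

cv <- count_violations(dv)          # against the packaged 13 key ranges
as.integer(cv); classify_violations(as.integer(cv))
#> 4
#> "within"
attr(cv, "violated")
#> "StdevGapSize_over_N" "MinGapSize_over_N" "CLogP" "MaxGapSize_over_N"
```

The compound's single substituent leaves most of the ring bare, so all three
gap-distribution descriptors violate their oral-drug ranges and the low
clogP adds a fourth — landing exactly on the ≤ 4 boundary, still "within".

A full multi-set study on synthetic libraries (no external data needed):

```r
sets <- list(oral   = generate_library(42, "oral-like",   seed = 11)$mols,
             sparse = generate_library(42, "sparse",      seed = 12)$mols,
             kinase = generate_library(42, "kinase-like", seed = 13)$mols)
study <- run_study(sets, reference = "oral")
study
#> <mc_study: 126 compounds in 3 sets, reference 'oral'>
#>     set      raw normalized       volume avg_radius
#>  kinase 369.5237   1.275585 1.272020e+17   51.33924
#>    oral   0.0000   0.000000 2.265978e+19   86.20363
#>  sparse 437.7846   1.511219 7.870688e+16   48.93294

tapply(study$violations$violations, study$violations$set, median)
#> kinase   oral sparse
#>      6      1      9
```

Median violation counts separate the oral-like library (1, "within") from
the sparse one (9, "outside"); raw distances are in PC-score units,
normalized ones in units of the universe's PC1 semi-axis.

## Command line

`inst/scripts/mcspace-cli.R` wraps the pipeline:

```sh
Rscript inst/scripts/mcspace-cli.R simulate --n 200 --profile oral-like --seed 7 \
        --out lib.smi --truth truth.csv
Rscript inst/scripts/mcspace-cli.R descriptors --in lib.smi --out mold.csv
Rscript inst/scripts/mcspace-cli.R violations --in mold.csv --out violations.csv
Rscript inst/scripts/mcspace-cli.R select --in mold.csv --out medoids.csv --k 42 --seed 17
```

## Scope notes

2-D descriptors only — no conformational analysis. clogP is a Crippen-type
approximation, tPSA an Ertl-type fragment sum; neither aims to reproduce any
commercial calculator bit-exactly. The druglikeness filter is a
property-space surrogate for proximity to oral macrocycle drugs, not an
oral-bioavailability predictor. See the methods vignette
(`vignettes/macrocycle-chemical-space.Rmd`) for conventions, parameters and
limitations.
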