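Package: mcspace
Title: Macrocycle-Specific Molecular Descriptors and Chemical-Space Analysis
Version: 0.1.0
Authors@R:
    person("MCSpace", "Developers", email = "mcspace@example.org",
           role = c("aut", "cre"))
Description: Computes a set of 90 two-dimensional molecular descriptors
    tailored to macrocyclic compounds, including ring/peripheral/substituent
    atom decomposition, substituent gap-size statistics, ring rigidity, and
    classic druglikeness properties. Provides the downstream chemical-space
    pipeline: 0-100 descriptor scaling, principal component analysis by SVD,
    hyperellipsoid volume and average-radius diversity metrics, normalized
    centroid distances, descriptor importance ranking with redundancy pruning,
    an oral-macrocycle-druglikeness filter based on 13 key property ranges,
    PAM k-medoids representative selection, and a synthetic macrocycle
    generator with construction-time ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
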