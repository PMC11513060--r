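Package: TemperatureIndices
Title: Temperature-Based Topological Indices for Molecular Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes temperature-based topological indices of simple
    connected molecular graphs, where the temperature of a vertex b in an
    n-vertex graph is d_b/(n - d_b). Provides the thirteen named temperature
    indices (first and second hyper, sum- and product-connectivity,
    reciprocal and reduced reciprocal product-connectivity,
    arithmetic-geometric and geometric-arithmetic, forgotten, temperature
    Sombor and modified temperature Sombor, harmonic, and atom-bond
    connectivity temperature indices) together with the three parametric
    families that generalise them. Includes an explicit constructor for
    carbon nanocone graphs CNC_k[n] with their temperature edge partition
    and closed-form index evaluation, closed forms for benzenoid systems
    from vertex, hexagon and inlet counts, a bundled dataset of 30 lower
    benzenoid hydrocarbons with total pi-electron energies, and a
    grid-search optimiser for the exponent of the general F-temperature
    index that maximises its Pearson correlation with pi-electron energy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite, withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
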