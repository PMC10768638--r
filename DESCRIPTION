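Package: gbsgraph
Title: Gaussian Boson Sampling Simulation for Weighted-Clique Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, exact classical simulation of Gaussian boson sampling
    (GBS) applied to graph problems. Vertex-weighted graphs are encoded into
    squeezing parameters and an interferometer unitary through weighted-Laplacian
    rescaling and Takagi-Autonne decomposition; collision-free photon detection
    patterns are sampled from the exact hafnian-based distribution and
    postprocessed (greedy shrinking plus local search) into maximum weighted
    cliques. Two drug-discovery front-ends are included: binding interaction
    graphs built from protein/ligand pharmacophore points for molecular docking,
    and weighted full stem graphs for RNA secondary-structure prediction scored
    by the Matthews correlation coefficient. Synthetic fixture generators
    (planted-clique graphs, Haar-random unitaries, rigid pharmacophore
    complexes, designed RNA sequences) make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    igraph,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
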