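Package: morphofold
Title: Folding Analysis of Epithelial Surface Meshes by Unfolding Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciphering how the folding pattern of a closed
    epithelial surface encodes its inflated three-dimensional shape, as in
    the horn primordium of rhinoceros beetles. Provides triangle-mesh input
    and output (OBJ, PLY, STL, OFF), plain and HC-modified Laplacian
    smoothing with region masks and boundary feathering, a pressure-driven
    unfolding simulator based on steepest-descent minimization of a
    membrane energy, vertex-traced correspondence between folded and
    unfolded states, furrow visualization and region-specific furrow
    removal analyses, morphometrics for the three transformation modes
    (elongation, angular change, branching), and seeded parametric
    generators of folded test surfaces (accordion-pleated cylinders,
    furrowed disks, Yoshimura-folded tubes, furrow-biased tube bases,
    branched cap models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
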