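Package: optcycle
Title: Minimal Cycle Representatives for Persistent Homology via Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes one-dimensional persistent homology of Vietoris-Rips
    filtrations with exact rational coefficients via the R = DV boundary-matrix
    reduction, and shrinks the resulting cycle representatives by solving
    linear and mixed-integer programs: uniform- and length-weighted edge-loss
    minimization over persistent and filtered cycle bases, and uniform- and
    area-weighted triangle-loss (volume-optimal) minimization. Includes
    generators for synthetic point-cloud and Erdos-Renyi dissimilarity
    corpora, loss functions (edge count, length, triangle count, Heron area,
    Surveyor's area), and descriptive statistics over optimized corpora:
    coefficient profiles, loop counts, size-reduction ratios, LP/MIP
    agreement, and duplicate-interval detection.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    yaml
SystemRequirements: Python (>= 3.8) with numpy and scipy, used as the
    linear-programming backend through a local worker process.
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
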