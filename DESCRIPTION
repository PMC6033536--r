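Package: uorfsim
Title: Stochastic Simulation of Scanning and Elongating Ribosome
    Interference at Upstream Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time two-species exclusion-process (TASEP) simulator
    of ribosome traffic on an mRNA 5' leader containing a single upstream
    open reading frame (uORF). Scanning preinitiation complexes and
    elongating ribosomes move as extended particles on a codon lattice;
    scanning ribosomes may initiate at the uORF start, elongating ribosomes
    may terminate or reinitiate at its stop, and collisions with elongating
    ribosomes can dissociate scanning ribosomes. The package provides
    parameter sweeps over the ribosome loading rate with response-curve
    summaries (maxima, non-monotonicity detection, threshold scans), an
    exact stationary-flux oracle for small single-site-footprint instances
    by full Markov-chain enumeration, and ribosome-profiling summary
    statistics (translation efficiency, pause score, expression-binned
    Z-scores of translation-efficiency fold changes) with a synthetic
    cohort generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
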