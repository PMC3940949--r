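Package: curvenap
Title: A-Tract Periodicity, Intrinsic DNA Bend Prediction, and Nucleoid-Associated Protein Comparative Statistics
Version: 0.1.0
Authors@R: person("curvenap", "maintainers", email = "curvenap@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA curvature-related A-tract periodicity in
    bacterial chromosomes (spacing histograms, noise-filtered Fourier power
    spectra, and the band-restricted MaxQ* index), predicting intrinsic DNA
    bends with an A-tract wedge model, scanning genomes with position-specific
    score matrices at calibrated cutoffs, correlating windowed bend and
    binding-site profiles, and comparing MaxQ* across genome groups defined by
    nucleoid-associated protein and CRISPR presence (Mann-Whitney U and Fisher
    exact tests). Includes a synthetic-genome generator with planted periodic
    A-tract arrays, motif sites, and simulated genome-attribute tables for
    fully self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
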