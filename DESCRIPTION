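Package: scatCMR
Title: Non-Invasive Genetic Capture-Mark-Recapture from Scat Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end workflow for estimating abundance of elusive
    mammals from faecal (scat) DNA. Covers power analysis for SNP panel
    design (probability of identity for unrelated individuals and
    siblings, locus filtering cascades), quality control of replicated
    scat genotypes (amplification rates, consensus calling, allelic
    dropout and false-allele estimation), identification of individuals
    by hierarchical clustering on allelic mismatches, per-session
    population-genetic summaries (diversity, Ritland relatedness,
    linkage-disequilibrium effective population size), and spatially
    explicit capture-recapture with count detectors (full likelihood,
    half-normal / hazard-rate / negative-exponential detection, habitat
    and session density models, AICc ranking, delta-method abundance).
    A synthetic-data generator emulating a transect-based scat survey in
    a fenced reserve provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
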