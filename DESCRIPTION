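Package: magtrack
Title: Donor Microbiota Engraftment Tracking from Metagenome-Assembled
    Genome Read Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies donor microbiota engraftment after microbiota
    transplant therapy (MTT/FMT) from shotgun metagenomic reads. Post-treatment
    reads are classified against reference databases assembled de novo from
    the donor and the patient's pre-treatment sample, binned into uniquely
    donor-aligned, uniquely pre-treatment-aligned, ambiguous and unmapped
    reads, and ambiguous reads are reallocated with a Bayesian posterior built
    from empirical self- and cross-alignment rates. Reports engrafted,
    persistent and novel community proportions, per-scaffold engrafted read
    mass, and includes a seeded read-mixture simulator for validating the
    estimator (mixture series, contamination spike-ins, depth downsampling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    Rsamtools,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
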