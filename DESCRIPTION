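Package: pathprobe
Title: Pathway Metabolite Screening and Annotation from Untargeted LC-HRMS/MS
Version: 0.1.0
Authors@R:
    person("pathprobe", "developers", email = "pathprobe@example.org",
           role = c("aut", "cre"))
Description: Screens and annotates secondary-metabolite pathway products in
    untargeted liquid chromatography high-resolution tandem mass spectrometry
    (LC-HRMS/MS) data. Detects the "modified metabolome" by matching neutral
    losses in MS/MS spectra against a registry of 61 phenylpropanoid
    modification reactions, builds molecular networks between experimental
    spectra and probe-molecule reference spectra using the modified cosine or
    spectral entropy similarity, filters pathway clusters by probe co-occurrence
    or pathway-specific modifications, and annotates cluster members by network
    propagation from seed nodes and by de-novo fragment substructure assembly.
    Includes a synthetic-data generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
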