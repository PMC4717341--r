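Package: divload
Title: Mitochondrial Diversity and Infrapopulation Size in Host-Symbiont Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-level mitochondrial (COI) diversity analysis for
    host-symbiont systems such as feather mites on passerine birds.
    Computes nucleotide diversity, Tajima's D and the Ramos-Onsins-Rozas
    R2 expansion test with a fixed-S neutral coalescent null, builds
    minimum-spanning haplotype networks, and estimates the relationship
    between species genetic diversity and median infrapopulation size
    (mites per host individual) by a one-mite-per-host resampling
    procedure with weighted Gaussian GLMs, intraclass-correlation
    repeatability diagnostics and robustness checks. Includes a
    coalescent-based generator of synthetic vertically transmitted
    infrapopulation datasets so the whole pipeline is testable without
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
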