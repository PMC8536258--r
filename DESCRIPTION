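Package: clonecensus
Title: Precursor Censuses from Ovarian Clone-Marking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the number and type of dividing somatic precursor cells in
    the developing Drosophila ovary from clone-marking (mosaic labeling)
    experiments scored in adult ovarioles. Implements a binomial model linking
    per-cell labeling probability to the expected fraction of single-cell
    lineages, a one-vs-two-lineage mixture deconvolution that converts observed
    clone-category frequencies (EC-only, EC/FSC, FSC-only, FC-only, EC+FC) into
    single-lineage type frequencies, disaggregation of per-ovariole marked-cell
    yields into per-lineage yields, and a precursor census normalized to 16
    adult follicle stem cells per germarium. A stochastic clone simulator with
    known ground truth supports validation of the whole pipeline by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
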