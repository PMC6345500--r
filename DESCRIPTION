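Package: braingrid
Title: Brain-Grid Radiological Classification of Cerebral Gliomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Brain-Grid radiological classification system for
    cerebral gliomas: a fixed 48-cell partition of the brain defined by eight
    anatomical landmark planes in standard stereotaxic (MNI or Talairach)
    space. Provides point-to-cell labeling, NIfTI labelmap export, tumor
    segmentation mask classification (infiltrated cells, per-cell volumes,
    plane distances, laterality), a white-matter tract to grid-cell
    association table for "structures at risk" queries, longitudinal
    comparison of serial studies with white-matter spread-route proposals,
    cohort summaries with per-cell infiltration frequency maps, and a
    synthetic lesion generator (bulky and diffuse phenotypes, nested growth
    series) for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
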