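Package: hybridscope
Title: Enumeration and Phenotyping of Circulating Neoplastic-Immune Hybrid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A liquid-biopsy image-analysis pipeline for circulating
    neoplastic-immune hybrid cells (CHCs, CK+/CD45+) and circulating tumor
    cells (CTCs, CK+/CD45-) in peripheral blood mononuclear cell (PBMC)
    preparations. Provides a synthetic immunofluorescence field and cohort
    generator with planted ground truth, DAPI-seeded nuclear segmentation with
    membrane-guided cell expansion, control-region percentile gating with
    enumeration normalized per 50,000 PBMCs, longitudinal response/resistance
    course classification, an exact Mann-Whitney U test for small cohorts, and
    a beta-variational autoencoder (with per-batch KL-weight annealing) for
    morphology embeddings, UMAP projection, and responsive-versus-resistant
    phenotype reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    cluster,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
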