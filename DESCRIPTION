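Package: myeloparc
Title: Surface-Based T1w/T2w Myelin Mapping and Gradient Parcellation for
    Comparative Primate Neuroanatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cortical myeloarchitecture from paired white/pial
    surface meshes and T1w/T2w MR volumes: mid-thickness construction,
    vertex-wise surface areas and wedge volumes, Gaussian ribbon sampling of
    the T1w/T2w ratio onto the surface, template-referenced low-frequency
    bias correction, on-mesh gradient-ridge parcellation with seeded growth,
    per-parcel areal metrics in native space, and interspecies two-way ANOVA
    with Bonferroni-corrected post hoc tests. Includes a synthetic cortical
    phantom generator (folded white/pial pairs, myelin islands with known
    area fractions, rasterized T1w/T2w volumes with multiplicative bias and
    additive noise) so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    car,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
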