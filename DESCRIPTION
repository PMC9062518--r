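Package: divnn
Title: Neural-Network Estimation of Alpha, Beta, and Gamma Plant Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates and maps alpha, beta, and gamma vascular-plant
    diversity from vegetation-plot species inventories using small fully
    connected neural networks. Derives diversity labels from plot data
    (focal-plot richness, multiple-site Sorensen dissimilarity over the N
    nearest neighbouring plots, and neighbourhood species richness), builds
    per-site feature tables from climatic and anthropogenic rasters and
    occurrence-based sampling-effort counts in an equal-area projection,
    trains ensembles of regression networks with mean-absolute-error loss
    and softplus outputs, and produces gridded diversity predictions with
    coefficient-of-variation uncertainty. Includes a synthetic-landscape
    generator with a known diversity-environment relationship so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
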