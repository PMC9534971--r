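Package: wellmosaic
Title: Quantification of Endothelial Coverage, Smooth-Muscle Layering and
    Orbital Shear in Whole-Well Coculture Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the image-based readouts of vessel-on-a-dish
    endothelial/smooth-muscle-cell (EC/SMC) coculture models grown in
    circular wells on an orbital shaker. Provides a synthetic multi-channel
    well-mosaic generator with full ground truth (region label maps, nucleus
    tables), texture-based classification of the endothelial channel into
    confluent islands, cord-like networks and bare gaps, radial well zoning
    into center and periphery, region-coupled statistics (coverage
    fractions, ki-67 proliferation index by region, island-normalized
    cell-tracker intensity as an SMC layering index, radial intensity
    profiles with fibronectin-to-SMC ratios), flow-alignment order
    parameters, one-way ANOVA with Tukey post hoc comparisons, and a
    closed-form orbital-shaker wall-shear-stress estimate. All
    quantifications return tibbles and chain with the pipe; ggplot2
    figures mirror the standard whole-well layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
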