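Package: miscsoc
Title: Soil Organic Carbon Accounting for Grassland-to-Miscanthus Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying soil organic carbon (SOC) change after
    land-use conversion from temperate grassland to the perennial C4
    bioenergy crop Miscanthus. Computes core-based SOC stocks by the
    fixed-depth and cubic-spline equivalent-soil-mass (ESM) methods,
    partitions SOC into crop-derived (C4) and pre-existing (C3) carbon
    with the delta-13C natural-abundance two-pool mixing model, simulates
    monthly soil carbon turnover with a five-pool (DPM/RPM/BIO/HUM/IOM)
    RothC-lineage model under grassland and land-use-change scenarios, and
    converts SOC and nitrous-oxide costs into global-warming-potential
    intensities per unit of feedstock energy. Includes a synthetic
    field-trial generator with exported ground truth so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
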