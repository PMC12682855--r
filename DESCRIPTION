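Package: pindicator
Title: Phosphorus Efficiency Metrics and a Composite P Indicator for Root Phenotyping Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the five phosphorus (P) efficiency metrics used in wheat
    phenotyping trials (P acquisition efficiency, P utilization efficiency by the
    balance method, root acquisition efficiency, agronomic P use efficiency and
    P relative efficiency), aggregates them into genotype-level metric tables,
    builds a composite 0-5 "P indicator" by min-max normalization, classifies
    genotypes into efficiency/responsiveness quadrants, and quantifies agreement
    between phenotyping platforms via Pearson correlation, Lin's concordance
    correlation coefficient and Bland-Altman limits of agreement. Includes an
    image-analysis chain for rhizotron root photographs (panorama stitching,
    SVD low-rank denoising, Laplacian-of-Gaussian segmentation, top-connected
    cleaning, projected-area extraction, B-spline growth curves) and synthetic
    generators for factorial harvest trials, paired-platform genotype
    efficiencies, longitudinal root-area series and rendered root scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    car,
    splines,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
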