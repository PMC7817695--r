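Package: oajoint
Title: Rapid-Throughput Mouse Knee-Joint Phenotyping and Osteoarthritis
    Gene Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for quantitative osteoarthritis phenotyping of the
    mouse knee and for calling abnormal joint phenotypes in mutant lines.
    Quantifies articular-cartilage surface damage from joint-surface-replica
    images by edge detection and circularity-filtered particle analysis,
    calibrates subchondral microradiographs against plastic and steel
    standards to report relative bone mineral content, segments cartilage
    and subchondral bone in contrast-enhanced density volumes within
    automatically scaled volumes of interest and computes the standard
    morphometric parameters (Cg.V, Cg.Th, BV/TV, Tb.Th, Tb.N, TMD), and
    screens mutant-line phenotype tables against wild-type reference data
    using reference ranges, Wilcoxon tests with an effective-number-of-tests
    Bonferroni correction, and robust minimum-volume-ellipsoid Mahalanobis
    outlier detection. Includes OARSI histology score arithmetic, precision
    and repeatability metrics, power calculations, a 21-point gene
    prioritization score, and seeded synthetic-data generators with known
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
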