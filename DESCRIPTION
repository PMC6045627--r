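Package: airwaymorph
Title: Automated Lung Histomorphometry of Small Airways, Peribronchial
    Collagen and Emphysema
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automatic morphometric analysis of calibrated 2-D lung
    histology images. Detects small bronchioles on H&E sections, delineates
    the external (basal membrane) and internal (luminal) epithelium limits,
    and computes a six-parameter morphometric panel (bronchiole, lumen and
    epithelium areas, epithelium thickness from hundreds of radial measures,
    circularity of epithelium and lumen, Feret diameter). Quantifies
    peribronchial collagen on picrosirius-red sections as the percentage of
    chromogen-positive area relative to epithelium plus chromogen area, and
    quantifies emphysema by enumerating parenchymal airspaces (density, Feret
    diameter and count per square millimetre of parenchymal tissue) after
    automatic removal of bronchi and vessels. Ships a synthetic histology
    phantom generator with exact geometric ground truth so that every stage
    of the pipeline is testable without slide data, plus per-animal
    aggregation and group-comparison statistics (one-way ANOVA with
    Bonferroni-adjusted pairwise tests, or Kruskal-Wallis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    tiff,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Visualization
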