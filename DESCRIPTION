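Package: fishheart
Title: Quantitative Cardiac Phenotyping for Adult Zebrafish
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative cardiac phenotyping of adult zebrafish:
    biplane area-length volumetry, ejection fraction, fractional shortening,
    radial strain and velocity-strain loop analysis from paced ex vivo
    beating-heart videos; Doppler diastolic indices (E/A ratio, myocardial
    performance index); single-myofibril force-transient kinetics (activation
    and force-redevelopment rates, biphasic relaxation, force-pCa Hill
    analysis, rundown quality control); image-based morphometry (ventricle
    surface area to body weight, tissue area fractions, positive-nuclei
    percentages, cell areas); and cohort statistics (critical swimming speed,
    Kaplan-Meier survival with log-rank testing, group comparisons). A
    synthetic-data module generates every input with known ground truth so
    each stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    signal,
    pracma,
    minpack.lm,
    survival,
    jsonlite,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
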