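Package: doublecrop
Title: Mapping Winter Wheat-Summer Maize Rotations from Dual-Sensor NDVI Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping double-cropping rotations (winter wheat followed
    by summer maize) from 16-day-composite vegetation-index satellite imagery.
    Assembles interleaved dual-sensor NDVI time series on an 8-day merged
    cadence, replaces cloud- and snow-contaminated observations by linear
    interpolation between high-quality neighbours, smooths each pixel's annual
    curve with Harmonic Analysis of Time Series (HANTS, iterative Fourier
    least squares with one-sided outlier suppression), classifies the smoothed
    phenology curves into five land-cover classes with a random forest, and
    derives multi-year products: confusion-matrix accuracy with kappa, area
    consistency indices against statistical tables, area and growth-rate
    series, epoch change maps, planting-frequency rasters and peak-NDVI
    metrics. Includes a synthetic scene generator emulating MODIS-like
    bimodal crop phenology with quality flags, so the full pipeline runs and
    is tested without any satellite download.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    randomForest,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
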