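Package: grasscasa
Title: Grassland Net Primary Productivity with a Modified CASA Model and
    Pixel-Scale Climate Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates monthly, seasonal and annual net primary productivity
    (NPP) of semi-arid grassland from red/near-infrared surface reflectance,
    station meteorology and a land-cover map, using a modified
    Carnegie-Ames-Stanford Approach (CASA) light-use-efficiency model
    (NPP = APAR x epsilon, with FPAR estimated from NDVI and the simple
    ratio, and temperature and moisture stress scalars). Provides
    inverse-distance-weighted interpolation of station records to rasters,
    Angstrom-Prescott conversion of sunshine duration to solar radiation,
    plot-level validation statistics (slope, intercept, R2, F, RMSE, bias),
    and pixel-wise correlation and first-order partial-correlation
    attribution of NPP to precipitation and temperature, annually and by
    season. Includes a self-consistent synthetic-world generator with known
    ground-truth couplings so the full pipeline is testable without any
    satellite or station downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
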