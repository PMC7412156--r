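Package: thermoseries
Title: Dynamic Infrared Thermography Time-Series Features for Breast Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a dynamic infrared thermography (DIT) screening
    pipeline for breast exams. From a 20-frame sequence of radiometric
    temperature arrays per breast, it quantizes frames to a shared gray
    scale, extracts region-of-interest temperature and texture features
    (simple statistics, k-means grouping, histogram distances, Unser
    sum/difference texture estimators, ecological diversity indices,
    spatiogram similarity, gliding-box lacunarity), decimates the resulting
    feature trajectories into Higuchi sub-series, summarises each sub-series
    by its range and root mean square, selects features by correlation-based
    feature selection with best-first search, and classifies breasts as
    healthy or sick with a radial-basis-function support vector machine
    under leave-one-out cross-validation. A synthetic exam generator
    emulating post-cooling thermal recovery makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
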