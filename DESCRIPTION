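Package: phonadapt
Title: Phonetic Complexity of Infant Vocalizations and Parental Vowel
    Hyperarticulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the link between parents' articulatory
    adaptation in infant-directed speech and the phonetic complexity of
    their infants' vocalizations. Implements the Word Complexity Measure
    for Swedish (WCM-SE) over IPA-like transcriptions of infant
    vocalizations, vowel space area (VSA) estimation from point-vowel
    formant data in Hz or Bark with fundamental-frequency screening and
    mid-vowel windowing, register comparison (infant- vs adult-directed
    speech) and regression of infant complexity on the VSA difference,
    plus a calibrated synthetic-data generator so the whole pipeline can
    be exercised and validated without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
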