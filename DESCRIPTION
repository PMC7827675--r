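Package: safascore
Title: Multicriteria Sustainability Assessment of Cattle Farms with a
    SAFA-Style Indicator Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multicriteria sustainability assessment of cattle
    farming systems using a hierarchical indicator framework in the style
    of the FAO Sustainability Assessment of Food and Agriculture (SAFA)
    guidelines. Provides a bundled framework of four dimensions, 21 themes,
    58 subthemes and 116 indicators rated on a five-level percent scale;
    adapters that convert Welfare Quality principle scores, wildlife
    capture tables (Shannon-Wiener diversity, endemic species counts,
    key-species weighting) and reference-normalised soil chemistry into
    indicator scores; mean-based aggregation to subtheme and theme ratings
    with data-quality annotation; a positive/negative theme-valuation and
    farm-ranking procedure with cohort-relative rating bands; SVG
    sustainability polygons and report export; and a seeded synthetic-data
    generator for Native Silvopastoral, Intensive Silvopastoral and
    Monoculture farm archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
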