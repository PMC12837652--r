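Package: fertunit
Title: Fertilization-Unit Dosing and Gamete Management Planning for Aquatic Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates the fertilization unit -- the quantity of sperm, as a
    fresh volume or a whole number of cryopreservation containers, needed to
    reliably fertilize the eggs produced by one female -- for aquatic species
    such as blue catfish, zebrafish, and eastern oysters. Back-calculates
    hatchery production requirements (eggs, sperm volume, container counts,
    minimum broodstock numbers) from a target offspring count and species
    husbandry metrics, and quantifies how overuse or underuse of sperm
    relative to the unit degrades cost-normalized fertilization efficiency.
    Ships validated species parameter profiles, YAML/JSON/CSV profile
    serialization, report rendering, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
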