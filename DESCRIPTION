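Package: phenotree
Title: Integrated Species-Phenon Trees Against Geologic Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and draws time-calibrated evolutionary-tree charts for
    paleontological datasets in which two loosely coupled trees describe the
    same organisms: a tree of species lineages and a tree of phena
    (morphotaxa). Species time ranges are expanded into rectangular boxes,
    phenon ranges are algorithmically broken at species origins and
    transferred along ancestral chains of species boxes, and the result is
    rendered as a standalone SVG range chart with guide symbols marking true
    range ends versus artificial breaks. Includes a tab-delimited datapack
    reader/writer, a species-phenon relationship map exporter, deterministic
    example and randomized fixture generators, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
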