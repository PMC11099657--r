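Package: aneukin
Title: Reciprocal Aneuploidy Analysis and Morphokinetics of Mouse Oocyte Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shallow whole-genome-sequencing copy-number analysis of matched mouse
    egg and first-polar-body pairs, reverse-translated from clinical preimplantation
    genetic testing for aneuploidy (PGT-A). Binned read counts are called against a
    euploid male normal panel over fixed 10 Mb windows, integer chromatid copy
    numbers are designated jointly for each egg/polar-body pair under the meiosis-I
    conservation constraint (egg + polar body = 4 chromatids), and errors are
    classified as non-disjunction (NDJ) or premature separation of sister chromatids
    (PSSC) with severity grouping and shallow-NGS karyotype nomenclature. A
    ground-truthed synthetic-data generator emulates dose-dependent chromosome
    mis-segregation, overdispersed bin counts, and ploidy-class-conditional
    morphokinetics of meiotic maturation (tGVBD, tPB1, dMI), with the group
    statistics used for time-lapse analyses (Shapiro-Wilk gated ANOVA/Tukey or
    Kruskal-Wallis/Dunn, Grubbs outlier screening, categorical tests).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
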