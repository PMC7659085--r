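Package: ohnorhythm
Title: Diurnal Rhythm Detection and Duplicate-Gene Divergence in Organ
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cyclic (diurnal) gene expression across
    organ RNA-seq time courses and for asking how gene duplicates retained
    from the teleost genome duplication diverged in their expression
    rhythms. Provides counts-per-million normalisation with replicate
    averaging and an expressed-gene filter; a nonparametric umbrella rank
    test (summed Mann-Whitney U statistics over a rising and a falling
    slope) with exact or permutation p-values; identification of ohnolog
    pairs (2:1 to a non-duplicated outgroup) and singletons (1:1) from
    Biomart-style homology tables, with a synteny co-linearity score;
    classification of cyclic duplicate pairs into intra- and inter-organ
    functional-divergence categories; NanoString nCounter normalisation;
    and a seeded negative-binomial simulator of cosine-rhythmic count
    matrices and homology tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
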