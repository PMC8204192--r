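Package: opalscan
Title: Discovery of UGA-to-Trp Recoded Endosymbiont Genomes in Metagenome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Screens assembled metagenome contigs for stop-codon
    reassignment by comparing open-reading-frame coding density under the
    standard bacterial genetic code (translation table 11) and the
    UGA-to-tryptophan code (table 4), excludes organelle-like contigs via
    marker-gene hits, detects assembly circularity from exact terminal
    overlaps, characterizes candidate reduced genomes (coding density,
    gene overlap, intergenic lengths, proteome isoelectric points), and
    attributes a eukaryotic host by SparCC-style compositional
    correlation of length-weighted bin abundances across samples.  Ships
    a synthetic-community generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
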