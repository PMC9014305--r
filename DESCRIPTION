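Package: circsrna
Title: Circular RNA Detection and C/D Box sRNA Analysis from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circular-RNA back-splice junctions in RNA-Seq reads by
    exact split-read matching against a reference genome, aggregates junction
    evidence into circRNA candidates with count and length filters, compares
    wild-type and RNA-ligase-knockout samples to call circRNA depletion and
    RPKM fold changes, and annotates candidate loci as C/D box sRNAs with a
    terminal-stem circularizability call. Includes a synthetic-data generator
    that plants circular C/D-box-like sRNA loci in a prokaryote-scale genome
    and simulates 51-nt reads with a machine-readable truth table, and a
    packaged catalog of 31 circular RNA loci reported for Thermococcus
    kodakarensis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stringi,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
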