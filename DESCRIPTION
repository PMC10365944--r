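Package: pegstop
Title: Design of Stop-Codon-Installing Prime Editing Reagents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers protein-coding codons convertible into premature stop
    codons by prime editing (and, for comparison, by cytosine-base-editor
    iSTOP and adenine-base-editor i-Silence strategies), designs the complete
    editing reagents (pegRNA with primer-binding site and reverse
    transcription template, PE3 nicking sgRNA, Golden-Gate cloning oligos),
    designs precise reversion pegRNAs for installed nonsense mutations, and
    aggregates targetability statistics over annotated genomes and variant
    tables at gene, transcript, exon, early-exon and open-reading-frame
    level. Includes a deterministic synthetic-genome generator with planted,
    ground-truth-known target sites so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
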