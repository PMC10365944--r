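# pegstop

Design toolkit for installing premature stop codons by **prime editing**,
and for getting precisely back out again.

Gene inactivation with base editors is constrained by chemistry: a
cytosine base editor can only create stops from codons of three amino
acids (Gln, Arg, Trp — the iSTOP strategy), and start-codon disruption by
an adenine base editor (i-Silence) only works when the ATG happens to sit
in the editing window. A prime editor (PE) writes arbitrary templated
substitutions downstream of its nick, so *any* sense codon can be
converted into TAA/TAG/TGA with at most three base changes. `pegstop`
implements the full computational side of that strategy:

* **Stop-substitution calculus** — for every sense codon, the substitution
  plans reaching each stop codon (`stops_reachable()`, `min_plan()`), and
  the strand-pure C→T / G→A routes available to a CBE
  (`cbe_stop_routes()`).
* **Site discovery** — scanners over spliced CDS models for PE stop sites
  (`scan_pe_stops()`), iSTOP sites (`scan_istop()`) and i-Silence
  start-codon sites (`scan_isilence()`), with in-frame filtering and
  exon-junction exclusion.
* **Reagent design** — pegRNAs assembled as
  `spacer + scaffold + RTT + PBS (+ 3' appendix)` with a 13-nt PBS, an RTT
  extending ~14 nt past the last edit (grown while the scaffold-adjacent
  base would be C), PE3 nicking sgRNAs 50–90 bp away, 1x/2x/3x adjacent
  stop-codon plans, and Golden-Gate cloning oligos
  (`design_pegrna()`, `plan_multi_stop()`, `emit_oligos()`).
* **Precise reversion** — when the forward edit spares the PAM GG
  (positions +5/+6 from the nick), the mutant allele is re-targetable at
  the same protospacer; `design_reversion()` builds the back-mutation
  pegRNA and verifies in silico that forward-then-reverse restores the
  reference byte-exactly. `classify_rescue()` labels sites
  PE_precise / ABE_precise / ABE_bystander / PE_unreachable.
* **Targetability statistics** — gene / transcript / exon / early-exon /
  ORF coverage (`coverage_report()`, `find_orfs()`), and
  nonsense-variant classification against a ClinVar-style table
  (`variant_targetability()`, windows +1..+6 or +1..+9).
* **Synthetic fixtures** — `make_genome()` builds small annotated genomes
  (FASTA + GFF3) with planted, ground-truth-known sites and decoys, so
  the entire pipeline is testable offline.

Geometry used throughout: the nickase cuts the PAM strand between
protospacer positions 17 and 18 (3 nt upstream of the NGG); "+n" counts
bases 3' of the nick on the PAM strand, so +1..+3 are protospacer 18–20
and +4..+6 are the PAM triplet.

## Worked example

```r
library(pegstop)

fx   <- make_genome(seed = 7)                 # synthetic annotated genome
hits <- scan_pe_stops(fx$genome, fx$transcripts)   # 450 hits
h    <- hits[hits$codon == "CGA", ][1, ]      # an Arg codon, 1 sub to TGA

design_pegrna(fx$genome, fx$transcripts, h)
#> <pegrna> chr2:tx02 nick@585 (+ strand PAM AGG)
#>   spacer  GTACAACATCAGATGGAACCG
#>   PBS(13) TTCCATCTGATGT
#>   RTT(16) GTACAAGGGACCTCAG
#>   edits   +2:C>T
#>   PE3 nick sgRNA CTATGGAGTCCATATACGTT (PAM AGG, 78 bp from pegRNA nick)
#>   in-silico check: OK
```

The CGA codon sits at +1..+3 of the nick; a single C→T at +2 writes TGA.
The PBS is the reverse complement of the 13 nt 5' of the nick, the 16-nt
RTT covers the edit plus the 14-nt extension, and the PE3 nicking sgRNA
cuts the opposite strand 78 bp away (closest candidate to the 70-bp
midpoint of the 50–90 bp range). Because the edit spares the PAM GG, the
same protospacer reverts the mutation:

```r
design_reversion(fx$genome, design_pegrna(fx$genome, fx$transcripts, h))
#> <reversion_design> same PAM: TRUE; nick sgRNA shared: TRUE; locus restored: TRUE
```

Coverage on the same fixture shows the chemistry gap the tool exists to
close — every coding exon is PE-targetable, but only 56% have an iSTOP
codon in window:

```r
coverage_report(rbind(hits, scan_istop(fx$genome, fx$transcripts)),
                fx$genome, fx$transcripts, "exon")
#>   level editor targetable total percent
#> 1  exon     PE         16    16  100.00
#> 2  exon  iSTOP          9    16   56.25
```

A thin command-line front end (`inst/cli/pegstop.R`) exposes the same
workflows as `scan`, `design`, `coverage`, `revert` and `variants`
subcommands over FASTA/GFF3/TSV files.

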