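---
title: "Designing and reverting nonsense substitutions with prime editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and reverting nonsense substitutions with prime editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegstop)
```

## The model

A prime editor is an nCas9(H840A)–reverse-transcriptase fusion guided by
a pegRNA: a spacer and scaffold followed by a 3' extension consisting of
a reverse-transcription template (RTT) and a primer-binding site (PBS).
The nickase cuts the PAM-bearing strand three nucleotides upstream of the
NGG, i.e. between protospacer positions 17 and 18. The PBS anneals to
the bases 5' of the nick; the RTT then templates new DNA over the bases
3' of the nick. We count those bases +1, +2, ... on the PAM strand, so
+1..+3 are protospacer positions 18–20 and +4..+6 are the PAM triplet
itself.

Because the RTT can encode arbitrary substitutions, any in-frame sense
codon lying in the editable region can be rewritten into TAA, TAG or TGA
with at most three base changes. That is the entire premise of the
package: where a cytosine base editor can only produce stops from
CAA/CAG/CGA (C→T on the coding strand) and TGG (C→T on the template
strand) — codons of glutamine, arginine and tryptophan — a prime editor
covers all 20 amino acids. `amino_acids_stop_reachable()` derives both
facts by enumeration rather than stating them.

## The scanners and their filters

All three scanners work on the spliced CDS of each transcript (built by
`build_cds_map()`, which also records per-base genomic coordinates, exon
numbers and junction offsets). Motif hits whose protospacer+PAM
footprint or target codon would straddle an exon–exon junction are
excluded: such matches exist only in the spliced array, not in the
genome, and a junction-free footprint is also what guarantees the
contiguous genomic context that reagent design needs. Scanning the
arrays rather than raw genomic DNA means protospacers reaching outside
the CDS are out of scope; the one exception is the i-Silence scanner,
which surveys the full first-exon sequence so that protospacers may
reach into the 5' UTR around the start codon.

Editor-specific rules:

* **PE** (`scan_pe_stops()`): every NGG protospacer on either strand;
  every in-frame sense codon wholly contained in the nick-relative
  window. The default window is +1..+6, a conservative choice that
  favours nick-proximal edits where prime editing is most efficient;
  +1..+9 is the relaxed window used when a fixed-position variant must
  be reached. A `codon_placement = "edited_bases"` mode relaxes
  whole-codon containment to containment of the substituted bases only;
  the default mirrors the fixed-width motif reading of the search
  definition, and the choice is exposed because the rule is a
  convention, not a law.
* **iSTOP** (`scan_istop()`): in-frame CAG/CAA/CGA with the editable C
  at protospacer positions 4–8 of a coding-strand NGG protospacer, or
  TGG positioned so its template-strand Cs fall in the same window of a
  template-strand protospacer. Among a TGG's strand-pure routes the
  scanner keeps the first window-compatible one under the standard
  ordering (fewest substitutions, then TAA < TAG < TGA).
* **i-Silence** (`scan_isilence()`): only the annotated start codon,
  only in the first exon; a hit needs an editable adenine — the
  coding-strand A of ATG or the template-strand A opposite its T — at
  protospacer positions 4–8. Both adenines are accepted by default
  (`adenine = "both"`) because the window statement constrains the
  target nucleotide, not its strand; the argument narrows it if wanted.

Two codon classes are never targets: the initiator ATG (rewriting it is
start-codon disruption, i.e. the i-Silence strategy, not a nonsense
substitution) and existing stop codons.

## Reagent sizing rules

`build_pegrna()` applies fixed defaults chosen for predictable initial
designs rather than per-site optimisation:

* **PBS**: 13 nt, the reverse complement of the 13 bases immediately 5'
  of the nick on the PAM strand (equivalently protospacer positions
  5–17). The length is configurable (1–17).
* **RTT**: covers +1 through the most-3' edited base plus a 14-nt
  extension, emitted as the reverse complement of the edited segment.
  If the scaffold-adjacent (5'-most) RTT base would be C — which
  impairs scaffold function in this expression format — the RTT grows
  base by base until it is not, with a 30-nt growth cap treated as an
  error.
* **Spacer**: the 20-nt protospacer, G-prepended to 21 nt when it does
  not start with G (U6 transcription convention; `g_prepend = FALSE`
  disables it).
* **PE3 nicking sgRNA** (`select_nick_sgrna()`): opposite-strand NGG
  protospacers whose nick falls 50–90 bp from the pegRNA nick; among
  candidates the distance closest to the 70-bp midpoint wins, ties going
  to the smaller distance and then the smaller coordinate. The midpoint
  rule is a determinism device — the literature gives only the range.
* **Cloning oligos** (`emit_oligos()`): spacer duplex with 5' ACCG /
  3' GTTTC (top) and 5' CTCTGAAAC (bottom); extension duplex (RTT+PBS)
  with 5' GTGC (top) and 5' GACA (bottom) overhangs, matching a
  Golden-Gate assembly into a U6 pegRNA backbone.
* **Scaffold and 3' appendix**: the canonical SpCas9 scaffold ships as
  `SGRNA_SCAFFOLD`; the exoribonuclease-resistant 3' stabilising motif
  is plasmid-specific, so `XRRNA_PLACEHOLDER` is a synthetic stand-in
  of representative length that must be overridden before ordering
  oligos. Both are plain arguments.

`plan_multi_stop()` extends a hit to 2 or 3 consecutive stop codons —
larger edits evade mismatch-repair rejection of small heteroduplexes and
empirically edit better. The extra codons must lie 3' of the nick on the
PAM strand, because the RTT cannot template upstream of the nick; for
template-strand PAMs that means the extra stops extend coding-upstream
(codons k−1, k−2) rather than downstream. Spacer and PBS are invariant
across 1x/2x/3x by construction.

## Reversion and rescue classes

A prime edit that spares +5/+6 (the GG of the PAM) leaves the same
protospacer usable on the mutant allele: `design_reversion()` reuses it
with the edit applied to the spacer and an RTT templating the reference
bases, and reuses the forward nicking sgRNA whenever its footprint
escaped the edit. When the PAM was destroyed, the edited allele is
searched for an alternative NGG placing every edited base in the window;
failure raises a typed `pegstop_pe_unreachable` error. Every reversion
design is verified by in-silico application: forward-then-reverse must
restore the contig byte-exactly.

For iSTOP primaries, `classify_rescue()` asks whether an adenine base
editor could revert the installed C→T: each installed T reads A on the
opposite strand, and all such As must sit at protospacer positions 4–8
of one NGG protospacer. A candidate with no *additional* adenine in its
window yields `ABE_precise`; if every candidate carries bystander
adenines the site is `ABE_bystander` (the operational bystander rule is
our reconstruction: the concept is standard, the exact rule is not
printed anywhere). PE rescue of iSTOP edits is evaluated exactly as for
PE primaries. `best_rescue_class()` orders
PE_precise > ABE_precise > ABE_bystander > PE_unreachable for
transcript-level summaries.

## Variant targetability

`variant_targetability()` implements the fixed-position survey: filter
to single-nucleotide nonsense records unique by gene and location,
reject records whose reference base disagrees with the genome (flagged,
excluded from denominators), then classify each survivor within ±100 bp
of flanking sequence. PE-targetable means some NGG protospacer on either
strand places the variant base at +1..+9 (the relaxed window, since the
position cannot be chosen); iSTOP-targetable means a C→T (or G→A) record
whose C sits at protospacer positions 4–8. The class vocabulary includes
`iSTOP_only` alongside PE_and_iSTOP / PE_only / neither: the two windows
sit on opposite sides of the nick, so iSTOP-yes/PE-no is geometrically
possible even though it is rare.

## The synthetic-data generator

`make_genome()` builds small annotated genomes by inverse motif
synthesis: forcing one neighbouring codon to an NGG-type codon
(AGG/CGG/GGG/TGG) or a proline CCN codon places a PAM at exactly the
offset that puts the target codon at the intended window position, with
all forced codons sense codons so the frame stays clean. Defaults: genes
of 90–130 codons, 30-nt 5' UTRs, 20-nt 3' UTRs, 80–150-nt GT..AG
introns, 250-bp intergenic spacers, background GC 0.45 — small but
realistic enough that incidental PAMs occur at natural density, which is
deliberate: recall is asserted against the planted truth, precision
against a brute-force enumerator that also sees the incidental sites.
Planted decoys (out-of-frame codon, out-of-window codon, junction-split
protospacer) must never be reported; planted variant loci carry known
classifications including a PAM-desert built from A/T-only codons.
Regeneration from the same seed is byte-identical.

What the generator does **not** emulate: real exon-length and
gene-length distributions, isoform overlap, repeat content, alternative
PAM densities of biased-GC genomes, and annotation noise beyond a
non-multiple-of-3 CDS. Passing tests therefore demonstrate geometric
and algorithmic correctness, not genome-scale coverage figures; the
published-genome percentages depend on the annotation release and are
left to users running `load_annotated_genome()` on real assemblies.

## Numerical and representational choices

* Coordinates are 1-based inclusive throughout, the R/Bioconductor and
  genome-browser convention; BED export converts to 0-based starts.
* The stop-codon tie-break (fewest substitutions, then TAA < TAG < TGA)
  is a determinism device; `forced_stop` overrides it wherever a
  specific stop is wanted.
* A CDS whose length is not a multiple of 3 is trimmed at the 3' end
  with a warning; a transcript not starting ATG is flagged
  `low_confidence_start` but still scanned with the first CDS base as
  frame anchor.
* `find_orfs()` uses ATG-only starts, first in-frame stop, both strands,
  75-nt minimum — the conventional short-ORF default; all are
  arguments.
* All RNA segments are emitted in the DNA alphabet (T not U), matching
  oligo-ordering practice.

## Problem sizes in the test suite

The suite generates its data at run time: fixture genomes of ~7 kb
(8 genes) are scanned and compared hit-for-hit against brute-force
enumerators on 20+ seeds; 120 random designs are applied in silico and,
where a reversion design exists, reverted byte-exactly; the genetic-code
module is checked against exhaustive enumeration over all 61 sense
codons. These sizes keep the default run in the low minutes on one CPU
while exercising every code path, including both PAM strands, multi-exon
splicing and every decoy class.

## Known limitations

No efficiency prediction or on-target scoring (designs are geometric,
screening stays empirical); NGG PAMs only; no off-target search; no
MMR-inhibition (PE4/PE5) modelling; standard genetic code only; no
selenocysteine recoding or liftover handling.
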