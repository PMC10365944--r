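# shared fixture shortcuts; everything is generated in code at test time

default_fixture <- function(seed = 7, ...) make_genome(seed, ...)

all_hits <- function(fx) {
  rbind(
    scan_pe_stops(fx$genome, fx$transcripts),
    scan_istop(fx$genome, fx$transcripts),
    scan_isilence(fx$genome, fx$transcripts)
  )
}

truth_key <- function(ts) {
  paste(ts$editor, ts$transcript_id, ts$codon_index, ts$pam_strand, ts$proto_g1)
}

hit_key <- function(hits) {
  paste(hits$editor, hits$transcript_id, hits$codon_index, hits$pam_strand,
        hits$proto_g1)
}

# a single-locus, plus-strand, single-exon transcript over a raw sequence
as_locus <- function(seq, id = "locus", contig = "chrL") {
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, contig))
  iv <- data.frame(start = 1L, end = nchar(seq))
  tx <- transcript_model(id, paste0(id, "_gene"), contig, "+", iv, iv)
  list(genome = genome, transcripts = stats::setNames(list(tx), id), tx = tx)
}

# engineered locus: CDS of `n` codons with codon k targetable at +1..+3
# (codon k+1 forced to AGG); returns as_locus() output plus k
plus_strand_locus <- function(k = 12, n = 40, seed = 5, target = "CGA") {
  codons <- pegstop:::with_seed(seed, pegstop:::random_sense_codons(n))
  codons[1] <- "ATG"
  codons[n] <- "TAA"
  codons[k] <- target
  codons[k + 1] <- "AGG"
  loc <- as_locus(paste(codons, collapse = ""))
  loc$k <- k
  loc
}
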