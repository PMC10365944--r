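# Scanner geometry on engineered loci, plus oracle equivalence and the
# window/strand properties.

test_that("a codon at +1..+3 of a planted PAM yields exactly one hit there", {
  loc <- plus_strand_locus(k = 12, target = "CGA")   # codon k+1 = AGG
  hits <- scan_pe_stops(loc$genome, loc$transcripts)
  at_k <- hits[hits$codon_index == loc$k, ]
  planted <- at_k[at_k$codon_offset == 1L & at_k$pam_strand == "+", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$n_subs, 1L)
  expect_equal(planted$product, "TGA")
  expect_equal(planted$edit_offsets, "1")
  expect_equal(planted$edit_ref, "C")
  expect_equal(planted$edit_alt, "T")
  # the nick sits 3 nt upstream of the PAM
  expect_equal(planted$nick_g, planted$proto_g1 + 17L)
})

test_that("window containment excludes +7..+9 codons unless widened", {
  # force codon k-1 to AGG so codon k sits at +7..+9 of that PAM
  codons <- pegstop:::with_seed(6, pegstop:::random_sense_codons(40))
  codons[1] <- "ATG"; codons[40] <- "TAA"
  codons[20] <- "CGA"; codons[19] <- "AGG"
  # remove other PAM-forming context near codon 20 is unnecessary: we only
  # assert about the planted anchor
  loc <- as_locus(paste(codons, collapse = ""))
  anchor_cds <- 3L * 20L - 25L
  h6 <- scan_pe_stops(loc$genome, loc$transcripts, window = c(1, 6))
  h9 <- scan_pe_stops(loc$genome, loc$transcripts, window = c(1, 9))
  in6 <- h6[h6$codon_index == 20 & h6$proto_g1 == anchor_cds, ]
  in9 <- h9[h9$codon_index == 20 & h9$proto_g1 == anchor_cds, ]
  expect_equal(nrow(in6), 0L)
  expect_equal(nrow(in9), 1L)
  expect_equal(in9$codon_offset, 7L)
})

test_that("relaxed codon placement admits partially-out-of-window codons", {
  # codon at +5..+7 overlaps the PAM GG, so it reads GGx; its minimal plan
  # (GGG -> TAG) edits +5 and +6 only.  The whole-codon rule rejects it
  # under (1,6); the edited-bases rule accepts it.
  codons <- pegstop:::with_seed(8, pegstop:::random_sense_codons(40))
  codons[1] <- "ATG"; codons[40] <- "TAA"
  k <- 15L
  # place PAM so codon k starts at +5: proto start s = 3k - 23; the PAM
  # write also sets codon k's first two bases to GG
  s <- 3L * k - 23L
  seq <- paste(codons, collapse = "")
  substr(seq, 3L * k - 2L, 3L * k) <- "GGG"
  substr(seq, s + 20L, s + 22L) <- "AGG"
  loc <- as_locus(seq)
  whole <- scan_pe_stops(loc$genome, loc$transcripts, window = c(1, 6))
  relaxed <- scan_pe_stops(loc$genome, loc$transcripts, window = c(1, 6),
                           codon_placement = "edited_bases")
  w <- whole[whole$codon_index == k & whole$proto_g1 == s &
               whole$pam_strand == "+", ]
  r <- relaxed[relaxed$codon_index == k & relaxed$proto_g1 == s &
                 relaxed$pam_strand == "+", ]
  expect_equal(nrow(w), 0L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$codon, "GGG")
  expect_equal(r$product, "TAG")
  expect_equal(r$edit_offsets, "5,6")   # both edits inside the window
})

test_that("iSTOP window and frame rules behave on engineered loci", {
  base <- function(k, codon, pam_codon_at) {
    codons <- pegstop:::with_seed(9, pegstop:::random_sense_codons(45))
    codons[1] <- "ATG"; codons[45] <- "TAA"
    codons[k] <- codon
    codons[pam_codon_at] <- "AGG"
    as_locus(paste(codons, collapse = ""))
  }
  # C at protospacer position 6 (PAM = codon k+5): reported
  loc <- base(18, "CAG", 23)
  h <- scan_istop(loc$genome, loc$transcripts)
  got <- h[h$codon_index == 18 & h$proto_g1 == 3L * 18L - 7L, ]
  expect_equal(nrow(got), 1L)
  expect_equal(got$product, "TAG")
  expect_equal(got$edit_offsets, "6")

  # same codon, PAM two codons further: C would sit at position 12 -> no hit
  loc2 <- base(18, "CAG", 25)
  h2 <- scan_istop(loc2$genome, loc2$transcripts)
  expect_equal(nrow(h2[h2$codon_index == 18 & h2$proto_g1 == 3L * 18L - 13L, ]), 0L)

  # out-of-frame CAG at the same window position is not reported
  fx <- default_fixture(seed = 41, features = "decoy_frame")
  ts <- fx$truth$sites
  h3 <- scan_istop(fx$genome, fx$transcripts)
  expect_false(any(h3$proto_g1 == ts$proto_g1 & h3$pam_strand == ts$pam_strand))
})

test_that("i-Silence hits require the start codon in exon 1 geometry", {
  fx <- default_fixture(seed = 42, features = c("isilence", "pe_plus"))
  hits <- scan_isilence(fx$genome, fx$transcripts)
  ts <- fx$truth$sites[fx$truth$sites$editor == "iSilence", ]
  expect_true(truth_key(ts) %in% hit_key(hits))
  planted <- hits[hits$proto_g1 == ts$proto_g1, ]
  expect_equal(planted$edit_offsets, "5")     # A at protospacer position 5
  expect_equal(planted$codon, "ATG")
  # internal ATGs never yield hits
  expect_true(all(hits$codon_index == 1L))
  # a transcript whose first exon lacks the start codon is skipped
  tx <- fx$transcripts[[ts$transcript_id]]
  fake_e1 <- data.frame(start = max(1L, tx$exons$start[1] - 60L),
                        end = tx$exons$start[1] - 40L)
  tx2 <- transcript_model("noatg", tx$gene_id, tx$contig, "+",
                          rbind(fake_e1, tx$exons), tx$cds)
  expect_warning(h0 <- scan_isilence(fx$genome, list(noatg = tx2)),
                 "first exon")
  expect_equal(nrow(h0), 0L)
})

test_that("scanners equal the brute-force enumerator on fixture genomes", {
  for (seed in c(101, 102, 103)) {
    fx <- default_fixture(seed)
    hits <- all_hits(fx)
    expect_identical(impl_pe_keys(hits),
                     oracle_scan_pe(fx$genome, fx$transcripts))
    expect_identical(impl_istop_keys(hits),
                     oracle_scan_istop(fx$genome, fx$transcripts))
    expect_identical(impl_isilence_keys(hits, fx$transcripts),
                     oracle_scan_isilence(fx$genome, fx$transcripts))
    validate_hits(hits, fx$genome)
  }
})

test_that("hit sets mirror under genome reverse-complementation", {
  fx <- default_fixture(seed = 55, features = c("pe_plus", "istop_cag"))
  hits <- scan_pe_stops(fx$genome, fx$transcripts)
  # mirror the genome and annotation
  L <- vapply(as.character(fx$genome), nchar, 1L)
  mg <- Biostrings::reverseComplement(fx$genome)
  mtx <- lapply(fx$transcripts, function(tx) {
    n <- L[[tx$contig]]
    flip <- function(df) data.frame(start = n + 1L - df$end, end = n + 1L - df$start)
    transcript_model(tx$transcript_id, tx$gene_id, tx$contig,
                     pegstop:::flip_strand(tx$strand), flip(tx$exons), flip(tx$cds))
  })
  mirrored <- scan_pe_stops(mg, mtx)
  # coordinates mirror, biology identical
  expect_equal(nrow(mirrored), nrow(hits))
  key <- function(h, n) sort(paste(h$transcript_id, h$codon_index, h$n_subs,
                                   h$product, h$protospacer))
  expect_equal(key(mirrored), key(hits))
  m_g1 <- vapply(seq_len(nrow(mirrored)), function(i) {
    L[[mirrored$contig[i]]] + 1L - mirrored$proto_g1[i]
  }, 1L)
  expect_setequal(m_g1, hits$proto_g1)
})

test_that("window monotonicity: (1,6) hits are a subset of (1,9) hits", {
  fx <- default_fixture(seed = 66)
  h6 <- scan_pe_stops(fx$genome, fx$transcripts, window = c(1, 6))
  h9 <- scan_pe_stops(fx$genome, fx$transcripts, window = c(1, 9))
  expect_true(all(h6$hit_id %in% h9$hit_id))
  expect_gt(nrow(h9), nrow(h6))
})
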