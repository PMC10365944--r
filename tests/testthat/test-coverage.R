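# Coverage aggregation and variant classification.

test_that("an empty hit table gives zero coverage at every level", {
  fx <- default_fixture(seed = 71, features = c("pe_plus", "istop_cag"))
  none <- scan_pe_stops(fx$genome, fx$transcripts)[0, ]
  for (lv in c("gene", "transcript", "exon", "early_exon")) {
    rep <- coverage_report(none, fx$genome, fx$transcripts, lv, editors = "PE")
    expect_equal(rep$targetable, 0L)
    expect_gt(rep$total, 0L)
    expect_equal(rep$percent, 0)
  }
  expect_error(coverage_report(none, fx$genome, fx$transcripts, "chromosome"))
})

test_that("coverage counts equal oracle-derived record sets", {
  fx <- default_fixture(seed = 72)
  hits <- all_hits(fx)
  # oracle-derived targetable transcripts for PE
  ok <- oracle_scan_pe(fx$genome, fx$transcripts)
  o_tx <- unique(vapply(strsplit(ok, "|", fixed = TRUE), `[[`, "", 2))
  rep <- coverage_report(hits, fx$genome, fx$transcripts, "transcript",
                         editors = "PE")
  expect_equal(rep$targetable, length(o_tx))
  expect_equal(rep$total, length(fx$transcripts))
  # planted sites guarantee their transcript is counted
  ts <- fx$truth$sites
  planted_tx <- unique(ts$transcript_id[ts$kind == "site" & ts$editor == "PE"])
  recs <- attr(rep, "records")
  expect_true(all(recs$PE[recs$record %in% planted_tx]))
  # percentages recompute from counts
  expect_equal(rep$percent, 100 * rep$targetable / rep$total)
})

test_that("per-gene iSTOP coverage is nested in the PE+iSTOP union", {
  fx <- default_fixture(seed = 73)
  hits <- all_hits(fx)
  rep <- coverage_report(hits, fx$genome, fx$transcripts, "gene",
                         editors = c("PE", "iSTOP"))
  recs <- attr(rep, "records")
  expect_true(all(!recs$iSTOP | (recs$iSTOP | recs$PE)))
  istop_set <- recs$record[recs$iSTOP]
  union_set <- recs$record[recs$iSTOP | recs$PE]
  expect_true(all(istop_set %in% union_set))
})

test_that("early-exon coverage restricts to exons 1..ceiling(E/5)", {
  fx <- default_fixture(seed = 74, exons_per_gene = c(3L, 6L))
  hits <- all_hits(fx)
  rep_all <- coverage_report(hits, fx$genome, fx$transcripts, "exon")
  rep_early <- coverage_report(hits, fx$genome, fx$transcripts, "early_exon")
  expect_lt(rep_early$total[1], rep_all$total[1])
  early_recs <- attr(rep_early, "records")
  expect_true(all(early_recs$exon <= vapply(
    early_recs$transcript_id,
    function(id) early_exon_count(fx$transcripts[[id]]), 1L
  )))
})

test_that("ORF-level coverage runs over ORF-derived transcript models", {
  s <- pegstop:::with_seed(75, pegstop:::random_bases(1500, 0.5))
  genome <- Biostrings::DNAStringSet(c(chrO = s))
  orfs <- find_orfs(s, min_len = 150, contig = "chrO")
  skip_if(nrow(orfs) == 0, "no ORFs in this draw (seed-fixed, should not happen)")
  otx <- orfs_as_transcripts(orfs)
  hits <- scan_pe_stops(genome, otx)
  rep <- coverage_report(hits, genome, otx, "orf")
  expect_equal(rep$total, nrow(orfs))
  expect_true(rep$targetable <= rep$total)
})

test_that("variant classification matches the planted truth and the oracle", {
  fx <- default_fixture(seed = 76, features = c("variant", "pe_plus"))
  vt <- make_variant_table(fx, n_decoys = 2, seed = 3)
  res <- variant_targetability(vt, fx$genome)
  exp <- attr(vt, "expected")
  for (i in seq_len(nrow(exp))) {
    row <- res[res$pos == exp$pos[i] & res$contig == exp$contig[i], ]
    if (exp$kind[i] == "planted") {
      expect_equal(row$status, "classified")
      expect_equal(row$class, exp$expected_class[i], label = exp$kind[i])
      # independent brute-force protospacer enumeration agrees
      cs <- as.character(fx$genome[[exp$contig[i]]])
      expect_equal(row$class,
                   oracle_variant_class(cs, exp$pos[i], exp$ref[i], exp$alt[i]))
    } else if (exp$kind[i] == "decoy_consequence") {
      expect_equal(row$status, "filtered_consequence")
    } else if (exp$kind[i] == "decoy_ref_mismatch") {
      expect_equal(row$status, "ref_mismatch")
    }
  }
  # the random missense decoys are filtered before classification
  expect_true(all(res$status[res$gene == "random"] == "filtered_consequence"))
})

test_that("a variant base exactly at +9 is PE-targetable only under (1,9)", {
  # protospacer with PAM then the variant 3 nt past the PAM
  seq <- paste0(
    strrep("T", 30),
    "ACGTACGTACGTACGTA", "CAT",   # protospacer positions 1..20
    "TGG",                        # PAM (+4..+6)
    "AAC",                        # +7..+9; variant at +9
    strrep("T", 30)
  )
  genome <- Biostrings::DNAStringSet(c(v = seq))
  x <- 30L + 23L + 3L             # the C at +9
  v <- data.frame(contig = "v", pos = x, ref = "C", alt = "T",
                  gene = "g", consequence = "nonsense")
  r9 <- variant_targetability(v, genome, pe_window = c(1, 9))
  r6 <- variant_targetability(v, genome, pe_window = c(1, 6))
  expect_true(r9$pe)
  expect_false(r6$pe)
  # monotonicity on the fixture variants too
  fx <- default_fixture(seed = 77, features = "variant")
  vt <- make_variant_table(fx, n_decoys = 0)
  p6 <- variant_targetability(vt, fx$genome, pe_window = c(1, 6))
  p9 <- variant_targetability(vt, fx$genome, pe_window = c(1, 9))
  cls <- !is.na(p6$pe)
  expect_true(all(!p6$pe[cls] | p9$pe[cls]))
})

test_that("a G>A variant whose C-image sits at protospacer position 3 is not iSTOP-targetable", {
  # the only candidate protospacer is on the minus strand (CC-PAM on plus
  # at 41-42); the variant G at plus 61 reads C at position 3 of that
  # protospacer -- one position short of the 4-8 editing window
  seq <- paste0(strrep("T", 40), "CC", strrep("T", 18), "G", strrep("T", 40))
  genome <- Biostrings::DNAStringSet(c(w = seq))
  v <- data.frame(contig = "w", pos = 61L, ref = "G", alt = "A",
                  gene = "g", consequence = "nonsense")
  r <- variant_targetability(v, genome)
  expect_equal(r$status, "classified")
  expect_false(r$istop)
  # moving the PAM one base right puts the C at position 4: targetable
  seq2 <- paste0(strrep("T", 41), "CC", strrep("T", 17), "G", strrep("T", 40))
  genome2 <- Biostrings::DNAStringSet(c(w = seq2))
  r2 <- variant_targetability(v, genome2)
  expect_true(r2$istop)
})

test_that("BED export keeps footprints and scores aligned with hits", {
  fx <- default_fixture(seed = 78, features = c("pe_plus", "pe_minus"))
  hits <- scan_pe_stops(fx$genome, fx$transcripts)
  bed <- hits_to_bed(hits)
  expect_equal(nrow(bed), nrow(hits))
  expect_true(all(bed$end - bed$start == 23L))
  expect_equal(bed$score, hits$n_subs)
  # the BED interval really contains the protospacer on the named strand
  i <- 1L
  cs <- as.character(fx$genome[[bed$chrom[i]]])
  span <- substr(cs, bed$start[i] + 1L, bed$end[i])
  expect_equal(nchar(span), 23L)
  if (bed$strand[i] == "+") {
    expect_equal(substr(span, 1, 20), hits$protospacer[i])
  } else {
    expect_equal(substr(revcomp(span), 1, 20), hits$protospacer[i])
  }
})
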