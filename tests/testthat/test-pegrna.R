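# Reagent geometry: PBS/RTT sizing and complementarity, nick placement,
# multi-stop planning, nicking-sgRNA selection, cloning oligos.

planted_hit <- function(fx, feature_strand = "+") {
  ts <- fx$truth$sites
  ts <- ts[ts$editor == "PE" & ts$kind == "site" &
             ts$pam_strand == feature_strand, ][1, ]
  hits <- scan_pe_stops(fx$genome, fx$transcripts)
  hits[hits$transcript_id == ts$transcript_id &
         hits$codon_index == ts$codon_index &
         hits$pam_strand == ts$pam_strand &
         hits$proto_g1 == ts$proto_g1, ][1, ]
}

test_that("default designs have a 13-nt PBS complementary to the flank", {
  fx <- default_fixture(seed = 81, features = c("pe_plus", "pe_minus"))
  for (strand in c("+", "-")) {
    h <- planted_hit(fx, strand)
    peg <- build_pegrna(fx$genome, h)
    expect_equal(nchar(peg$pbs), 13L)
    # PBS equals the reverse complement of protospacer positions 5..17
    expect_equal(peg$pbs, revcomp(substr(h$protospacer, 5, 17)))
    # and of the 13 nt immediately 5' of the nick on the PAM strand
    cs <- as.character(fx$genome[[h$contig]])
    up <- pegstop:::oriented_read(
      cs, h$g_pam_strand,
      pegstop:::oriented_shift(h$nick_g, h$g_pam_strand, -13L), 13L
    )
    expect_equal(peg$pbs, revcomp(up))
  }
})

test_that("the nick is 3 nt upstream of the PAM on the PAM strand", {
  fx <- default_fixture(seed = 82)
  hits <- scan_pe_stops(fx$genome, fx$transcripts)
  d <- ifelse(hits$g_pam_strand == "+",
              hits$proto_g1 + 20L - (hits$nick_g + 3L),
              (hits$nick_g - 3L) - (hits$proto_g1 - 20L))
  expect_true(all(d == 0L))
})

test_that("RTT equals the reverse complement of the edited downstream segment", {
  fx <- default_fixture(seed = 83, features = c("pe_plus", "pe_minus"))
  for (strand in c("+", "-")) {
    h <- planted_hit(fx, strand)
    peg <- build_pegrna(fx$genome, h)
    cs <- as.character(fx$genome[[h$contig]])
    ref_seg <- pegstop:::oriented_read(cs, h$g_pam_strand, h$nick_g, peg$rtt_len)
    seg <- strsplit(ref_seg, "")[[1]]
    plan <- hit_plan(h)
    # RTT minus the edits is the reverse complement of the reference
    rtt_seg <- strsplit(revcomp(peg$rtt), "")[[1]]
    expect_equal(rtt_seg[-plan$edits$offset], seg[-plan$edits$offset])
    expect_equal(rtt_seg[plan$edits$offset], plan$edits$alt)
    # RTT covers the last edit plus the 14-nt extension (unless grown)
    expect_gte(peg$rtt_len, max(plan$edits$offset) + 14L)
    # the scaffold-adjacent base is never C
    expect_false(substr(peg$rtt, 1, 1) == "C")
  }
})

test_that("the RTT grows past a C terminus and the spacer gets its 5' G", {
  # engineer: G run at the default RTT terminus forces growth
  codons <- pegstop:::with_seed(84, pegstop:::random_sense_codons(40))
  codons[1] <- "ATG"; codons[40] <- "TAA"
  k <- 12L
  codons[k] <- "CGA"; codons[k + 1L] <- "AGG"
  # default terminus at +15 (edit at +1, 14-nt extension); pave +15 onward
  # with G so the C-avoidance rule must extend the RTT
  codons[k + 4L] <- "AGG"; codons[k + 5L] <- "GGG"; codons[k + 6L] <- "GGA"
  loc <- as_locus(paste(codons, collapse = ""))
  hits <- scan_pe_stops(loc$genome, loc$transcripts)
  h <- hits[hits$codon_index == k & hits$codon_offset == 1L, ][1, ]
  peg <- build_pegrna(loc$genome, h)
  expect_gt(peg$rtt_len, max(hit_plan(h)$edits$offset) + 14L)
  expect_false(substr(peg$rtt, 1, 1) == "C")
  # G-prepend rule
  if (substr(h$protospacer, 1, 1) != "G") {
    expect_equal(nchar(peg$spacer), 21L)
    expect_equal(substr(peg$spacer, 1, 1), "G")
  }
  peg2 <- build_pegrna(loc$genome, h, g_prepend = FALSE)
  expect_equal(peg2$spacer, h$protospacer)
})

test_that("multi-stop plans share spacer/PBS and translate to stop runs", {
  fx <- default_fixture(seed = 85, features = c("pe_plus", "pe_minus"))
  for (strand in c("+", "-")) {
    h <- planted_hit(fx, strand)
    designs <- lapply(1:3, function(n) {
      design_pegrna(fx$genome, fx$transcripts, h, n_stops = n)
    })
    subs <- vapply(designs, function(d) d$plan$n_subs, 1L)
    expect_true(all(diff(subs) >= 0))
    expect_equal(designs[[1]]$plan$edits, hit_plan(h)$edits)
    # same spacer and PBS across 1x/2x/3x
    sp <- vapply(designs, function(d) d$pegrna$spacer, "")
    pb <- vapply(designs, function(d) d$pegrna$pbs, "")
    expect_equal(length(unique(sp)), 1L)
    expect_equal(length(unique(pb)), 1L)
    # edited CDS carries consecutive stops exactly at the planned codons
    for (n in 1:3) {
      v <- designs[[n]]$validation
      expect_true(v$ok)
      expect_true(v$stop_ok)
      expect_equal(sort(v$stop_codons_at), sort(designs[[n]]$plan$codon_index))
      if (n > 1) {
        expect_equal(diff(sort(designs[[n]]$plan$codon_index)),
                     rep(1L, n - 1L))
      }
    }
  }
})

test_that("multi-stop planning refuses stops and missing CDS", {
  loc <- plus_strand_locus(k = 38, n = 40)     # codon 39 near the terminal stop
  hits <- scan_pe_stops(loc$genome, loc$transcripts)
  h <- hits[hits$codon_index == 38 & hits$codon_offset == 1L, ][1, ]
  map <- build_cds_map(loc$genome, loc$tx)
  expect_error(plan_multi_stop(map, h, 3), "insufficient CDS|already a stop")
})

test_that("nicking sgRNA selection follows the midpoint-70 rule", {
  # synthetic candidate distances via a constructed locus are brittle;
  # test the selection rule through a genome engineered to offer exact
  # candidate distances on the minus strand: CC PAM at p places a nick at
  # p+5, so candidates at distances {40, 72, 95} and {55, 88} are planted
  make_locus <- function(dists) {
    L <- 400L
    s <- strsplit(strrep("T", L), "")[[1]]
    nick <- 200L
    for (d in dists) {
      p <- nick + d - 5L            # CC at p,p+1 -> candidate nick p+5
      s[p] <- "C"; s[p + 1L] <- "C"
    }
    paste(s, collapse = "")
  }
  g1 <- Biostrings::DNAStringSet(c(n = make_locus(c(40, 72, 95))))
  ns <- select_nick_sgrna(g1, "n", "+", 200L)
  expect_equal(ns$distance, 72)
  g2 <- Biostrings::DNAStringSet(c(n = make_locus(c(55, 88))))
  ns2 <- select_nick_sgrna(g2, "n", "+", 200L)
  expect_equal(ns2$distance, 55)
  g3 <- Biostrings::DNAStringSet(c(n = make_locus(c(40, 95))))
  expect_warning(ns3 <- select_nick_sgrna(g3, "n", "+", 200L), "no opposite-strand")
  expect_null(ns3)
  # selected nick sgRNAs across fixture designs stay inside [50, 90]
  fx <- default_fixture(seed = 86)
  hits <- scan_pe_stops(fx$genome, fx$transcripts)
  set.seed(1)
  for (i in sample(nrow(hits), 10)) {
    d <- design_pegrna(fx$genome, fx$transcripts, hits[i, ])
    if (!is.null(d$nick_sgrna)) {
      expect_gte(d$nick_sgrna$distance, 50)
      expect_lte(d$nick_sgrna$distance, 90)
      expect_equal(d$nick_sgrna$g_strand,
                   pegstop:::flip_strand(hits$g_pam_strand[i]))
    }
  }
})

test_that("cloning oligos carry the documented overhangs and reconstruct", {
  fx <- default_fixture(seed = 87, features = "pe_plus")
  h <- planted_hit(fx)
  peg <- build_pegrna(fx$genome, h)
  ol <- emit_oligos(peg)
  seqs <- stats::setNames(ol$sequence, ol$oligo)
  expect_match(seqs[["spacer_top"]], "^ACCG")
  expect_match(seqs[["spacer_top"]], "GTTTC$")
  expect_match(seqs[["spacer_bottom"]], "^CTCTGAAAC")
  expect_match(seqs[["extension_top"]], "^GTGC")
  expect_match(seqs[["extension_bottom"]], "^GACA")
  # strip overhangs, anneal: spacer and extension come back exactly
  expect_equal(sub("GTTTC$", "", sub("^ACCG", "", seqs[["spacer_top"]])),
               peg$spacer)
  expect_equal(revcomp(sub("^CTCTGAAAC", "", seqs[["spacer_bottom"]])),
               peg$spacer)
  ext <- paste0(peg$rtt, peg$pbs)
  expect_equal(sub("^GTGC", "", seqs[["extension_top"]]), ext)
  expect_equal(revcomp(sub("^GACA", "", seqs[["extension_bottom"]])), ext)
})

test_that("in-silico application changes exactly the planned bases", {
  # property over many random fixture designs
  n_checked <- 0L
  for (seed in c(88, 89)) {
    fx <- default_fixture(seed)
    hits <- scan_pe_stops(fx$genome, fx$transcripts)
    set.seed(seed)
    idx <- sample(nrow(hits), min(25L, nrow(hits)))
    for (i in idx) {
      d <- design_pegrna(fx$genome, fx$transcripts, hits[i, ])
      v <- d$validation
      expect_true(v$ok, label = hits$hit_id[i])
      expect_equal(v$n_changed, v$expected_changes, label = hits$hit_id[i])
      expect_true(v$stop_ok, label = hits$hit_id[i])
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)
})
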