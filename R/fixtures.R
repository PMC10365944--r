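# Deterministic synthetic genomes with planted, ground-truth-known editor
# target sites, decoy near-misses, and variant loci.
#
# Planting works by inverse motif synthesis on the CDS codon string:
# forcing one neighbouring codon to an NGG-type (AGG/CGG/GGG/TGG) or
# CCN-type (proline) codon places a PAM at the exact offset that puts the
# target codon at the intended window position.  All forced codons are
# sense codons, the initiator is ATG and the terminal codon a stop, so the
# reading frame stays clean.  Every geometric identity used here is
# cross-checked against the scanners (and a brute-force enumerator) in the
# test suite.

NGG_CODONS <- c("AGG", "CGG", "GGG", "TGG")
CCN_CODONS <- c("CCA", "CCC", "CCG", "CCT")
AT_SENSE_CODONS <- c("TTT", "TTA", "ATT", "ATA", "AAT", "AAA", "TAT")

random_sense_codons <- function(n) {
  sample(sense_codons(), n, replace = TRUE)
}

random_bases <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_intron <- function(gc = 0.45) {
  len <- sample(80:150, 1)
  paste0("GT", random_bases(len - 4L, gc), "AG")
}

pick_k <- function(lo, hi) sample(seq.int(lo, hi), 1L)

# one gene's CDS-level plan: codons, forced junction, truth rows (CDS units)
plan_fixture_gene <- function(feature, gene_id, tx_id, n_ex, gc) {
  n <- if (feature == "variant") sample(120L:130L, 1L) else sample(90:130, 1L)
  codons <- random_sense_codons(n)
  codons[1] <- "ATG"
  codons[n] <- sample(STOP_CODONS, 1L)
  L <- 3L * n
  truth <- list()
  variants <- list()
  protected <- list()          # CDS ranges no junction may interrupt
  forced_junction <- NA_integer_

  add_site <- function(kind, editor, pam_strand, k, codon, product, n_subs,
                       proto_cds, note = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = kind, editor = editor, gene_id = gene_id, transcript_id = tx_id,
      pam_strand = pam_strand, codon_index = k, codon = codon,
      product = product, n_subs = n_subs, proto_cds = proto_cds,
      proto_g1 = NA_integer_, note = note, stringsAsFactors = FALSE
    )
  }
  protect <- function(lo, hi) {
    protected[[length(protected) + 1L]] <<- c(max(1L, lo), min(L - 1L, hi))
  }

  if (feature %in% c("pe_plus", "decoy_junction")) {
    k <- pick_k(9L, n - 4L)
    codons[k] <- sample(setdiff(sense_codons(), c("ATG", NGG_CODONS)), 1L)
    codons[k + 1L] <- sample(NGG_CODONS, 1L)
    mp <- min_plan(codons[k])
    protect(3L * k - 21L, 3L * k + 5L)
    if (feature == "pe_plus") {
      add_site("site", "PE", "+", k, codons[k], mp$product, mp$n_subs,
               3L * k - 19L, "codon at +1..+3")
    } else {
      forced_junction <- 3L * k - 10L
      add_site("decoy_junction", "PE", "+", k, codons[k], mp$product,
               mp$n_subs, 3L * k - 19L, "protospacer split by junction")
    }
  } else if (feature == "pe_minus") {
    k <- pick_k(9L, n - 8L)
    codons[k] <- sample(setdiff(sense_codons(), c("ATG", CCN_CODONS)), 1L)
    codons[k - 1L] <- sample(CCN_CODONS, 1L)
    mp <- min_plan(codons[k])
    protect(3L * k - 8L, 3L * k + 19L)
    add_site("site", "PE", "-", k, codons[k], mp$product, mp$n_subs,
             3L * k + 17L, "template-strand PAM, codon at +1..+3")
  } else if (feature == "istop_cag") {
    k <- pick_k(6L, n - 8L)
    codons[k] <- sample(c("CAG", "CAA", "CGA"), 1L)
    codons[k + 5L] <- sample(NGG_CODONS, 1L)
    protect(3L * k - 9L, 3L * k + 17L)
    add_site("site", "iSTOP", "+", k, codons[k],
             cbe_stop_routes(codons[k])[[1]]$product, 1L,
             3L * k - 7L, "C at protospacer position 6")
  } else if (feature == "istop_tgg") {
    k <- pick_k(8L, n - 4L)
    codons[k] <- "TGG"
    codons[k - 5L] <- sample(CCN_CODONS, 1L)
    protect(3L * k - 19L, 3L * k + 18L)
    add_site("site", "iSTOP", "-", k, "TGG", "TAG", 1L,
             3L * k + 5L, "template C at protospacer position 7")
  } else if (feature == "isilence") {
    codons[6] <- "AAG"                  # CDS 18 = G
    codons[7] <- "GGA"                  # CDS 19 = G -> PAM NGG at CDS 17-19
    protect(1L, 25L)
    add_site("site", "iSilence", "+", 1L, "ATG", "GTG", 1L,
             -3L, "start-codon A at protospacer position 5; proto_cds in exon1-array units")
  } else if (feature == "decoy_window") {
    k <- pick_k(11L, n - 4L)
    codons[k] <- sample(setdiff(sense_codons(), c("ATG", NGG_CODONS)), 1L)
    codons[k - 1L] <- sample(NGG_CODONS, 1L)
    mp <- min_plan(codons[k])
    protect(3L * k - 27L, 3L * k + 2L)
    add_site("decoy_window", "PE", "+", k, codons[k], mp$product, mp$n_subs,
             3L * k - 25L, "codon at +7..+9: outside (1,6), inside (1,9)")
  } else if (feature == "decoy_frame") {
    k <- pick_k(6L, n - 9L)
    codons[k] <- "TAC"                  # ends in C
    codons[k + 1L] <- "AGA"             # => out-of-frame CAG at CDS 3k..3k+2
    codons[k + 6L] <- "GGA"             # PAM GG at CDS 3k+16, 3k+17
    protect(3L * k - 8L, 3L * k + 18L)
    add_site("decoy_frame", "iSTOP", "+", k, "CAG", "TAG", 1L,
             3L * k - 5L, "CAG out of frame; must not be reported")
  } else if (feature == "variant") {
    stopifnot(n >= 120L)
    kA <- 20L; kB <- 45L; kC <- 80L; kD <- 105L; kE <- 112L
    codons[kA] <- "CAA"
    codons[kA + 1L] <- sample(NGG_CODONS, 1L)   # PE: variant at +1
    codons[kA + 5L] <- sample(NGG_CODONS, 1L)   # iSTOP: C at position 6
    codons[kB] <- "AAG"
    codons[kB + 1L] <- sample(NGG_CODONS, 1L)
    codons[(kC - 13L):(kC + 13L)] <- sample(AT_SENSE_CODONS, 27L, replace = TRUE)
    codons[kC] <- "CAA"                         # lone C in a PAM desert
    codons[kD] <- "GCT"
    add_var <- function(off, ref, alt, consequence, class, kind) {
      variants[[length(variants) + 1L]] <<- data.frame(
        gene_id = gene_id, transcript_id = tx_id, cds_offset = off,
        ref_cds = ref, alt_cds = alt, consequence = consequence,
        expected_class = class, kind = kind, stringsAsFactors = FALSE
      )
    }
    add_var(3L * kA - 2L, "C", "T", "nonsense", "PE_and_iSTOP", "planted")
    add_var(3L * kB - 2L, "A", "T", "nonsense", "PE_only", "planted")
    add_var(3L * kC - 2L, "C", "T", "nonsense", "neither", "planted")
    add_var(3L * kD - 2L, "G", "A", "missense", NA_character_, "decoy_consequence")
    # deliberate reference mismatch: claim the complementary base
    add_var(3L * kE - 2L, complement(substr(codons[kE], 1L, 1L)), "T",
            "nonsense", NA_character_, "decoy_ref_mismatch")
    protect(1L, L - 1L)                 # single-exon gene anyway
  }

  list(
    feature = feature, gene_id = gene_id, tx_id = tx_id,
    codons = codons, n_codons = n, L = L,
    truth = truth, variants = variants,
    protected = protected, forced_junction = forced_junction,
    n_ex = if (feature == "variant") 1L
           else if (feature == "decoy_junction") max(2L, n_ex)
           else n_ex,
    utr5 = 30L, utr3 = 20L, gc = gc
  )
}

choose_junctions <- function(gp) {
  L <- gp$L
  n_cuts <- gp$n_ex - 1L
  if (n_cuts <= 0L) return(integer(0))
  forbidden <- function(j) {
    any(vapply(gp$protected, function(r) j >= r[1] && j <= r[2], logical(1)))
  }
  picked <- integer(0)
  if (!is.na(gp$forced_junction)) {
    picked <- gp$forced_junction
    n_cuts <- n_cuts - 1L
  }
  pool <- setdiff(25L:(L - 25L), unlist(lapply(gp$protected, function(r) r[1]:r[2])))
  while (n_cuts > 0L && length(pool)) {
    j <- pool[sample.int(length(pool), 1L)]
    if (all(abs(j - picked) >= 20L)) {
      picked <- c(picked, j)
      n_cuts <- n_cuts - 1L
    }
    pool <- setdiff(pool, j)
  }
  sort(picked)
}

# assemble one gene region in transcript orientation plus coordinate maps
assemble_gene_region <- function(gp) {
  cds <- paste(gp$codons, collapse = "")
  J <- choose_junctions(gp)
  bounds <- c(0L, J, gp$L)
  chunks <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- if (length(chunks) > 1L) {
    vapply(seq_len(length(chunks) - 1L), function(i) random_intron(gp$gc),
           character(1))
  } else character(0)
  utr5 <- random_bases(gp$utr5, gp$gc)
  utr3 <- random_bases(gp$utr3, gp$gc)

  region <- utr5
  exon_t <- list()
  cds_t <- list()
  pos <- nchar(utr5)
  cum_introns <- 0L
  for (i in seq_along(chunks)) {
    cds_start_t <- pos + 1L
    region <- paste0(region, chunks[i])
    pos <- pos + nchar(chunks[i])
    cds_t[[i]] <- c(cds_start_t, pos)
    ex_start <- if (i == 1L) 1L else cds_start_t
    ex_end <- if (i == length(chunks)) pos + gp$utr3 else pos
    exon_t[[i]] <- c(ex_start, ex_end)
    if (i < length(chunks)) {
      region <- paste0(region, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  region <- paste0(region, utr3)

  # CDS offset -> transcript coordinate
  intron_lens <- nchar(introns)
  t_of_cds <- function(o) {
    ci <- findInterval(o - 0.5, bounds)   # chunk index
    gp$utr5 + o + if (ci > 1L) sum(intron_lens[seq_len(ci - 1L)]) else 0L
  }
  list(region = region, exon_t = exon_t, cds_t = cds_t,
       junctions = J, t_of_cds = t_of_cds, M = nchar(region))
}

#' Generate a synthetic annotated genome with planted editor sites
#'
#' Builds a small multi-contig genome whose genes each carry one planted
#' feature: a prime-editing stop site on the coding or template strand, an
#' iSTOP site (CAG/CAA/CGA or TGG class), an i-Silence start-codon site, a
#' decoy (out-of-frame codon, out-of-window codon, or junction-split
#' protospacer), or a set of variant loci with known targetability
#' classes.  A pseudogene is appended to exercise the biotype filter.
#' Regeneration with the same seed and configuration is byte-identical.
#'
#' @param seed Integer seed governing every random choice.
#' @param features Character vector, one planted feature per gene, from
#'   `pe_plus`, `pe_minus`, `istop_cag`, `istop_tgg`, `isilence`,
#'   `decoy_window`, `decoy_frame`, `decoy_junction`, `variant`.
#' @param exons_per_gene Integer vector cycled over genes for exon counts.
#' @param include_pseudogene Append a pseudogene record (default TRUE).
#' @param gc Background GC content for non-coding sequence (default 0.45).
#' @param intergenic Spacer between genes in bp (default 250).
#' @return List of class `fixture_genome`: `genome` (DNAStringSet),
#'   `transcripts`, `truth` (`sites`, `variants` data frames), `gff`
#'   (annotation rows), `manifest`.
#' @export
make_genome <- function(seed,
                        features = c("pe_plus", "pe_minus", "istop_cag",
                                     "istop_tgg", "isilence", "decoy_window",
                                     "decoy_frame", "decoy_junction"),
                        exons_per_gene = c(1L, 3L, 2L),
                        include_pseudogene = TRUE,
                        gc = 0.45, intergenic = 250L) {
  with_seed(seed, {
    n_genes <- length(features)
    plans <- lapply(seq_len(n_genes), function(i) {
      plan_fixture_gene(
        features[i], sprintf("gene%02d", i), sprintf("tx%02d", i),
        exons_per_gene[((i - 1L) %% length(exons_per_gene)) + 1L], gc
      )
    })

    n_contigs <- if (n_genes > 4L) 2L else 1L
    contig_of <- rep(seq_len(n_contigs), length.out = n_genes)
    contig_names <- sprintf("chr%d", seq_len(n_contigs))
    contig_seqs <- stats::setNames(rep("", n_contigs), contig_names)

    transcripts <- list()
    gff <- list()
    truth_sites <- list()
    truth_variants <- list()

    for (i in seq_len(n_genes)) {
      gp <- plans[[i]]
      asm <- assemble_gene_region(gp)
      strand <- if (gp$feature == "variant") "+" else c("+", "-")[(i %% 2L) + 1L]
      cn <- contig_names[contig_of[i]]
      contig_seqs[cn] <- paste0(contig_seqs[cn], random_bases(intergenic, gc))
      R <- nchar(contig_seqs[cn]) + 1L
      region_g <- if (strand == "+") asm$region else revcomp(asm$region)
      contig_seqs[cn] <- paste0(contig_seqs[cn], region_g)

      g_of_t <- function(t) {
        if (strand == "+") R - 1L + t else R - 1L + (asm$M + 1L - t)
      }
      iv <- function(tt) {
        g <- sort(c(g_of_t(tt[1]), g_of_t(tt[2])))
        data.frame(start = g[1], end = g[2])
      }
      exons <- do.call(rbind, lapply(asm$exon_t, iv))
      cdss <- do.call(rbind, lapply(asm$cds_t, iv))
      tx <- transcript_model(gp$tx_id, gp$gene_id, cn, strand, exons, cdss)
      transcripts[[gp$tx_id]] <- tx

      gff[[length(gff) + 1L]] <- fixture_gff_rows(gp, tx)

      for (tr in gp$truth) {
        # proto_cds: CDS offset of protospacer position 1 (for the
        # i-Silence site it is stored in exon-1-array units, i.e. relative
        # to the transcript start, which equals t directly)
        t_anchor <- if (tr$editor == "iSilence") {
          gp$utr5 + tr$proto_cds            # array units: t = utr5 - 3
        } else {
          asm$t_of_cds(tr$proto_cds)
        }
        tr$proto_g1 <- g_of_t(t_anchor)
        truth_sites[[length(truth_sites) + 1L]] <- tr
      }
      for (vr in gp$variants) {
        t <- asm$t_of_cds(vr$cds_offset)
        g <- g_of_t(t)
        # variant gene is forced to the plus strand: genomic == CDS bases
        truth_variants[[length(truth_variants) + 1L]] <- data.frame(
          contig = cn, pos = g, ref = vr$ref_cds, alt = vr$alt_cds,
          gene = vr$gene_id, consequence = vr$consequence,
          expected_class = vr$expected_class, kind = vr$kind,
          stringsAsFactors = FALSE
        )
      }
    }

    if (include_pseudogene) {
      cn <- contig_names[1]
      contig_seqs[cn] <- paste0(contig_seqs[cn], random_bases(intergenic, gc))
      R <- nchar(contig_seqs[cn]) + 1L
      pseudo <- random_bases(300L, gc)
      contig_seqs[cn] <- paste0(contig_seqs[cn], pseudo)
      gff[[length(gff) + 1L]] <- data.frame(
        seqid = cn, source = "pegstop", type = "gene",
        start = R, end = R + 299L, score = ".", strand = "+", phase = ".",
        attributes = "ID=pseudo1;gene_biotype=pseudogene",
        stringsAsFactors = FALSE
      )
    }
    for (cn in contig_names) {
      contig_seqs[cn] <- paste0(contig_seqs[cn], random_bases(intergenic, gc))
    }

    genome <- Biostrings::DNAStringSet(contig_seqs)
    truth_sites <- if (length(truth_sites)) {
      do.call(rbind, c(truth_sites, list(make.row.names = FALSE)))
    } else data.frame()
    truth_variants <- if (length(truth_variants)) {
      do.call(rbind, c(truth_variants, list(make.row.names = FALSE)))
    } else data.frame()

    structure(
      list(
        genome = genome,
        transcripts = transcripts,
        truth = list(sites = truth_sites, variants = truth_variants),
        gff = do.call(rbind, c(gff, list(make.row.names = FALSE))),
        manifest = list(seed = seed, features = features,
                        exons_per_gene = exons_per_gene,
                        include_pseudogene = include_pseudogene,
                        gc = gc, intergenic = intergenic)
      ),
      class = "fixture_genome"
    )
  })
}

fixture_gff_rows <- function(gp, tx) {
  g_attr <- sprintf("ID=%s;gene_biotype=protein_coding", gp$gene_id)
  m_attr <- sprintf("ID=%s;Parent=%s", gp$tx_id, gp$gene_id)
  span <- range(c(tx$exons$start, tx$exons$end))
  rows <- list(
    data.frame(seqid = tx$contig, source = "pegstop", type = "gene",
               start = span[1], end = span[2], score = ".",
               strand = tx$strand, phase = ".", attributes = g_attr,
               stringsAsFactors = FALSE),
    data.frame(seqid = tx$contig, source = "pegstop", type = "mRNA",
               start = span[1], end = span[2], score = ".",
               strand = tx$strand, phase = ".", attributes = m_attr,
               stringsAsFactors = FALSE)
  )
  for (i in seq_len(nrow(tx$exons))) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = tx$contig, source = "pegstop", type = "exon",
      start = tx$exons$start[i], end = tx$exons$end[i], score = ".",
      strand = tx$strand, phase = ".",
      attributes = sprintf("ID=%s.e%d;Parent=%s", gp$tx_id, i, gp$tx_id),
      stringsAsFactors = FALSE
    )
  }
  phase <- 0L
  for (i in seq_len(nrow(tx$cds))) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = tx$contig, source = "pegstop", type = "CDS",
      start = tx$cds$start[i], end = tx$cds$end[i], score = ".",
      strand = tx$strand, phase = as.character(phase),
      attributes = sprintf("ID=%s.c%d;Parent=%s", gp$tx_id, i, gp$tx_id),
      stringsAsFactors = FALSE
    )
    phase <- (3L - ((tx$cds$end[i] - tx$cds$start[i] + 1L - phase) %% 3L)) %% 3L
  }
  do.call(rbind, rows)
}

#' Write a fixture genome to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `truth_sites.tsv`,
#' `truth_variants.tsv` and `manifest.json` into `dir`.  Output is
#' byte-deterministic for a given fixture.
#'
#' @param fx A [make_genome()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "fixture_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(fx$genome, file.path(dir, "genome.fa"))
  con <- file(file.path(dir, "annotation.gff3"), "w")
  writeLines("##gff-version 3", con)
  utils::write.table(fx$gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(fx$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth$variants, file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fx$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Build a variant table from a fixture's planted variant loci
#'
#' Returns the planted nonsense/missense/mismatch records in the minimal
#' variant-table layout plus `n_decoys` additional random non-nonsense
#' records drawn from the genome.
#'
#' @param fx A [make_genome()] result whose features include `"variant"`.
#' @param n_decoys Extra random missense decoy rows (default 2).
#' @param seed Seed for the decoy draw.
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`; the expected classification is attached as attribute
#'   `"expected"`.
#' @export
make_variant_table <- function(fx, n_decoys = 2, seed = 1) {
  stopifnot(inherits(fx, "fixture_genome"))
  tv <- fx$truth$variants
  if (!nrow(tv)) stop("fixture has no planted variant loci; include the 'variant' feature")
  out <- tv[, c("contig", "pos", "ref", "alt", "gene", "consequence")]
  with_seed(seed, {
    for (i in seq_len(n_decoys)) {
      cn <- sample(names(fx$genome), 1L)
      cs <- as.character(fx$genome[[cn]])
      p <- sample(seq(50L, nchar(cs) - 50L), 1L)
      ref <- substr(cs, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      out <- rbind(out, data.frame(
        contig = cn, pos = p, ref = ref, alt = alt, gene = "random",
        consequence = "missense", stringsAsFactors = FALSE
      ))
    }
  })
  rownames(out) <- NULL
  attr(out, "expected") <- tv
  out
}
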