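# Genome + annotation model: transcript models, spliced CDS maps with
# bidirectional genomic<->CDS coordinate lookup, exon numbering relative to
# the start-codon exon, and a six-frame ORF finder.
#
# Coordinates are 1-based inclusive genomic throughout (GFF3/browser
# convention).  Exons and CDS intervals are stored ordered 5'->3' in
# transcript orientation, i.e. descending genomic start for "-" strand.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Data frames with `start`/`end` columns (1-based
#'   inclusive genomic); any row order is accepted and rows are sorted into
#'   transcript (5'->3') orientation.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  ord <- function(df) {
    df <- df[order(df$start), c("start", "end"), drop = FALSE]
    if (strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  exons <- ord(as.data.frame(exons))
  cds <- ord(as.data.frame(cds))
  if (!nrow(cds) || sum(cds$end - cds$start + 1L) <= 0L) {
    stop("transcript ", transcript_id, " has no CDS")
  }
  st <- sort(exons$start)
  en <- sort(exons$end)
  if (any(st[-1] <= en[-length(en)])) {
    stop("exons of ", transcript_id, " overlap")
  }
  for (i in seq_len(nrow(cds))) {
    if (!any(exons$start <= cds$start[i] & exons$end >= cds$end[i])) {
      stop("CDS interval outside exons in ", transcript_id)
    }
  }
  structure(
    list(
      transcript_id = transcript_id, gene_id = gene_id,
      contig = contig, strand = strand,
      exons = exons, cds = cds, n_exons = nrow(exons)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (gene %s) %s:%s, %d exon(s), CDS %d bp\n",
    x$transcript_id, x$gene_id, x$contig, x$strand,
    x$n_exons, sum(x$cds$end - x$cds$start + 1L)
  ))
  invisible(x)
}

# genomic position of the first CDS base (the start-codon A)
start_codon_pos <- function(tx) {
  if (tx$strand == "+") tx$cds$start[1] else tx$cds$end[1]
}

#' Load a genome and its protein-coding transcript models
#'
#' Reads a FASTA genome and a GFF3 annotation (gene/mRNA/exon/CDS features
#' with Parent links) and returns the genome plus one
#' [transcript_model()] per protein-coding mRNA.  Genes whose
#' `gene_biotype` is not `protein_coding` (e.g. pseudogenes) and non-mRNA
#' transcripts are dropped.  CDS features whose Parent is not a known mRNA
#' are skipped with a warning; a GFF contig absent from the FASTA is an
#' error.
#'
#' @param fasta_path Path to the genome FASTA (gzip accepted).
#' @param gff_path Path to the GFF3 annotation (gzip accepted).
#' @return A list with elements `genome` (named `DNAStringSet`) and
#'   `transcripts` (named list of `transcript_model`).
#' @export
load_annotated_genome <- function(fasta_path, gff_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*", "", names(genome))
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))

  missing_contigs <- setdiff(unique(df$seqnames), names(genome))
  if (length(missing_contigs)) {
    stop("annotation contig(s) absent from FASTA: ",
         paste(missing_contigs, collapse = ", "))
  }

  is_gene <- df$type %in% c("gene", "pseudogene")
  genes <- df[is_gene, , drop = FALSE]
  biotype <- if ("gene_biotype" %in% names(genes)) {
    as.character(genes$gene_biotype)
  } else {
    rep(NA_character_, nrow(genes))
  }
  coding_gene_ids <- genes$ID[genes$type == "gene" &
                                (is.na(biotype) | biotype == "protein_coding")]

  mrna <- df[df$type %in% c("mRNA", "transcript") & df$Parent %in% coding_gene_ids, ,
             drop = FALSE]
  mrna_ids <- mrna$ID

  cds <- df[df$type == "CDS", , drop = FALSE]
  orphan <- !(cds$Parent %in% mrna_ids)
  # orphans are either CDS of dropped (non-coding) genes, or truly unparented
  truly_unparented <- orphan & (is.na(cds$Parent) |
                                  !cds$Parent %in% df$ID[df$type %in% c("mRNA", "transcript")])
  if (any(truly_unparented)) {
    warning(sum(truly_unparented), " CDS feature(s) without a parent mRNA skipped")
  }
  cds <- cds[!orphan, , drop = FALSE]
  exon <- df[df$type == "exon" & df$Parent %in% mrna_ids, , drop = FALSE]

  txs <- list()
  for (i in seq_len(nrow(mrna))) {
    id <- mrna$ID[i]
    e <- exon[exon$Parent == id, c("start", "end"), drop = FALSE]
    k <- cds[cds$Parent == id, c("start", "end"), drop = FALSE]
    if (!nrow(k)) next
    if (!nrow(e)) e <- k
    txs[[id]] <- transcript_model(
      transcript_id = id, gene_id = mrna$Parent[i],
      contig = mrna$seqnames[i], strand = mrna$strand[i],
      exons = e, cds = k
    )
  }
  list(genome = genome, transcripts = txs)
}

#' Build the spliced CDS map of a transcript
#'
#' Splices the CDS intervals into a coding-strand sequence and records, per
#' CDS base, its genomic coordinate, its exon number (the start-codon exon
#' is exon 1) and the set of exon-junction offsets.  A junction offset `j`
#' means a splice junction lies between CDS bases `j` and `j+1`.  A CDS
#' whose length is not a multiple of 3 is trimmed at the 3' end with a
#' warning (annotation-noise tolerance).
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param tx A [transcript_model()].
#' @return An object of class `cds_map` with fields `seq`, `gpos`,
#'   `junctions`, `exon_of`, `contig`, `strand`, `transcript_id`,
#'   `gene_id`, `n_exons`, `low_confidence_start`.
#' @export
build_cds_map <- function(genome, tx) {
  cseq <- contig_seq(genome, tx$contig)
  chunks <- character(nrow(tx$cds))
  gpos <- vector("list", nrow(tx$cds))
  exon_idx <- integer(nrow(tx$cds))
  for (i in seq_len(nrow(tx$cds))) {
    s <- tx$cds$start[i]; e <- tx$cds$end[i]
    piece <- substr(cseq, s, e)
    if (tx$strand == "+") {
      chunks[i] <- piece
      gpos[[i]] <- s:e
    } else {
      chunks[i] <- revcomp(piece)
      gpos[[i]] <- e:s
    }
    exon_idx[i] <- which(tx$exons$start <= s & tx$exons$end >= e)[1]
  }
  seq <- paste(chunks, collapse = "")
  gpos <- unlist(gpos)
  lens <- nchar(chunks)
  junctions <- if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer(0)
  exon_rel <- exon_idx - exon_idx[1] + 1L
  exon_of <- rep(exon_rel, lens)

  L <- nchar(seq)
  if (L %% 3L != 0L) {
    warning("CDS length of ", tx$transcript_id, " (", L,
            ") not a multiple of 3; trailing ", L %% 3L, " base(s) trimmed")
    L <- L - L %% 3L
    seq <- substr(seq, 1, L)
    gpos <- gpos[seq_len(L)]
    exon_of <- exon_of[seq_len(L)]
    junctions <- junctions[junctions < L]
  }
  if (L < 3L) stop("CDS of ", tx$transcript_id, " shorter than one codon after trimming")
  structure(
    list(
      seq = seq, gpos = gpos, junctions = as.integer(junctions),
      exon_of = exon_of, contig = tx$contig, strand = tx$strand,
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      n_exons = tx$n_exons,
      low_confidence_start = substr(seq, 1, 3) != "ATG"
    ),
    class = "cds_map"
  )
}

#' @export
print.cds_map <- function(x, ...) {
  cat(sprintf(
    "<cds_map> %s %s:%s, %d bp CDS, %d junction(s)%s\n",
    x$transcript_id, x$contig, x$strand, nchar(x$seq), length(x$junctions),
    if (x$low_confidence_start) " [no annotated ATG start]" else ""
  ))
  invisible(x)
}

#' Genomic coordinate of a CDS offset, and back
#'
#' The two lookups are mutually inverse bijections over the CDS.
#'
#' @param map A [build_cds_map()] result.
#' @param i CDS offset(s), 1-based from the start-codon A.
#' @param gpos Genomic coordinate(s).
#' @return Integer vector (NA where a genomic position is not in the CDS).
#' @export
cds_to_genomic <- function(map, i) map$gpos[i]

#' @rdname cds_to_genomic
#' @export
genomic_to_cds <- function(map, gpos) match(gpos, map$gpos)

#' Number of "early" exons of a transcript
#'
#' Early exons are exons 1 to ceiling(E/5), where E is the transcript's
#' total exon count and exon 1 is the exon harbouring the start codon.
#'
#' @param tx A [transcript_model()] (or anything with an `n_exons` field).
#' @return Integer count, at least 1.
#' @export
#' @examples
#' early_exon_count(list(n_exons = 10))  # 2
early_exon_count <- function(tx) {
  e <- tx$n_exons
  stopifnot(is.numeric(e), e >= 1)
  as.integer(ceiling(e / 5))
}

#' Find open reading frames in a nucleotide sequence
#'
#' Scans all six reading frames for ORFs that start at ATG and end at the
#' first in-frame stop codon (stop included in the reported span).  By
#' default only the longest ORF per stop codon is reported (the 5'-most
#' ATG after the previous in-frame stop).
#'
#' @param seq Character scalar or `DNAString`.
#' @param min_len Minimum ORF length in nt (>= 3, divisible by 3);
#'   default 75, the conventional short-ORF cutoff.
#' @param contig Contig label for the output.
#' @param both_strands Scan the reverse complement as well.
#' @param longest_only Report only the longest ORF per stop codon.
#' @return Data frame with columns `contig`, `strand`, `start`, `end`,
#'   `length`, `seq` (coordinates on the input sequence, 1-based; `seq` is
#'   reported in reading orientation).
#' @export
find_orfs <- function(seq, min_len = 75, contig = "seq",
                      both_strands = TRUE, longest_only = TRUE) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  seq <- toupper(seq)
  min_len <- as.integer(min_len)
  if (min_len < 3L || min_len %% 3L != 0L) {
    stop("min_len must be >= 3 and divisible by 3")
  }
  L <- nchar(seq)
  scan_one <- function(s, strand) {
    out <- list()
    for (f in 0:2) {
      if (L - f < 3L) next
      starts <- seq.int(1L + f, L - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      stop_i <- which(cods %in% STOP_CODONS)
      atg_i <- which(cods == "ATG")
      prev <- 0L
      for (si in stop_i) {
        cand <- atg_i[atg_i > prev & atg_i < si]
        if (length(cand)) {
          picks <- if (longest_only) cand[1] else cand
          for (ci in picks) {
            a <- starts[ci]; b <- starts[si] + 2L
            len <- b - a + 1L
            if (len >= min_len) {
              if (strand == "+") {
                out[[length(out) + 1L]] <- data.frame(
                  contig = contig, strand = "+", start = a, end = b,
                  length = len, seq = substr(s, a, b),
                  stringsAsFactors = FALSE
                )
              } else {
                out[[length(out) + 1L]] <- data.frame(
                  contig = contig, strand = "-", start = L + 1L - b,
                  end = L + 1L - a, length = len, seq = substr(s, a, b),
                  stringsAsFactors = FALSE
                )
              }
            }
          }
        }
        prev <- si
      }
    }
    out
  }
  res <- scan_one(seq, "+")
  if (both_strands) res <- c(res, scan_one(revcomp(seq), "-"))
  if (!length(res)) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wrap ORFs as single-exon transcript models
#'
#' Lets predicted ORFs be scanned with the same machinery as annotated
#' transcripts (each ORF becomes a one-exon, one-CDS transcript).
#'
#' @param orfs A [find_orfs()] result.
#' @param contig Contig name override (defaults to the ORF's own).
#' @return Named list of `transcript_model`.
#' @export
orfs_as_transcripts <- function(orfs, contig = NULL) {
  txs <- list()
  for (i in seq_len(nrow(orfs))) {
    id <- sprintf("orf_%s_%d_%d_%s", orfs$contig[i], orfs$start[i],
                  orfs$end[i], orfs$strand[i])
    iv <- data.frame(start = orfs$start[i], end = orfs$end[i])
    txs[[id]] <- transcript_model(
      transcript_id = id, gene_id = id,
      contig = if (is.null(contig)) orfs$contig[i] else contig,
      strand = orfs$strand[i], exons = iv, cds = iv
    )
  }
  txs
}
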