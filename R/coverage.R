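# Targetability aggregation (gene/transcript/exon/early-exon/ORF) and
# variant-table classification.

#' Aggregate hits into a targetability report
#'
#' A record is targetable by an editor iff at least one of that editor's
#' hits falls in it.  Levels: `gene`, `transcript` (one record per
#' transcript), `exon` (one record per coding exon of each transcript),
#' `early_exon` (coding exons numbered 1..ceiling(E/5), exon 1 being the
#' start-codon exon), `orf` (transcript-level over ORF-derived transcript
#' models, see [orfs_as_transcripts()]).  Duplicate hits on the same codon
#' from different PAMs count once: records, not hits, are deduplicated.
#'
#' @param hits A scanner result (rows from one or more editors).
#' @param genome,transcripts The inputs the hits were computed over.
#' @param level One of `"gene"`, `"transcript"`, `"exon"`, `"early_exon"`,
#'   `"orf"`.
#' @param editors Editors to tabulate; defaults to those present plus any
#'   requested via this argument.
#' @return Data frame with columns `level`, `editor`, `targetable`,
#'   `total`, `percent`; the per-record truth table is attached as
#'   attribute `"records"`.
#' @export
coverage_report <- function(hits, genome, transcripts,
                            level = c("gene", "transcript", "exon",
                                      "early_exon", "orf"),
                            editors = NULL) {
  level <- match.arg(level)
  transcripts <- as_transcript_list(transcripts)
  if (is.null(editors)) {
    editors <- unique(hits$editor)
    if (!length(editors)) editors <- "PE"
  }

  if (level %in% c("gene", "transcript", "orf")) {
    if (level == "gene") {
      rec_of_tx <- vapply(transcripts, function(tx) tx$gene_id, character(1))
    } else {
      rec_of_tx <- vapply(transcripts, function(tx) tx$transcript_id, character(1))
    }
    records <- unique(unname(rec_of_tx))
    hit_rec <- rec_of_tx[match(hits$transcript_id,
                               vapply(transcripts, `[[`, character(1),
                                      "transcript_id"))]
    truth <- data.frame(record = records, stringsAsFactors = FALSE)
    for (ed in editors) {
      truth[[ed]] <- records %in% unique(hit_rec[hits$editor == ed])
    }
  } else {
    recs <- list()
    for (tx in transcripts) {
      map <- suppressWarnings(build_cds_map(genome, tx))
      ex <- sort(unique(map$exon_of))
      if (level == "early_exon") ex <- ex[ex <= early_exon_count(tx)]
      if (length(ex)) {
        recs[[tx$transcript_id]] <- data.frame(
          transcript_id = tx$transcript_id, exon = ex,
          record = paste0(tx$transcript_id, ":exon", ex),
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- if (length(recs)) {
      do.call(rbind, c(recs, list(make.row.names = FALSE)))
    } else {
      data.frame(transcript_id = character(), exon = integer(),
                 record = character(), stringsAsFactors = FALSE)
    }
    key_hits <- paste0(hits$transcript_id, ":exon", hits$exon)
    for (ed in editors) {
      truth[[ed]] <- truth$record %in% key_hits[hits$editor == ed]
    }
    truth <- truth[, c("record", editors), drop = FALSE]
  }

  out <- do.call(rbind, lapply(editors, function(ed) {
    data.frame(
      level = level, editor = ed,
      targetable = sum(truth[[ed]]), total = nrow(truth),
      percent = if (nrow(truth)) 100 * sum(truth[[ed]]) / nrow(truth) else 0,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "records") <- truth
  out
}

#' Read a minimal variant table
#'
#' Expects tab-separated columns `contig`, `pos`, `ref`, `alt`, `gene`,
#' `consequence` (extra columns pass through).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "gene", "consequence")
  if (!all(need %in% names(df))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Map a ClinVar-style variant_summary extract onto the minimal table
#'
#' Column-name adapter so ClinVar `variant_summary.txt` extracts (one
#' assembly's rows) can be classified without re-shaping by hand.
#' Nonsense status is taken from a `consequence`-like column if present,
#' else from `Type`/`Name` heuristics are NOT attempted: rows without a
#' recognisable consequence column are rejected.
#'
#' @param df Data frame with ClinVar-style columns.
#' @param columns Named character vector mapping the minimal names to the
#'   input's column names.
#' @return Data frame with the minimal columns.
#' @export
as_variant_table <- function(df,
                             columns = c(contig = "Chromosome",
                                         pos = "PositionVCF",
                                         ref = "ReferenceAlleleVCF",
                                         alt = "AlternateAlleleVCF",
                                         gene = "GeneSymbol",
                                         consequence = "consequence")) {
  missing <- setdiff(unname(columns), names(df))
  if (length(missing)) {
    stop("input lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    contig = as.character(df[[columns[["contig"]]]]),
    pos = as.integer(df[[columns[["pos"]]]]),
    ref = toupper(as.character(df[[columns[["ref"]]]])),
    alt = toupper(as.character(df[[columns[["alt"]]]])),
    gene = as.character(df[[columns[["gene"]]]]),
    consequence = as.character(df[[columns[["consequence"]]]]),
    stringsAsFactors = FALSE
  )
  out
}

# does any NGG protospacer on `strand` of `cseq` place plus-coordinate
# `x` at +w1..+w2 of its nick?
pe_reachable_at <- function(cseq, x, window) {
  L <- nchar(cseq)
  for (n in window[1]:window[2]) {
    # plus strand: +1 base at plus coord c; x at +n => c = x-n+1;
    # PAM at +4..+6 => plus coords c+3..c+5, GG at c+4, c+5
    c0 <- x - n + 1L
    s <- c0 - 17L
    if (s >= 1L && c0 + 5L <= L &&
        substr(cseq, c0 + 4L, c0 + 5L) == "GG") return(TRUE)
    # minus strand: +1 base at plus coord c; x at +n => c = x+n-1;
    # PAM GG at plus coords c-4, c-5 as C,C on plus (reading CC leftwards)
    c0 <- x + n - 1L
    if (c0 + 17L <= L && c0 - 5L >= 1L &&
        substr(cseq, c0 - 5L, c0 - 4L) == "CC") return(TRUE)
  }
  FALSE
}

# does any NGG protospacer place `x` (which reads C on `which` strand)
# at protospacer positions 4..8?
istop_reachable_at <- function(cseq, x, c_on = c("+", "-"), be_window = BE_WINDOW) {
  L <- nchar(cseq)
  for (q in be_window[1]:be_window[2]) {
    if (c_on == "+") {
      s <- x - q + 1L                   # plus-strand protospacer start
      if (s >= 1L && s + 22L <= L &&
          substr(cseq, s + 21L, s + 22L) == "GG") return(TRUE)
    } else {
      a <- x + q - 1L                   # minus protospacer pos-1 plus coord
      if (a <= L && a - 22L >= 1L &&
          substr(cseq, a - 22L, a - 21L) == "CC") return(TRUE)
    }
  }
  FALSE
}

#' Classify nonsense variants for editor targetability
#'
#' Applies the nonsense-SNV filter (consequence equals `"nonsense"`,
#' single-base ref/alt, uniqueness by gene + location), checks the
#' reference base against the genome (mismatches are flagged and excluded
#' from denominators), and classifies the survivors:
#' PE-targetable iff some NGG protospacer on either strand places the
#' variant base within `pe_window` (+1..+9 by default) of the nick;
#' iSTOP-targetable iff the record is a C-to-T (or G-to-A) change whose C
#' sits at protospacer positions 4-8 of a suitable NGG protospacer.
#'
#' @param variants Data frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`.
#' @param genome Named character vector or `DNAStringSet`.
#' @param pe_window Nick-relative window for the prime editor,
#'   default `c(1, 9)`.
#' @param flank Flanking context (bp) that must be available around a
#'   variant; classification only inspects this window.
#' @return The input with added columns `status`
#'   (`classified` / `filtered_consequence` / `filtered_multibase` /
#'   `duplicate` / `ref_mismatch`), `pe`, `istop` (logicals, NA when not
#'   classified) and `class` (`PE_and_iSTOP`, `PE_only`, `iSTOP_only`,
#'   `neither`, or NA).
#' @export
variant_targetability <- function(variants, genome, pe_window = c(1, 9),
                                  flank = 100) {
  pe_window <- check_window(pe_window)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  n <- nrow(v)
  v$status <- "classified"
  v$pe <- NA
  v$istop <- NA
  v$class <- NA_character_

  single <- nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt
  v$status[!single] <- "filtered_multibase"
  nons <- tolower(v$consequence) == "nonsense"
  v$status[single & !nons] <- "filtered_consequence"
  key <- paste(v$gene, v$contig, v$pos, sep = "|")
  dup <- duplicated(key)
  v$status[single & nons & dup] <- "duplicate"

  for (i in which(v$status == "classified")) {
    cseq <- contig_seq(genome, v$contig[i])
    x <- as.integer(v$pos[i])
    if (x < 1L || x > nchar(cseq) ||
        substr(cseq, x, x) != toupper(v$ref[i])) {
      v$status[i] <- "ref_mismatch"
      next
    }
    lo <- max(1L, x - as.integer(flank))
    hi <- min(nchar(cseq), x + as.integer(flank))
    local <- substr(cseq, lo, hi)
    xl <- x - lo + 1L
    v$pe[i] <- pe_reachable_at(local, xl, pe_window)
    v$istop[i] <- if (v$ref[i] == "C" && v$alt[i] == "T") {
      istop_reachable_at(local, xl, "+")
    } else if (v$ref[i] == "G" && v$alt[i] == "A") {
      istop_reachable_at(local, xl, "-")
    } else FALSE
    v$class[i] <- if (v$pe[i] && v$istop[i]) "PE_and_iSTOP"
      else if (v$pe[i]) "PE_only"
      else if (v$istop[i]) "iSTOP_only"
      else "neither"
  }
  v
}

#' Write hits as TSV
#' @param hits Scanner result.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert hits to BED6+ intervals
#'
#' One interval per hit covering the protospacer+PAM footprint; score is
#' the substitution count, strand is the genomic PAM strand, and editor,
#' codon, product and edit plan follow as extra columns.
#'
#' @param hits Scanner result.
#' @return Data frame in BED column order (`start` is 0-based).
#' @export
hits_to_bed <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(), strand = character(),
                      editor = character(), codon = character(),
                      product = character(), edits = character(),
                      stringsAsFactors = FALSE))
  }
  left <- ifelse(hits$g_pam_strand == "+", hits$proto_g1, hits$proto_g1 - 22L)
  data.frame(
    chrom = hits$contig,
    start = left - 1L,
    end = left + 22L,
    name = hits$hit_id,
    score = hits$n_subs,
    strand = hits$g_pam_strand,
    editor = hits$editor,
    codon = hits$codon,
    product = hits$product,
    edits = paste0(hits$edit_offsets, ":", hits$edit_ref, ">", hits$edit_alt),
    stringsAsFactors = FALSE
  )
}
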