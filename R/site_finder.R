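# Editor-specific target-site scanners over spliced CDS arrays.
#
# Geometry recap (all on the PAM-bearing strand of a candidate site):
#   protospacer = positions 1..20, PAM (NGG) = 21..23,
#   nick between positions 17 and 18,
#   "+n" = n-th base 3' of the nick, so +1..+3 are protospacer 18..20 and
#   +4..+6 are the PAM triplet.
#
# Scanning happens on the spliced CDS sequence of each transcript (and its
# reverse complement for template-strand PAMs).  A hit whose
# protospacer+PAM footprint or target codon would straddle an exon-exon
# junction is excluded: such a motif match exists only in the spliced
# array, not in the genome.  Because surviving footprints are junction-free
# their genomic coordinates are contiguous, which is what reagent design
# requires.

PE_WINDOW_DEFAULT <- c(1L, 6L)
PE_WINDOW_VARIANT <- c(1L, 9L)
BE_WINDOW <- c(4L, 8L)

hit_columns <- c(
  "hit_id", "editor", "gene_id", "transcript_id", "contig", "tx_strand",
  "pam_strand", "g_pam_strand", "protospacer", "pam", "proto_g1", "nick_g",
  "codon_index", "codon", "codon_cds_start", "exon", "offset_units",
  "codon_offset", "edit_offsets", "edit_ref", "edit_alt", "n_subs", "product"
)

empty_hits <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(hit_columns)), hit_columns),
    stringsAsFactors = FALSE
  )
  for (col in c("proto_g1", "nick_g", "codon_index", "codon_cds_start",
                "exon", "codon_offset", "n_subs")) {
    df[[col]] <- integer(0)
  }
  df
}

check_window <- function(window) {
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] >= 1L, window[1] <= window[2])
  window
}

# per-strand scan context of one cds_map
strand_context <- function(map, pam_strand) {
  L <- nchar(map$seq)
  if (pam_strand == "+") {
    list(
      sseq = map$seq, jn = map$junctions, L = L,
      to_coding = function(i) i
    )
  } else {
    list(
      sseq = revcomp(map$seq),
      jn = if (length(map$junctions)) sort(L - map$junctions) else integer(0),
      L = L,
      to_coding = function(i) L + 1L - i
    )
  }
}

# protospacer start offsets (scan coordinates) with NGG at 21..23
pam_anchored_starts <- function(sseq, L) {
  ch <- strsplit(sseq, "")[[1]]
  if (L < 23L) return(integer(0))
  gg <- which(ch[-L] == "G" & ch[-1] == "G")
  ss <- gg - 21L
  ss[ss >= 1L & ss + 22L <= L]
}

# genomic PAM strand of a hit
genomic_pam_strand <- function(tx_strand, pam_strand) {
  if (tx_strand == "+") pam_strand else flip_strand(pam_strand)
}

make_hit_row <- function(map, ctx, pam_strand, s, editor, codon_index, codon,
                         cstart, offset_units, codon_offset, offsets, refs,
                         alts, product) {
  g_strand <- genomic_pam_strand(map$strand, pam_strand)
  data.frame(
    hit_id = sprintf("%s|%s|c%d|%s%d", editor, map$transcript_id,
                     codon_index, pam_strand, s),
    editor = editor,
    gene_id = map$gene_id,
    transcript_id = map$transcript_id,
    contig = map$contig,
    tx_strand = map$strand,
    pam_strand = pam_strand,
    g_pam_strand = g_strand,
    protospacer = substr(ctx$sseq, s, s + 19L),
    pam = substr(ctx$sseq, s + 20L, s + 22L),
    proto_g1 = map$gpos[ctx$to_coding(s)],
    nick_g = map$gpos[ctx$to_coding(s + 17L)],
    codon_index = codon_index,
    codon = codon,
    codon_cds_start = cstart,
    exon = map$exon_of[cstart],
    offset_units = offset_units,
    codon_offset = codon_offset,
    edit_offsets = paste_csv(offsets),
    edit_ref = paste_csv(refs),
    edit_alt = paste_csv(alts),
    n_subs = length(offsets),
    product = product,
    stringsAsFactors = FALSE
  )
}

# shared inner loop: enumerate in-frame sense codons whose scan-strand
# footprint is t..t+2, calling `emit(t, cstart, k, codon)`
inframe_codons_in <- function(map, ctx, pam_strand, t_range, emit) {
  for (t in t_range) {
    if (t < 1L || t + 2L > ctx$L) next
    cstart <- if (pam_strand == "+") t else ctx$L - t - 1L
    if (cstart < 1L || cstart %% 3L != 1L) next
    k <- (cstart + 2L) %/% 3L
    if (k == 1L) next                       # initiator codon is not a target
    codon <- substr(map$seq, cstart, cstart + 2L)
    if (codon %in% STOP_CODONS) next        # already a stop (incl. terminal)
    # codon split by a junction (coding-frame offsets)
    if (any(map$junctions %in% c(cstart, cstart + 1L))) next
    emit(t, cstart, k, codon)
  }
}

scan_pe_one <- function(map, window, max_subs, codon_placement) {
  rows <- list()
  for (pam_strand in c("+", "-")) {
    ctx <- strand_context(map, pam_strand)
    for (s in pam_anchored_starts(ctx$sseq, ctx$L)) {
      wl <- s + 16L + window[1]
      wh <- s + 16L + window[2]
      t_range <- if (codon_placement == "whole") {
        if (wh - wl < 2L) integer(0) else wl:(wh - 2L)
      } else {
        (wl - 2L):wh
      }
      inframe_codons_in(map, ctx, pam_strand, t_range, function(t, cstart, k, codon) {
        # the hit's genomic footprint is protospacer+PAM plus this codon:
        # it must fit the array and be junction-free (a wider window never
        # invalidates a hit found under a narrower one)
        span_end <- max(s + 22L, t + 2L)
        if (span_end > ctx$L) return()
        if (any(ctx$jn >= s & ctx$jn <= span_end - 1L)) return()
        plan <- min_plan(codon)
        if (plan$n_subs > max_subs) return()
        # scan-strand offsets of the edited codon positions
        oj <- if (pam_strand == "+") t + plan$positions - 1L else t + 3L - plan$positions
        n_off <- oj - (s + 16L)
        if (codon_placement != "whole" && !all(oj >= wl & oj <= wh)) return()
        ord <- order(n_off)
        refs <- if (pam_strand == "+") plan$from else complement(plan$from)
        alts <- if (pam_strand == "+") plan$to else complement(plan$to)
        rows[[length(rows) + 1L]] <<- make_hit_row(
          map, ctx, pam_strand, s, "PE", k, codon, cstart,
          "nick", t - (s + 16L), n_off[ord], refs[ord], alts[ord], plan$product
        )
      })
    }
  }
  rows
}

scan_istop_one <- function(map, be_window = BE_WINDOW) {
  rows <- list()
  for (pam_strand in c("+", "-")) {
    ctx <- strand_context(map, pam_strand)
    targets <- if (pam_strand == "+") c("CAG", "CAA", "CGA") else "TGG"
    for (s in pam_anchored_starts(ctx$sseq, ctx$L)) {
      if (any(ctx$jn >= s & ctx$jn <= s + 21L)) next
      # codon footprint must start at protospacer positions 4..8
      t_range <- (s + be_window[1] - 1L):(s + be_window[2] - 1L)
      inframe_codons_in(map, ctx, pam_strand, t_range, function(t, cstart, k, codon) {
        if (!codon %in% targets) return()
        routes <- cbe_stop_routes(codon)
        plan <- NULL
        for (r in routes) {
          oj <- if (pam_strand == "+") t + r$positions - 1L else t + 3L - r$positions
          p <- oj - s + 1L            # protospacer positions of the edited Cs
          if (all(p >= be_window[1] & p <= be_window[2])) { plan <- r; break }
        }
        if (is.null(plan)) return()
        oj <- if (pam_strand == "+") t + plan$positions - 1L else t + 3L - plan$positions
        p <- oj - s + 1L
        ord <- order(p)
        refs <- if (pam_strand == "+") plan$from else complement(plan$from)
        alts <- if (pam_strand == "+") plan$to else complement(plan$to)
        rows[[length(rows) + 1L]] <<- make_hit_row(
          map, ctx, pam_strand, s, "iSTOP", k, codon, cstart,
          "protospacer", t - s + 1L, p[ord], refs[ord], alts[ord], plan$product
        )
      })
    }
  }
  rows
}

#' Scan transcripts for prime-editing stop-codon installation sites
#'
#' For every NGG protospacer on either strand of each spliced CDS, reports
#' every in-frame sense codon wholly contained in the nick-relative editing
#' window (default +1..+6) together with its minimal substitution plan.
#' Hits whose protospacer+PAM footprint or target codon spans an exon
#' junction are excluded; the initiator codon and existing stop codons are
#' not targets.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param transcripts List of [transcript_model()] (or a single one).
#' @param window Editing window in +n units, default `c(1, 6)`;
#'   `c(1, 9)` is the relaxed window used for fixed-position variants.
#' @param max_subs Maximum substitutions per codon (1-3).
#' @param codon_placement `"whole"` (default: entire codon inside the
#'   window, matching the fixed-width search motifs) or `"edited_bases"`
#'   (only the substituted bases need to lie in the window).
#' @return Data frame of hits, one row per (protospacer, codon) pair.
#'   `edit_offsets` are +n positions, `edit_ref`/`edit_alt` are bases on
#'   the PAM strand.
#' @export
scan_pe_stops <- function(genome, transcripts, window = c(1, 6), max_subs = 3,
                          codon_placement = c("whole", "edited_bases")) {
  window <- check_window(window)
  codon_placement <- match.arg(codon_placement)
  transcripts <- as_transcript_list(transcripts)
  rows <- list()
  for (tx in transcripts) {
    map <- build_cds_map(genome, tx)
    rows <- c(rows, scan_pe_one(map, window, as.integer(max_subs), codon_placement))
  }
  finish_hits(rows)
}

#' Scan transcripts for iSTOP (CBE) sites
#'
#' Reports in-frame CAG/CAA/CGA codons whose editable C sits at
#' protospacer positions 4-8 of a coding-strand NGG protospacer, and
#' in-frame TGG codons analogously positioned for template-strand C-to-T
#' conversion.  Junction-spanning footprints are excluded.
#'
#' @inheritParams scan_pe_stops
#' @return Data frame of hits; `edit_offsets` are protospacer positions.
#' @export
scan_istop <- function(genome, transcripts) {
  transcripts <- as_transcript_list(transcripts)
  rows <- list()
  for (tx in transcripts) {
    rows <- c(rows, scan_istop_one(build_cds_map(genome, tx)))
  }
  finish_hits(rows)
}

#' Scan transcripts for i-Silence (ABE) start-codon sites
#'
#' Only the annotated start codon is a target and only within the
#' transcript's first exon (the scanned array is the full first-exon
#' sequence, so the protospacer may reach into the 5' UTR).  A hit
#' requires an editable adenine of the start codon -- the coding-strand A
#' of ATG, or the template-strand A opposite its T -- at protospacer
#' positions 4-8 of an NGG protospacer on the corresponding strand.
#'
#' @inheritParams scan_pe_stops
#' @param adenine Which start-codon adenines may be targeted:
#'   `"both"` (default), `"coding"`, or `"template"`.
#' @return Data frame of hits; `edit_offsets` are protospacer positions
#'   and refer to the PAM strand (A>G).
#' @export
scan_isilence <- function(genome, transcripts,
                          adenine = c("both", "coding", "template")) {
  adenine <- match.arg(adenine)
  transcripts <- as_transcript_list(transcripts)
  rows <- list()
  for (tx in transcripts) {
    rows <- c(rows, scan_isilence_one(genome, tx, adenine))
  }
  finish_hits(rows)
}

scan_isilence_one <- function(genome, tx, adenine = "both",
                              be_window = BE_WINDOW) {
  cseq <- contig_seq(genome, tx$contig)
  e1 <- tx$exons[1, ]
  elen <- e1$end - e1$start + 1L
  # first-exon array in coding orientation, with genomic coordinate map
  if (tx$strand == "+") {
    arr <- substr(cseq, e1$start, e1$end)
    gpos <- e1$start:e1$end
  } else {
    arr <- revcomp(substr(cseq, e1$start, e1$end))
    gpos <- e1$end:e1$start
  }
  sc_g <- start_codon_pos(tx)
  m <- match(sc_g, gpos)                 # array offset of the start-codon A
  if (is.na(m) || m + 2L > elen || substr(arr, m, m + 2L) != "ATG") {
    warning("start codon of ", tx$transcript_id,
            " not within its first exon (or not ATG); transcript skipped")
    return(list())
  }
  rows <- list()
  emit <- function(pam_strand, s, p_edit, q_codon, sseq) {
    g_strand <- genomic_pam_strand(tx$strand, pam_strand)
    to_arr <- function(i) if (pam_strand == "+") i else elen + 1L - i
    rows[[length(rows) + 1L]] <<- data.frame(
      hit_id = sprintf("iSilence|%s|start|%s%d", tx$transcript_id, pam_strand, s),
      editor = "iSilence",
      gene_id = tx$gene_id,
      transcript_id = tx$transcript_id,
      contig = tx$contig,
      tx_strand = tx$strand,
      pam_strand = pam_strand,
      g_pam_strand = g_strand,
      protospacer = substr(sseq, s, s + 19L),
      pam = substr(sseq, s + 20L, s + 22L),
      proto_g1 = gpos[to_arr(s)],
      nick_g = gpos[to_arr(s + 17L)],
      codon_index = 1L,
      codon = "ATG",
      codon_cds_start = 1L,
      exon = 1L,
      offset_units = "protospacer",
      codon_offset = q_codon,
      edit_offsets = paste_csv(p_edit),
      edit_ref = "A",
      edit_alt = "G",
      n_subs = 1L,
      product = if (pam_strand == "+") "GTG" else "ACG",
      stringsAsFactors = FALSE
    )
  }
  # coding-strand protospacers: editable A is the A of ATG (array offset m)
  if (adenine %in% c("both", "coding")) {
    ss <- pam_anchored_starts(arr, elen)
    for (s in ss) {
      q <- m - s + 1L
      if (q >= be_window[1] && q <= be_window[2] && m + 2L <= s + 19L) {
        emit("+", s, q, q, arr)
      }
    }
  }
  # template-strand protospacers: editable A is opposite the T (offset m+1)
  if (adenine %in% c("both", "template")) {
    rc_arr <- revcomp(arr)
    ss <- pam_anchored_starts(rc_arr, elen)
    r <- elen - m                       # rc offset of array offset m+1
    for (s in ss) {
      q <- r - s + 1L                   # proto position of the editable A
      # ATG's image (CAT) occupies proto positions q-1 .. q+1
      if (q >= be_window[1] && q <= be_window[2] &&
          (q - 1L) >= 1L && (q + 1L) <= 20L) {
        emit("-", s, q, q - 1L, rc_arr)
      }
    }
  }
  rows
}

as_transcript_list <- function(transcripts) {
  if (inherits(transcripts, "transcript_model")) {
    transcripts <- stats::setNames(list(transcripts), transcripts$transcript_id)
  }
  transcripts
}

finish_hits <- function(rows) {
  if (!length(rows)) return(empty_hits())
  df <- do.call(rbind, rows)
  df <- df[order(df$transcript_id, df$editor, df$pam_strand,
                 df$proto_g1, df$codon_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Check hit-table invariants
#'
#' Re-validates every reported hit against the genome: the PAM ends in GG,
#' the protospacer matches the genome on the PAM strand, the nick is 3 nt
#' upstream of the PAM, the recorded reference bases match the genome and
#' applying the plan yields the recorded product codon.
#'
#' @param hits A scanner result.
#' @param genome The genome it was computed on.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_hits <- function(hits, genome) {
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    cseq <- contig_seq(genome, h$contig)
    proto <- oriented_read(cseq, h$g_pam_strand, h$proto_g1, 20L)
    pam <- oriented_read(cseq, h$g_pam_strand,
                         oriented_shift(h$proto_g1, h$g_pam_strand, 20L), 3L)
    if (proto != h$protospacer) stop("protospacer mismatch in hit ", h$hit_id)
    if (pam != h$pam) stop("PAM mismatch in hit ", h$hit_id)
    if (substr(pam, 2, 3) != "GG") stop("PAM not NGG in hit ", h$hit_id)
    if (oriented_shift(h$proto_g1, h$g_pam_strand, 17L) != h$nick_g) {
      stop("nick not 3 nt upstream of PAM in hit ", h$hit_id)
    }
    if (h$editor == "PE") {
      offs <- split_csv_int(h$edit_offsets)
      refs <- split_csv(h$edit_ref)
      for (j in seq_along(offs)) {
        g <- oriented_shift(h$nick_g, h$g_pam_strand, offs[j] - 1L)
        if (oriented_read(cseq, h$g_pam_strand, g, 1L) != refs[j]) {
          stop("reference base mismatch in hit ", h$hit_id)
        }
      }
    }
  }
  invisible(TRUE)
}
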