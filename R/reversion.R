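# Precise reversion of installed nonsense edits, and rescue-route
# classification for prime-editor vs base-editor primaries.
#
# A prime edit that spares PAM positions +5/+6 (the GG) leaves the same
# protospacer/PAM usable on the mutant allele: the reversion pegRNA reuses
# the (edited) protospacer and templates the reference bases back.  When
# the PAM was destroyed, an alternative NGG placing all edited bases in
# the editing window is searched on the edited allele.

pe_unreachable_error <- function(msg) {
  stop(errorCondition(msg, class = c("pegstop_pe_unreachable", "error")))
}

# all NGG protospacers on `strand` of cseq whose window +w1..+w2 contains
# every plus-coordinate in `targets`; returns list of (g_strand, proto_g1,
# nick_g, max_offset)
find_covering_protospacers <- function(cseq, targets, window) {
  L <- nchar(cseq)
  out <- list()
  # plus strand: target x at +n => nick +1 base c = x - n + 1
  c_lo <- max(targets) - window[2] + 1L
  c_hi <- min(targets) - window[1] + 1L
  if (c_lo <= c_hi) {
    for (c0 in c_lo:c_hi) {
      s <- c0 - 17L
      if (s < 1L || c0 + 5L > L) next
      if (substr(cseq, c0 + 4L, c0 + 5L) != "GG") next
      out[[length(out) + 1L]] <- list(
        g_strand = "+", proto_g1 = s, nick_g = c0,
        max_offset = max(targets) - c0 + 1L
      )
    }
  }
  # minus strand: target x at +n => +1 base plus coord c = x + n - 1
  c_lo <- max(targets) + window[1] - 1L
  c_hi <- min(targets) + window[2] - 1L
  if (c_lo <= c_hi) {
    for (c0 in c_lo:c_hi) {
      if (c0 + 17L > L || c0 - 5L < 1L) next
      if (substr(cseq, c0 - 5L, c0 - 4L) != "CC") next
      out[[length(out) + 1L]] <- list(
        g_strand = "-", proto_g1 = c0 + 17L, nick_g = c0,
        max_offset = c0 - min(targets) + 1L
      )
    }
  }
  out
}

# build a pegRNA directly from locus geometry (no scanner hit needed):
# `edits` is data.frame(offset, ref, alt) in +n units on g_strand
pegrna_from_locus <- function(genome, contig, g_strand, proto_g1, edits,
                              codon_index = NA_integer_, product = NA_character_,
                              transcript_id = NA_character_, ...) {
  cseq <- contig_seq(genome, contig)
  nick_g <- oriented_shift(proto_g1, g_strand, 17L)
  hit <- data.frame(
    hit_id = sprintf("locus|%s|%s%d", contig, g_strand, proto_g1),
    editor = "PE", gene_id = NA_character_, transcript_id = transcript_id,
    contig = contig, tx_strand = NA_character_, pam_strand = NA_character_,
    g_pam_strand = g_strand,
    protospacer = oriented_read(cseq, g_strand, proto_g1, 20L),
    pam = oriented_read(cseq, g_strand, oriented_shift(proto_g1, g_strand, 20L), 3L),
    proto_g1 = proto_g1, nick_g = nick_g,
    codon_index = codon_index, codon = NA_character_,
    codon_cds_start = NA_integer_, exon = NA_integer_,
    offset_units = "nick", codon_offset = NA_integer_,
    edit_offsets = paste_csv(edits$offset),
    edit_ref = paste_csv(edits$ref),
    edit_alt = paste_csv(edits$alt),
    n_subs = nrow(edits), product = product,
    stringsAsFactors = FALSE
  )
  plan <- new_edit_plan(edits, codon_index, product, NA_integer_)
  build_pegrna(genome, hit, plan, ...)
}

#' Design the precise reversion of a validated forward design
#'
#' If the forward plan left PAM positions +5/+6 intact (`same_pam`), the
#' reversion pegRNA targets the same location on the edited allele: same
#' PAM, protospacer as mutated by the edit, RTT templating the reference
#' bases.  Otherwise the edited allele is searched for an alternative NGG
#' protospacer (either strand) placing every edited base within `window`;
#' failing that, an error of class `pegstop_pe_unreachable` is raised.
#' The forward nicking sgRNA is reused when its protospacer+PAM is
#' untouched by the edit.
#'
#' @param genome The reference genome the forward design was made on.
#' @param design A [design_pegrna()] result.
#' @param window Editing window for the alternative-PAM search,
#'   default `c(1, 6)`.
#' @param ... Passed to the reverse [build_pegrna()] call.
#' @return List of class `reversion_design`: `forward`, `reverse`
#'   (`pegrna`, `nick_sgrna`), `same_pam`, `nick_sgrna_shared`,
#'   `restored` (TRUE iff forward-then-reverse is the identity on the
#'   contig).
#' @export
design_reversion <- function(genome, design, window = c(1, 6), ...) {
  window <- check_window(window)
  stopifnot(inherits(design, "pe_design"))
  if (!isTRUE(design$validation$ok)) {
    stop("forward design failed validation; refusing to design a reversion")
  }
  fwd <- design$pegrna
  edited_genome <- design$validation$edited_genome
  contig <- fwd$contig
  cseq0 <- contig_seq(genome, contig)
  cseq1 <- contig_seq(edited_genome, contig)

  same_pam <- !any(fwd$plan$edits$offset %in% c(5L, 6L))
  rev_edits_for <- function(g_strand, nick_g) {
    # revert every genomic position the forward plan changed
    pos <- vapply(fwd$plan$edits$offset, function(n) {
      oriented_shift(fwd$nick_g, fwd$g_pam_strand, n - 1L)
    }, integer(1))
    off <- if (g_strand == "+") pos - nick_g + 1L else nick_g - pos + 1L
    data.frame(
      offset = off,
      ref = vapply(pos, function(g) oriented_read(cseq1, g_strand, g, 1L), character(1)),
      alt = vapply(pos, function(g) oriented_read(cseq0, g_strand, g, 1L), character(1)),
      stringsAsFactors = FALSE
    )
  }

  if (same_pam) {
    g_strand <- fwd$g_pam_strand
    proto_g1 <- fwd$proto_g1
    nick_g <- fwd$nick_g
  } else {
    pos <- vapply(fwd$plan$edits$offset, function(n) {
      oriented_shift(fwd$nick_g, fwd$g_pam_strand, n - 1L)
    }, integer(1))
    cands <- find_covering_protospacers(cseq1, pos, window)
    if (!length(cands)) {
      pe_unreachable_error(
        "no NGG protospacer on the edited allele places all edits in the window"
      )
    }
    mx <- vapply(cands, `[[`, numeric(1), "max_offset")
    nk <- vapply(cands, `[[`, numeric(1), "nick_g")
    pick <- cands[[order(mx, nk)[1]]]     # most nick-proximal edits win
    g_strand <- pick$g_strand
    proto_g1 <- pick$proto_g1
    nick_g <- pick$nick_g
  }

  rev_peg <- pegrna_from_locus(
    edited_genome, contig, g_strand, proto_g1,
    rev_edits_for(g_strand, nick_g),
    codon_index = fwd$plan$codon_index,
    transcript_id = fwd$hit$transcript_id,
    pbs_len = fwd$pbs_len, rtt_ext = fwd$rtt_ext, ...
  )

  # nicking sgRNA: reuse if its footprint escaped the edit
  nick_shared <- FALSE
  rev_nick <- NULL
  if (!is.null(design$nick_sgrna)) {
    ns <- design$nick_sgrna
    sp1 <- oriented_read(cseq1, ns$g_strand,
                         oriented_shift(ns$nick_g, ns$g_strand, -17L), 23L)
    sp0 <- oriented_read(cseq0, ns$g_strand,
                         oriented_shift(ns$nick_g, ns$g_strand, -17L), 23L)
    if (identical(sp0, sp1)) {
      nick_shared <- TRUE
      rev_nick <- ns
    }
  }
  if (is.null(rev_nick)) {
    rev_nick <- tryCatch(
      select_nick_sgrna(edited_genome, contig, g_strand, nick_g),
      warning = function(w) NULL
    )
  }

  val <- validate_pegrna(edited_genome, rev_peg)
  restored <- identical(contig_seq(val$edited_genome, contig), cseq0)
  structure(
    list(
      forward = design,
      reverse = list(pegrna = rev_peg, nick_sgrna = rev_nick),
      same_pam = same_pam,
      nick_sgrna_shared = nick_shared,
      restored = restored
    ),
    class = "reversion_design"
  )
}

#' @export
print.reversion_design <- function(x, ...) {
  cat(sprintf(
    "<reversion_design> same PAM: %s; nick sgRNA shared: %s; locus restored: %s\n",
    x$same_pam, x$nick_sgrna_shared, x$restored
  ))
  invisible(x)
}

# genomic edits (plus-strand positions + strand-resolved bases) installed
# by a base-editing hit
istop_edit_positions <- function(hit) {
  offs <- split_csv_int(hit$edit_offsets)   # protospacer positions
  data.frame(
    gpos = vapply(offs, function(p) {
      oriented_shift(hit$proto_g1, hit$g_pam_strand, p - 1L)
    }, integer(1)),
    strand = hit$g_pam_strand,              # edited C sits on the PAM strand
    ref = split_csv(hit$edit_ref),
    alt = split_csv(hit$edit_alt),
    stringsAsFactors = FALSE
  )
}

#' Classify the rescue routes available after a nonsense edit
#'
#' For a prime-editing primary the outcome is `PE_precise` when
#' [design_reversion()] succeeds on the edited allele and `PE_unreachable`
#' otherwise.  For an iSTOP primary the installed C-to-T edit(s) are
#' applied in silico and the edited allele is examined for (i) ABE rescue:
#' an NGG protospacer placing every to-be-reverted adenine at protospacer
#' positions 4-8 -- `ABE_precise` if some such protospacer carries no
#' additional window adenine (bystander), `ABE_bystander` if every one
#' does; and (ii) PE rescue evaluated as for prime-editing primaries.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param transcripts Transcript list covering the hit.
#' @param hit One hit row (`PE` or `iSTOP`).
#' @param window PE rescue window, default `c(1, 6)`.
#' @param be_window ABE rescue window in protospacer positions,
#'   default `c(4, 8)`.
#' @return Character vector of applicable classes, ordered
#'   PE_precise > ABE_precise > ABE_bystander > PE_unreachable.
#' @export
classify_rescue <- function(genome, transcripts, hit, window = c(1, 6),
                            be_window = BE_WINDOW) {
  stopifnot(nrow(hit) == 1L)
  window <- check_window(window)
  classes <- character(0)

  if (hit$editor == "PE") {
    design <- design_pegrna(genome, transcripts, hit)
    res <- tryCatch(design_reversion(genome, design, window),
                    pegstop_pe_unreachable = function(e) NULL)
    return(if (!is.null(res) && res$restored) "PE_precise" else "PE_unreachable")
  }
  if (hit$editor != "iSTOP") {
    stop("rescue classification applies to PE or iSTOP primaries")
  }

  ed <- istop_edit_positions(hit)
  cseq0 <- contig_seq(genome, hit$contig)
  cseq1 <- cseq0
  for (i in seq_len(nrow(ed))) {
    base_plus <- if (ed$strand[i] == "+") ed$alt[i] else complement(ed$alt[i])
    substr(cseq1, ed$gpos[i], ed$gpos[i]) <- base_plus
  }

  # ABE rescue: each installed T reads A on the opposite strand (or the
  # edit itself installed an A on the PAM strand for G>A coding changes);
  # all those As must sit at protospacer positions 4-8 of one NGG
  # protospacer on the A-bearing strand
  a_strand <- flip_strand(ed$strand[1])
  L <- nchar(cseq1)
  targets <- ed$gpos
  cands <- list()
  if (a_strand == "+") {
    a_lo <- max(targets) - be_window[2] + 1L
    a_hi <- min(targets) - be_window[1] + 1L
    if (a_lo <= a_hi) for (a in a_lo:a_hi) {
      if (a < 1L || a + 22L > L) next
      if (substr(cseq1, a + 21L, a + 22L) != "GG") next
      cands[[length(cands) + 1L]] <- list(g_strand = "+", proto_g1 = a)
    }
  } else {
    a_lo <- min(targets) + be_window[1] - 1L
    a_hi <- max(targets) + be_window[2] - 1L
    if (a_lo <= a_hi) for (a in a_lo:a_hi) {
      if (a > L || a - 22L < 1L) next
      if (substr(cseq1, a - 22L, a - 21L) != "CC") next
      cands[[length(cands) + 1L]] <- list(g_strand = "-", proto_g1 = a)
    }
  }
  # keep candidates whose window really contains all target As
  ok_cands <- Filter(function(cd) {
    q <- if (cd$g_strand == "+") targets - cd$proto_g1 + 1L
         else cd$proto_g1 - targets + 1L
    all(q >= be_window[1] & q <= be_window[2])
  }, cands)
  if (length(ok_cands)) {
    clean <- vapply(ok_cands, function(cd) {
      win <- oriented_read(cseq1, cd$g_strand,
                           oriented_shift(cd$proto_g1, cd$g_strand,
                                          be_window[1] - 1L),
                           be_window[2] - be_window[1] + 1L)
      wpos <- be_window[1]:be_window[2]
      q_req <- if (cd$g_strand == "+") targets - cd$proto_g1 + 1L
               else cd$proto_g1 - targets + 1L
      a_at <- wpos[strsplit(win, "")[[1]] == "A"]
      length(setdiff(a_at, q_req)) == 0L
    }, logical(1))
    classes <- c(classes, if (any(clean)) "ABE_precise" else "ABE_bystander")
  }

  # PE rescue of the iSTOP edit
  pe_cands <- find_covering_protospacers(cseq1, ed$gpos, window)
  classes <- c(classes,
               if (length(pe_cands)) "PE_precise" else "PE_unreachable")
  ord <- c("PE_precise", "ABE_precise", "ABE_bystander", "PE_unreachable")
  intersect(ord, classes)
}

#' Pick the best rescue class under the standard ordering
#'
#' @param classes Character vector of rescue classes.
#' @return The single best class
#'   (PE_precise > ABE_precise > ABE_bystander > PE_unreachable).
#' @export
best_rescue_class <- function(classes) {
  ord <- c("PE_precise", "ABE_precise", "ABE_bystander", "PE_unreachable")
  ord[min(match(classes, ord))]
}
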