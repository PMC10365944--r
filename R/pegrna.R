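# pegRNA assembly: spacer + scaffold + RTT + PBS (+ optional 3' appendix),
# PE3 nicking-sgRNA selection, in-silico application, and cloning oligos.
#
# All RNA segments are emitted as DNA-alphabet strings (T not U), matching
# oligo-ordering practice.

#' Canonical SpCas9 sgRNA scaffold (DNA alphabet)
#'
#' The standard single-guide scaffold placed between the spacer and the
#' pegRNA 3' extension.  Override via the `scaffold` argument of
#' [build_pegrna()] if a variant scaffold is used.
#' @export
SGRNA_SCAFFOLD <- paste0(
  "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGG",
  "CACCGAGTCGGTGC"
)

#' Synthetic placeholder for an exoribonuclease-resistant 3' appendix
#'
#' Stabilising 3' motifs (~80 nt) appended to pegRNAs are plasmid-specific
#' and not bundled here: this constant is a SYNTHETIC placeholder of
#' representative length so pipelines exercising the appendix slot run
#' end-to-end.  Replace it with the validated motif of your expression
#' system before ordering oligos.
#' @export
XRRNA_PLACEHOLDER <- paste0(
  "GGCAGTCAGGCAGTTCAAGCTGACGCTGGATAGCGGTTCGATCCAGCGTCAGCTTGAACTG",
  "CCTGACTGCCAAGCTTGG"
)

# edit plan normal form used by the designer: data.frame(offset, ref, alt)
# in +n units on the PAM strand, plus the codon bookkeeping
new_edit_plan <- function(edits, codon_index, product, codon_offset) {
  edits <- edits[order(edits$offset), , drop = FALSE]
  rownames(edits) <- NULL
  structure(
    list(edits = edits, codon_index = as.integer(codon_index),
         product = product, codon_offset = as.integer(codon_offset),
         n_subs = nrow(edits)),
    class = "edit_plan"
  )
}

#' Edit plan encoded by a scanner hit
#'
#' @param hit One row of a scanner result (PE hits only).
#' @return An `edit_plan` (offsets in +n units, bases on the PAM strand).
#' @export
hit_plan <- function(hit) {
  stopifnot(nrow(hit) == 1L)
  if (hit$offset_units != "nick") {
    stop("hit_plan() needs a prime-editing hit (+n offsets)")
  }
  new_edit_plan(
    data.frame(offset = split_csv_int(hit$edit_offsets),
               ref = split_csv(hit$edit_ref),
               alt = split_csv(hit$edit_alt),
               stringsAsFactors = FALSE),
    hit$codon_index, hit$product, hit$codon_offset
  )
}

#' Extend a hit's plan to 1x/2x/3x adjacent stop codons
#'
#' Adds the next `n_stops - 1` in-frame codons located 3' of the nick on
#' the PAM strand (coding-downstream for coding-strand PAMs,
#' coding-upstream for template-strand PAMs, since the RTT can only
#' template bases downstream of the nick) and assigns each its
#' [min_plan()].  The extra codons may extend beyond the scanner window;
#' spacer and PBS are unchanged across `n_stops`.
#'
#' @param map The transcript's [build_cds_map()].
#' @param hit One PE hit row.
#' @param n_stops 1, 2 or 3 consecutive stop codons.
#' @param forced_stops Optional character vector of stop codons to force,
#'   one per codon.
#' @return An `edit_plan` covering all targeted codons.
#' @export
plan_multi_stop <- function(map, hit, n_stops = 1, forced_stops = NULL) {
  n_stops <- as.integer(n_stops)
  stopifnot(n_stops >= 1L, n_stops <= 3L, nrow(hit) == 1L)
  if (hit$editor != "PE") stop("multi-stop planning applies to PE hits")
  base <- hit_plan(hit)
  if (n_stops == 1L) return(base)

  step <- if (hit$pam_strand == "+") 1L else -1L
  n_codons <- nchar(map$seq) %/% 3L
  ks <- hit$codon_index + step * (seq_len(n_stops) - 1L)
  if (any(ks < 2L) || any(ks > n_codons)) {
    stop("insufficient CDS around the target for ", n_stops, " stop codons")
  }
  edits <- list()
  products <- character(n_stops)
  for (j in seq_len(n_stops)) {
    k <- ks[j]
    cstart <- 3L * k - 2L
    codon <- substr(map$seq, cstart, cstart + 3L - 1L)
    if (j > 1L && codon %in% STOP_CODONS) {
      stop("adjacent codon ", k, " is already a stop codon")
    }
    if (any(map$junctions %in% c(cstart, cstart + 1L))) {
      stop("adjacent codon ", k, " spans an exon junction")
    }
    plan <- if (!is.null(forced_stops)) {
      min_plan(codon, forced_stops[j])
    } else if (j == 1L) {
      min_plan(codon, hit$product)
    } else {
      min_plan(codon)
    }
    products[j] <- plan$product
    # +n offset of codon position p: codon start sits at codon_offset+3*(j-1)
    # further 3' along the PAM strand; within the codon, position p maps to
    # +(start + p - 1) on "+" PAMs and +(start + 3 - p) on "-" PAMs
    cod_start_off <- hit$codon_offset + 3L * (j - 1L)
    off <- if (hit$pam_strand == "+") {
      cod_start_off + plan$positions - 1L
    } else {
      cod_start_off + 3L - plan$positions
    }
    refs <- if (hit$pam_strand == "+") plan$from else complement(plan$from)
    alts <- if (hit$pam_strand == "+") plan$to else complement(plan$to)
    edits[[j]] <- data.frame(offset = off, ref = refs, alt = alts,
                             stringsAsFactors = FALSE)
  }
  # junction check over the whole edited codon block
  cds_span <- range(3L * ks - 2L, 3L * ks)
  if (any(map$junctions >= cds_span[1] & map$junctions < cds_span[2])) {
    stop("multi-stop codon block spans an exon junction")
  }
  new_edit_plan(do.call(rbind, edits), ks, products, hit$codon_offset)
}

#' Assemble a pegRNA for a hit
#'
#' Spacer = the protospacer (with a 5' G prepended unless it already
#' starts with G, the U6 transcription convention; disable with
#' `g_prepend = FALSE`).  PBS = reverse complement of the `pbs_len` bases
#' immediately 5' of the nick on the PAM strand (default 13 nt).  RTT =
#' reverse complement of the edited PAM-strand segment from +1 through the
#' most-3' edited base plus `rtt_ext` further bases (default 14), grown
#' base by base while the scaffold-adjacent (5'-most) RTT base would be C.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param hit One PE hit row from [scan_pe_stops()].
#' @param plan Optional `edit_plan` (e.g. from [plan_multi_stop()]);
#'   defaults to the hit's own plan.
#' @param pbs_len Primer-binding-site length, default 13 nt.
#' @param rtt_ext RTT extension past the last edit, default 14 nt.
#' @param appendix Optional named 3' appendix sequence (e.g.
#'   [XRRNA_PLACEHOLDER]).
#' @param g_prepend Prepend G to non-G-starting spacers (default TRUE).
#' @param scaffold Scaffold sequence, default [SGRNA_SCAFFOLD].
#' @return An object of class `pegrna`.
#' @export
build_pegrna <- function(genome, hit, plan = NULL, pbs_len = 13, rtt_ext = 14,
                         appendix = NULL, g_prepend = TRUE,
                         scaffold = SGRNA_SCAFFOLD) {
  stopifnot(nrow(hit) == 1L)
  pbs_len <- as.integer(pbs_len)
  rtt_ext <- as.integer(rtt_ext)
  stopifnot(pbs_len >= 1L, pbs_len <= 17L, rtt_ext >= 1L)
  if (is.null(plan)) plan <- hit_plan(hit)
  cseq <- contig_seq(genome, hit$contig)
  gstr <- hit$g_pam_strand

  # PBS from the protospacer itself: positions (18-pbs_len)..17
  pbs <- revcomp(substr(hit$protospacer, 18L - pbs_len, 17L))

  max_off <- max(plan$edits$offset)
  rtt_len <- max_off + rtt_ext
  read_plus_n <- function(n) {
    g <- oriented_shift(hit$nick_g, gstr, n - 1L)
    if (g < 1L || g > nchar(cseq)) {
      stop("RTT span runs off contig ", hit$contig)
    }
    oriented_read(cseq, gstr, g, 1L)
  }
  # C-avoidance: the scaffold-adjacent RTT base is the complement of the
  # PAM-strand base at +rtt_len; grow while that complement is C (base G)
  grown <- 0L
  while (read_plus_n(rtt_len) == "G") {
    rtt_len <- rtt_len + 1L
    grown <- grown + 1L
    if (grown > 30L) stop("could not satisfy the RTT 5'-base rule within 30 nt")
  }
  seg <- vapply(seq_len(rtt_len), read_plus_n, character(1))
  seg[plan$edits$offset] <- plan$edits$alt
  rtt <- revcomp(paste(seg, collapse = ""))

  spacer <- hit$protospacer
  if (isTRUE(g_prepend) && substr(spacer, 1, 1) != "G") {
    spacer <- paste0("G", spacer)
  }
  structure(
    list(
      spacer = spacer, scaffold = scaffold, rtt = rtt, pbs = pbs,
      appendix = appendix,
      full_sequence = paste0(spacer, scaffold, rtt, pbs,
                             if (is.null(appendix)) "" else appendix),
      pbs_len = pbs_len, rtt_len = rtt_len, rtt_ext = rtt_ext,
      protospacer = hit$protospacer, pam = hit$pam,
      contig = hit$contig, g_pam_strand = gstr,
      proto_g1 = hit$proto_g1, nick_g = hit$nick_g,
      hit = as.list(hit), plan = plan
    ),
    class = "pegrna"
  )
}

#' @export
print.pegrna <- function(x, ...) {
  cat(sprintf("<pegrna> %s:%s nick@%d (%s strand PAM %s)\n",
              x$contig, x$hit$transcript_id %||% "", x$nick_g,
              x$g_pam_strand, x$pam))
  cat(sprintf("  spacer  %s\n  PBS(%d) %s\n  RTT(%d) %s\n",
              x$spacer, x$pbs_len, x$pbs, x$rtt_len, x$rtt))
  cat(sprintf("  edits   %s\n",
              paste(sprintf("+%d:%s>%s", x$plan$edits$offset,
                            x$plan$edits$ref, x$plan$edits$alt),
                    collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select a PE3 nicking sgRNA
#'
#' Scans for NGG protospacers on the strand opposite the pegRNA's PAM
#' strand whose nick falls 50-90 bp (configurable) from the pegRNA nick,
#' and returns the candidate whose distance is closest to the range
#' midpoint (70 bp by default; ties go to the smaller distance).
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param contig Contig of the locus.
#' @param pegrna_strand Genomic strand of the pegRNA's PAM.
#' @param pegrna_nick_g Genomic coordinate of the pegRNA's +1 base.
#' @param range Allowed nick-to-nick distance, default `c(50, 90)`.
#' @return A list of class `nick_sgrna` (`spacer`, `pam`, `nick_g`,
#'   `g_strand`, `distance`) or `NULL` (with a warning) when no candidate
#'   exists.
#' @export
select_nick_sgrna <- function(genome, contig, pegrna_strand, pegrna_nick_g,
                              range = c(50, 90)) {
  range <- as.integer(range)
  stopifnot(length(range) == 2L, range[1] <= range[2])
  cseq <- contig_seq(genome, contig)
  L <- nchar(cseq)
  target_strand <- flip_strand(pegrna_strand)
  lo <- max(1L, pegrna_nick_g - range[2] - 30L)
  hi <- min(L, pegrna_nick_g + range[2] + 30L)
  cand <- list()
  if (target_strand == "+") {
    # GG at plus coords g,g+1 with PAM = (g-1)..(g+1); +1 base at g-5
    for (g in lo:(hi - 1L)) {
      if (substr(cseq, g, g + 1L) != "GG") next
      s <- g - 21L
      if (s < 1L || g + 1L > L) next
      nick <- s + 17L
      d <- abs(nick - pegrna_nick_g)
      if (d >= range[1] && d <= range[2]) {
        cand[[length(cand) + 1L]] <- list(
          spacer = substr(cseq, s, s + 19L),
          pam = substr(cseq, s + 20L, s + 22L),
          nick_g = nick, g_strand = "+", distance = d
        )
      }
    }
  } else {
    # CC at plus coords p,p+1 => minus-strand PAM; protospacer pos1 at
    # plus p+22; +1 base (minus pos 18) at plus p+5
    for (p in lo:(hi - 1L)) {
      if (substr(cseq, p, p + 1L) != "CC") next
      if (p + 22L > L) next
      nick <- p + 5L
      d <- abs(nick - pegrna_nick_g)
      if (d >= range[1] && d <= range[2]) {
        cand[[length(cand) + 1L]] <- list(
          spacer = oriented_read(cseq, "-", p + 22L, 20L),
          pam = oriented_read(cseq, "-", p + 2L, 3L),
          nick_g = nick, g_strand = "-", distance = d
        )
      }
    }
  }
  if (!length(cand)) {
    warning("no opposite-strand NGG protospacer nicks within [",
            range[1], ", ", range[2], "] bp")
    return(NULL)
  }
  mid <- mean(range)
  d <- vapply(cand, `[[`, numeric(1), "distance")
  nick <- vapply(cand, `[[`, numeric(1), "nick_g")
  best <- order(abs(d - mid), d, nick)[1]
  structure(cand[[best]], class = "nick_sgrna")
}

#' Apply a pegRNA in silico and report the outcome
#'
#' Splices the reverse complement of the RTT over the nick as the new
#' PAM-strand sequence and reports (a) the Hamming distance between the
#' original and edited locus together with the planned substitution count,
#' (b) whether the edited CDS gains stop codons exactly at the planned
#' codon indices (when `transcripts` is supplied), and (c) whether PAM
#' positions +5/+6 survived the edit (feeds reversion design).  A PBS or
#' RTT inconsistent with the locus yields `ok = FALSE` with reasons.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param pegrna A [build_pegrna()] result.
#' @param transcripts Optional transcript list for the translation check.
#' @return List with `ok`, `edited_genome`, `n_changed`, `expected_changes`,
#'   `changed_pos`, `pam_intact`, `stop_ok`, `stop_codons_at`, `reasons`.
#' @export
validate_pegrna <- function(genome, pegrna, transcripts = NULL) {
  reasons <- character(0)
  cseq <- contig_seq(genome, pegrna$contig)
  gstr <- pegrna$g_pam_strand

  # PBS must anneal to the bases 5' of the nick
  ref_pbs_region <- oriented_read(
    cseq, gstr, oriented_shift(pegrna$nick_g, gstr, -pegrna$pbs_len), pegrna$pbs_len
  )
  if (revcomp(ref_pbs_region) != pegrna$pbs) {
    reasons <- c(reasons, "PBS does not match the 13 nt 5' of the nick")
  }
  # spacer (minus any prepended G) must match the protospacer
  sp <- pegrna$spacer
  if (nchar(sp) == 21L) sp <- substr(sp, 2, 21)
  if (sp != oriented_read(cseq, gstr, pegrna$proto_g1, 20L)) {
    reasons <- c(reasons, "spacer does not match the locus")
  }

  # write the reverse-transcribed segment over +1..+rtt_len
  new_seg <- revcomp(pegrna$rtt)              # PAM-strand 5'->3' from +1
  edited <- cseq
  if (gstr == "+") {
    substr(edited, pegrna$nick_g, pegrna$nick_g + pegrna$rtt_len - 1L) <- new_seg
  } else {
    substr(edited, pegrna$nick_g - pegrna$rtt_len + 1L, pegrna$nick_g) <-
      revcomp(new_seg)
  }

  a <- strsplit(cseq, "")[[1]]
  b <- strsplit(edited, "")[[1]]
  changed <- which(a != b)
  real_edits <- pegrna$plan$edits[pegrna$plan$edits$ref != pegrna$plan$edits$alt, ]
  expected <- sort(vapply(real_edits$offset, function(n) {
    oriented_shift(pegrna$nick_g, gstr, n - 1L)
  }, integer(1)))
  if (!identical(changed, expected)) {
    reasons <- c(reasons, "edited positions differ from the plan")
  }
  pam_intact <- !any(pegrna$plan$edits$offset %in% c(5L, 6L))

  stop_ok <- NA
  stop_at <- integer(0)
  if (!is.null(transcripts)) {
    transcripts <- as_transcript_list(transcripts)
    tx <- transcripts[[pegrna$hit$transcript_id]]
    if (!is.null(tx)) {
      eg <- set_contig_seq(genome, pegrna$contig, edited)
      map0 <- suppressWarnings(build_cds_map(genome, tx))
      map1 <- suppressWarnings(build_cds_map(eg, tx))
      n_cod <- nchar(map1$seq) %/% 3L
      cods0 <- substring(map0$seq, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
      cods1 <- substring(map1$seq, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
      stop_at <- which(cods1 %in% STOP_CODONS & !(cods0 %in% STOP_CODONS))
      planned <- sort(pegrna$plan$codon_index)
      stop_ok <- identical(sort(stop_at), planned) &&
        all(cods1[planned] == pegrna$plan$product[order(pegrna$plan$codon_index)])
    }
  }
  list(
    ok = length(reasons) == 0L,
    edited_genome = set_contig_seq(genome, pegrna$contig, edited),
    n_changed = length(changed),
    expected_changes = nrow(real_edits),
    changed_pos = changed,
    pam_intact = pam_intact,
    stop_ok = stop_ok,
    stop_codons_at = stop_at,
    reasons = reasons
  )
}

#' Cloning oligos for a pegRNA
#'
#' Golden-Gate oligo set: the spacer duplex carries 5' `ACCG` / 3' `GTTTC`
#' on the top strand and a 5' `CTCTGAAAC` end on the bottom strand; the 3'
#' extension (RTT+PBS) duplex carries 5' `GTGC` (top) and 5' `GACA`
#' (bottom) overhangs.  Stripping the overhangs and annealing
#' reconstructs the spacer and extension exactly.
#'
#' @param pegrna A [build_pegrna()] result.
#' @return Data frame with columns `oligo`, `sequence`.
#' @export
emit_oligos <- function(pegrna) {
  ext <- paste0(pegrna$rtt, pegrna$pbs)
  data.frame(
    oligo = c("spacer_top", "spacer_bottom", "extension_top", "extension_bottom"),
    sequence = c(
      paste0("ACCG", pegrna$spacer, "GTTTC"),
      paste0("CTCTGAAAC", revcomp(pegrna$spacer)),
      paste0("GTGC", ext),
      paste0("GACA", revcomp(ext))
    ),
    stringsAsFactors = FALSE
  )
}

#' One-call reagent design for a hit
#'
#' Bundles [plan_multi_stop()], [build_pegrna()], [select_nick_sgrna()]
#' and [validate_pegrna()] into a single design object.
#'
#' @inheritParams build_pegrna
#' @param transcripts Transcript list (for multi-stop planning and the
#'   translation check).
#' @param n_stops Number of consecutive stop codons to install (1-3).
#' @param nick_range PE3 nicking-sgRNA distance range, default `c(50, 90)`.
#' @param ... Passed on to [build_pegrna()].
#' @return List of class `pe_design`: `pegrna`, `nick_sgrna`, `plan`,
#'   `hit`, `validation`.
#' @export
design_pegrna <- function(genome, transcripts, hit, n_stops = 1,
                          nick_range = c(50, 90), ...) {
  transcripts <- as_transcript_list(transcripts)
  tx <- transcripts[[hit$transcript_id]]
  if (is.null(tx)) stop("hit's transcript not in `transcripts`")
  map <- suppressWarnings(build_cds_map(genome, tx))
  plan <- plan_multi_stop(map, hit, n_stops)
  peg <- build_pegrna(genome, hit, plan, ...)
  nick <- tryCatch(
    select_nick_sgrna(genome, hit$contig, hit$g_pam_strand, hit$nick_g,
                      nick_range),
    warning = function(w) NULL
  )
  val <- validate_pegrna(genome, peg, transcripts)
  structure(
    list(pegrna = peg, nick_sgrna = nick, plan = plan, hit = hit,
         validation = val),
    class = "pe_design"
  )
}

#' @export
print.pe_design <- function(x, ...) {
  print(x$pegrna)
  if (!is.null(x$nick_sgrna)) {
    cat(sprintf("  PE3 nick sgRNA %s (PAM %s, %d bp from pegRNA nick)\n",
                x$nick_sgrna$spacer, x$nick_sgrna$pam, x$nick_sgrna$distance))
  } else {
    cat("  no PE3 nicking sgRNA in range\n")
  }
  cat(sprintf("  in-silico check: %s\n",
              if (isTRUE(x$validation$ok)) "OK" else
                paste(x$validation$reasons, collapse = "; ")))
  invisible(x)
}
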