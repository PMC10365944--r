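# Independent brute-force oracles.  These deliberately avoid the package's
# scanning/splicing internals: naive loops, chartr-based reverse
# complements, exhaustive enumeration.  They define what "correct" means
# for the fast implementations.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

oracle_rc <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# every substitution pattern (3^3 - 1 non-identity patterns) that turns
# `codon` into a stop; returns data.frame(positions, product, n)
oracle_stop_plans <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  seen <- list()
  for (x1 in c("A", "C", "G", "T")) for (x2 in c("A", "C", "G", "T")) {
    for (x3 in c("A", "C", "G", "T")) {
      cand <- c(x1, x2, x3)
      if (all(cand == b)) next
      prod <- paste(cand, collapse = "")
      if (prod %in% ORACLE_STOPS) {
        pos <- which(cand != b)
        key <- paste(prod, paste(pos, collapse = ","))
        seen[[key]] <- list(positions = pos, product = prod, n = length(pos))
      }
    }
  }
  seen
}

# minimal plan under the package's documented tie-break, derived
# independently: fewest substitutions, then TAA < TAG < TGA
oracle_min_plan <- function(codon) {
  plans <- oracle_stop_plans(codon)
  best <- NULL
  for (p in plans) {
    # only the "direct" plan per stop (substituting exactly the differing
    # positions) is minimal for that stop; others are supersets
    if (is.null(best) ||
        p$n < best$n ||
        (p$n == best$n &&
         match(p$product, ORACLE_STOPS) < match(best$product, ORACLE_STOPS))) {
      best <- p
    }
  }
  best
}

# naive splice of a transcript's CDS: seq (coding strand), per-base genomic
# coords, junction offsets
oracle_splice <- function(genome, tx) {
  cs <- as.character(genome[[tx$contig]])
  pieces <- character(0)
  gpos <- integer(0)
  lens <- integer(0)
  for (i in seq_len(nrow(tx$cds))) {
    a <- tx$cds$start[i]; b <- tx$cds$end[i]
    p <- substr(cs, a, b)
    if (tx$strand == "-") {
      p <- oracle_rc(p)
      gpos <- c(gpos, b:a)
    } else {
      gpos <- c(gpos, a:b)
    }
    pieces <- c(pieces, p)
    lens <- c(lens, nchar(p))
  }
  seq <- paste(pieces, collapse = "")
  L <- 3L * (nchar(seq) %/% 3L)
  list(seq = substr(seq, 1, L), gpos = gpos[seq_len(L)],
       junctions = if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer(0),
       L = L)
}

# brute-force PE scanner: every offset x both strands, every in-frame codon
# wholly inside the window; returns a character vector of hit keys
oracle_scan_pe <- function(genome, transcripts, window = c(1, 6)) {
  keys <- character(0)
  for (tx in transcripts) {
    sp <- oracle_splice(genome, tx)
    L <- sp$L
    for (pam_strand in c("+", "-")) {
      sseq <- if (pam_strand == "+") sp$seq else oracle_rc(sp$seq)
      jn <- if (pam_strand == "+") sp$junctions else
        if (length(sp$junctions)) L - sp$junctions else integer(0)
      for (s in seq_len(max(0L, L - 22L))) {
        if (substr(sseq, s + 21, s + 22) != "GG") next
        for (t in (s + 16L + window[1]):(s + 16L + window[2] - 2L)) {
          span_end <- max(s + 22L, t + 2L)
          if (span_end > L) next
          if (any(jn >= s & jn <= span_end - 1L)) next
          cstart <- if (pam_strand == "+") t else L - t - 1L
          if (cstart < 1L || cstart %% 3L != 1L) next
          k <- (cstart + 2L) %/% 3L
          if (k == 1L) next
          codon <- substr(sp$seq, cstart, cstart + 2L)
          if (codon %in% ORACLE_STOPS) next
          if (any(sp$junctions %in% c(cstart, cstart + 1L))) next
          mp <- oracle_min_plan(codon)
          g1 <- sp$gpos[if (pam_strand == "+") s else L + 1L - s]
          keys <- c(keys, paste("PE", tx$transcript_id, pam_strand, g1, k,
                                mp$product, mp$n, sep = "|"))
        }
      }
    }
  }
  sort(keys)
}

# brute-force iSTOP scanner
oracle_scan_istop <- function(genome, transcripts, be_window = c(4, 8)) {
  keys <- character(0)
  for (tx in transcripts) {
    sp <- oracle_splice(genome, tx)
    L <- sp$L
    for (pam_strand in c("+", "-")) {
      sseq <- if (pam_strand == "+") sp$seq else oracle_rc(sp$seq)
      jn <- if (pam_strand == "+") sp$junctions else
        if (length(sp$junctions)) L - sp$junctions else integer(0)
      targets <- if (pam_strand == "+") c("CAG", "CAA", "CGA") else "TGG"
      for (s in seq_len(max(0L, L - 22L))) {
        if (substr(sseq, s + 21, s + 22) != "GG") next
        if (any(jn >= s & jn <= s + 21L)) next
        for (q in be_window[1]:be_window[2]) {
          t <- s + q - 1L
          if (t + 2L > L) next
          cstart <- if (pam_strand == "+") t else L - t - 1L
          if (cstart < 1L || cstart %% 3L != 1L) next
          k <- (cstart + 2L) %/% 3L
          if (k == 1L) next
          codon <- substr(sp$seq, cstart, cstart + 2L)
          if (!codon %in% targets) next
          if (any(sp$junctions %in% c(cstart, cstart + 1L))) next
          # some strand-pure C->T route must have all edited Cs in window
          route_ok <- FALSE
          prods <- character(0)
          if (pam_strand == "+") {
            # single C at codon position 1, protospacer position q
            route_ok <- q >= be_window[1] && q <= be_window[2]
            prods <- chartr("C", "T", substr(codon, 1, 1))
          } else {
            # TGG: template Cs opposite the Gs; codon pos 2 -> proto q+1,
            # pos 3 -> proto q.  Any single- or double-C route in-window.
            ok2 <- (q + 1L) <= be_window[2]
            ok3 <- TRUE  # proto q always in window here
            route_ok <- ok2 || ok3
          }
          if (route_ok) {
            g1 <- sp$gpos[if (pam_strand == "+") s else L + 1L - s]
            keys <- c(keys, paste("iSTOP", tx$transcript_id, pam_strand,
                                  g1, k, sep = "|"))
          }
        }
      }
    }
  }
  sort(keys)
}

# brute-force i-Silence scanner over the first-exon array
oracle_scan_isilence <- function(genome, transcripts, be_window = c(4, 8)) {
  keys <- character(0)
  for (tx in transcripts) {
    cs <- as.character(genome[[tx$contig]])
    e1 <- tx$exons[1, ]
    E <- e1$end - e1$start + 1L
    arr <- substr(cs, e1$start, e1$end)
    if (tx$strand == "-") arr <- oracle_rc(arr)
    # start codon array offset
    sc <- if (tx$strand == "+") tx$cds$start[1] - e1$start + 1L else
      e1$end - tx$cds$end[1] + 1L
    if (sc + 2L > E || substr(arr, sc, sc + 2L) != "ATG") next
    # coding-strand protospacers: A of ATG at proto 4..8
    for (s in seq_len(max(0L, E - 22L))) {
      if (substr(arr, s + 21, s + 22) != "GG") next
      q <- sc - s + 1L
      if (q >= be_window[1] && q <= be_window[2] && sc + 2L <= s + 19L) {
        keys <- c(keys, paste("iSilence", tx$transcript_id, "+", s, sep = "|"))
      }
    }
    rc_arr <- oracle_rc(arr)
    r <- E - sc  # rc offset of the T-opposite A (coding offset sc+1)
    for (s in seq_len(max(0L, E - 22L))) {
      if (substr(rc_arr, s + 21, s + 22) != "GG") next
      q <- r - s + 1L
      if (q >= be_window[1] && q <= be_window[2] && (q - 1L) >= 1L &&
          (q + 1L) <= 20L) {
        keys <- c(keys, paste("iSilence", tx$transcript_id, "-", s, sep = "|"))
      }
    }
  }
  sort(keys)
}

# package-hit tables reduced to the same key space
impl_pe_keys <- function(hits) {
  h <- hits[hits$editor == "PE", ]
  sort(paste("PE", h$transcript_id, h$pam_strand, h$proto_g1, h$codon_index,
             h$product, h$n_subs, sep = "|"))
}
impl_istop_keys <- function(hits) {
  h <- hits[hits$editor == "iSTOP", ]
  sort(paste("iSTOP", h$transcript_id, h$pam_strand, h$proto_g1,
             h$codon_index, sep = "|"))
}
impl_isilence_keys <- function(hits, transcripts) {
  h <- hits[hits$editor == "iSilence", ]
  if (!nrow(h)) return(character(0))
  # convert the genomic anchor back to a first-exon array offset
  s <- vapply(seq_len(nrow(h)), function(i) {
    tx <- transcripts[[h$transcript_id[i]]]
    e1 <- tx$exons[1, ]
    arr_of_g <- function(g, pam_strand) {
      coding_off <- if (tx$strand == "+") g - e1$start + 1L else e1$end - g + 1L
      E <- e1$end - e1$start + 1L
      if (pam_strand == "+") coding_off else E + 1L - coding_off
    }
    arr_of_g(h$proto_g1[i], h$pam_strand[i])
  }, integer(1))
  sort(paste("iSilence", h$transcript_id, h$pam_strand, s, sep = "|"))
}

# naive six-frame ORF oracle (triple loop, no vectorisation)
oracle_orfs <- function(s, min_len) {
  res <- list()
  L <- nchar(s)
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else oracle_rc(s)
    for (f in 0:2) {
      i <- 1L + f
      last_stop <- f - 2L
      while (i + 2L <= L) {
        cod <- substr(ss, i, i + 2L)
        if (cod %in% ORACLE_STOPS) {
          # earliest ATG after the previous in-frame stop
          j <- last_stop + 3L
          while (j < i) {
            if (substr(ss, j, j + 2L) == "ATG") break
            j <- j + 3L
          }
          if (j < i && substr(ss, j, j + 2L) == "ATG") {
            len <- i + 2L - j + 1L
            if (len >= min_len) {
              if (strand == "+") {
                res[[length(res) + 1L]] <- c(j, i + 2L, "+")
              } else {
                res[[length(res) + 1L]] <- c(L + 1L - (i + 2L), L + 1L - j, "-")
              }
            }
          }
          last_stop <- i
        }
        i <- i + 3L
      }
    }
  }
  if (!length(res)) return(character(0))
  sort(vapply(res, paste, character(1), collapse = "|"))
}

# brute-force variant classification around one position
oracle_variant_class <- function(cseq, x, ref, alt, pe_window = c(1, 9)) {
  L <- nchar(cseq)
  pe <- FALSE
  for (s in max(1L, x - 40L):min(L - 22L, x + 40L)) {
    # plus protospacer at s: nick +1 base at s+17
    if (substr(cseq, s + 21L, s + 22L) == "GG") {
      n <- x - (s + 17L) + 1L
      if (n >= pe_window[1] && n <= pe_window[2]) pe <- TRUE
    }
    # minus protospacer with PAM CC at s,s+1: +1 base at s+5
    if (substr(cseq, s, s + 1L) == "CC" && s + 22L <= L) {
      n <- (s + 5L) - x + 1L
      if (n >= pe_window[1] && n <= pe_window[2]) pe <- TRUE
    }
  }
  istop <- FALSE
  if ((ref == "C" && alt == "T") || (ref == "G" && alt == "A")) {
    for (s in max(1L, x - 40L):min(L - 22L, x + 40L)) {
      if (ref == "C" && substr(cseq, s + 21L, s + 22L) == "GG") {
        q <- x - s + 1L
        if (q >= 4L && q <= 8L) istop <- TRUE
      }
      if (ref == "G" && substr(cseq, s, s + 1L) == "CC" && s + 22L <= L) {
        q <- (s + 22L) - x + 1L
        if (q >= 4L && q <= 8L) istop <- TRUE
      }
    }
  }
  if (pe && istop) "PE_and_iSTOP" else if (pe) "PE_only"
  else if (istop) "iSTOP_only" else "neither"
}
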