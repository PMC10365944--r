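# small sequence helpers shared across modules

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors in, plain character vectors out.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement without reversal (scalar/vector)
complement <- function(x) chartr("ACGTN", "TGCAN", x)

# deterministic RNG scope: run expr under `seed`, restore caller RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# fetch a contig sequence as a character scalar
contig_seq <- function(genome, contig) {
  if (inherits(genome, "DNAStringSet")) {
    if (!contig %in% names(genome)) stop("contig '", contig, "' not in genome")
    return(as.character(genome[[contig]]))
  }
  if (is.character(genome)) {
    if (!contig %in% names(genome)) stop("contig '", contig, "' not in genome")
    return(unname(genome[[contig]]))
  }
  stop("genome must be a named character vector or a DNAStringSet")
}

# replace genome[[contig]] with new sequence, preserving container type
set_contig_seq <- function(genome, contig, seq) {
  if (inherits(genome, "DNAStringSet")) {
    genome[[contig]] <- Biostrings::DNAString(seq)
  } else {
    genome[[contig]] <- seq
  }
  genome
}

# Read `len` bases 5'->3' along genomic strand `g_strand`, starting at the
# base whose genomic coordinate is `from` (1-based).  On "-" the read walks
# leftwards and is complemented.
oriented_read <- function(cseq, g_strand, from, len) {
  if (g_strand == "+") {
    stopifnot(from >= 1, from + len - 1 <= nchar(cseq))
    substr(cseq, from, from + len - 1)
  } else {
    stopifnot(from - len + 1 >= 1, from <= nchar(cseq))
    revcomp(substr(cseq, from - len + 1, from))
  }
}

# genomic coordinate `offset` bases 3' of genomic position `pos` on strand
oriented_shift <- function(pos, g_strand, offset) {
  if (g_strand == "+") pos + offset else pos - offset
}

# flip "+"/"-"
flip_strand <- function(s) ifelse(s == "+", "-", "+")

paste_csv <- function(x) paste(x, collapse = ",")
split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
split_csv_int <- function(x) as.integer(split_csv(x))
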