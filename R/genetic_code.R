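# Stop-substitution calculus over the standard genetic code (table 1).
# A substitution plan records which codon positions change, from what to
# what, and which stop codon results.  "PE chemistry" allows arbitrary base
# changes; "CBE chemistry" is restricted to strand-pure deamination: all
# C->T on one strand or all G->A (i.e. C->T on the opposite strand).

#' Stop codons of the standard genetic code
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

DNA_ALPHABET <- c("A", "C", "G", "T")

# the 61 sense codons
sense_codons <- function() {
  setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
}

check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L) {
    stop("codon must be a single character string")
  }
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !all(strsplit(codon, "")[[1]] %in% DNA_ALPHABET)) {
    stop("codon must be 3 bases over A/C/G/T, got '", codon, "'")
  }
  codon
}

check_sense_codon <- function(codon) {
  codon <- check_codon(codon)
  if (codon %in% STOP_CODONS) stop("'", codon, "' is already a stop codon")
  codon
}

new_substitution_plan <- function(codon, positions, product) {
  cb <- strsplit(codon, "")[[1]]
  pb <- strsplit(product, "")[[1]]
  structure(
    list(
      codon = codon,
      positions = as.integer(positions),
      from = cb[positions],
      to = pb[positions],
      product = product,
      n_subs = length(positions)
    ),
    class = "substitution_plan"
  )
}

#' @export
print.substitution_plan <- function(x, ...) {
  cat(sprintf(
    "%s -> %s  (%d sub%s: %s)\n",
    x$codon, x$product, x$n_subs, if (x$n_subs > 1) "s" else "",
    paste(sprintf("pos%d %s>%s", x$positions, x$from, x$to), collapse = ", ")
  ))
  invisible(x)
}

#' Apply a substitution plan to its source codon
#'
#' @param codon Sense codon the plan was derived for.
#' @param plan A `substitution_plan` as returned by [stops_reachable()],
#'   [cbe_stop_routes()] or [min_plan()].
#' @return The product codon (character scalar).
#' @export
apply_plan <- function(codon, plan) {
  codon <- check_codon(codon)
  b <- strsplit(codon, "")[[1]]
  b[plan$positions] <- plan$to
  paste(b, collapse = "")
}

order_plans <- function(plans) {
  if (!length(plans)) return(plans)
  n <- vapply(plans, function(p) p$n_subs, integer(1))
  s <- vapply(plans, function(p) match(p$product, STOP_CODONS), integer(1))
  plans[order(n, s)]
}

#' Enumerate substitution routes from a sense codon to the stop codons
#'
#' For each of TAA/TAG/TGA the (unique) set of differing positions defines
#' one substitution plan; plans needing more than `max_subs` changes are
#' dropped.  Plans are ordered by substitution count, then by stop codon in
#' the fixed order TAA < TAG < TGA (a deterministic tie-break; biology does
#' not rank the three stops).
#'
#' @param codon A sense codon (3 bases, A/C/G/T; stop codons are rejected).
#' @param max_subs Maximum number of substitutions allowed (1-3).
#' @return List of `substitution_plan` objects (possibly shorter than 3).
#' @export
#' @examples
#' stops_reachable("CGA")[[1]]   # one C>T substitution gives TGA
stops_reachable <- function(codon, max_subs = 3) {
  codon <- check_sense_codon(codon)
  max_subs <- as.integer(max_subs)
  stopifnot(max_subs >= 1L, max_subs <= 3L)
  cb <- strsplit(codon, "")[[1]]
  plans <- list()
  for (stp in STOP_CODONS) {
    pos <- which(cb != strsplit(stp, "")[[1]])
    if (length(pos) >= 1L && length(pos) <= max_subs) {
      plans[[length(plans) + 1L]] <- new_substitution_plan(codon, pos, stp)
    }
  }
  order_plans(plans)
}

#' Strand-pure cytosine-base-editor routes to a stop codon
#'
#' A single CBE exposure deaminates cytosines on one strand only, so a
#' legal route converts the codon to a stop using substitutions that are
#' all C->T (coding strand) or all G->A (coding strand, i.e. C->T on the
#' template strand).  Mixed-strand routes are excluded.
#'
#' @inheritParams stops_reachable
#' @return List of `substitution_plan` objects; empty if no route exists.
#' @export
#' @examples
#' cbe_stop_routes("CAA")  # single C>T gives TAA
#' cbe_stop_routes("ATG")  # no strand-pure route: empty list
cbe_stop_routes <- function(codon) {
  codon <- check_sense_codon(codon)
  cb <- strsplit(codon, "")[[1]]
  plans <- list()
  for (chem in list(c("C", "T"), c("G", "A"))) {
    idx <- which(cb == chem[1])
    if (!length(idx)) next
    for (m in seq_len(2L^length(idx) - 1L)) {
      sel <- idx[bitwAnd(m, 2L^(seq_along(idx) - 1L)) > 0L]
      mut <- cb
      mut[sel] <- chem[2]
      prod <- paste(mut, collapse = "")
      if (prod %in% STOP_CODONS) {
        plans[[length(plans) + 1L]] <- new_substitution_plan(codon, sort(sel), prod)
      }
    }
  }
  order_plans(plans)
}

#' Amino acids whose codons can be converted into a stop codon
#'
#' Under unrestricted prime-editing chemistry ("PE", up to three arbitrary
#' substitutions) every sense codon reaches a stop, so all 20 amino acids
#' are returned.  Under strand-pure CBE chemistry ("CBE") only codons with
#' a [cbe_stop_routes()] hit count, which restricts the set to glutamine,
#' arginine and tryptophan.
#'
#' @param chemistry `"PE"` or `"CBE"`.
#' @return Sorted character vector of one-letter amino-acid codes.
#' @export
amino_acids_stop_reachable <- function(chemistry = c("PE", "CBE")) {
  if (is.character(chemistry)) chemistry <- toupper(chemistry)
  chemistry <- match.arg(chemistry)
  hit <- vapply(sense_codons(), function(cd) {
    if (chemistry == "PE") {
      length(stops_reachable(cd, 3)) > 0L
    } else {
      length(cbe_stop_routes(cd)) > 0L
    }
  }, logical(1))
  sort(unique(unname(Biostrings::GENETIC_CODE[sense_codons()[hit]])))
}

#' Select the substitution plan used by the designers
#'
#' Without `forced_stop`, returns the first plan under the
#' [stops_reachable()] ordering (fewest substitutions, then TAA < TAG <
#' TGA).  With `forced_stop`, returns the unique plan reaching that stop
#' codon, whatever its substitution count.
#'
#' @inheritParams stops_reachable
#' @param forced_stop Optional stop codon (TAA/TAG/TGA) to force.
#' @return A `substitution_plan`.
#' @export
#' @examples
#' min_plan("TGG")                      # 1 sub, G>A at position 2 -> TAG
#' min_plan("CAC", forced_stop = "TGA") # the 3-substitution route
min_plan <- function(codon, forced_stop = NULL) {
  codon <- check_sense_codon(codon)
  if (is.null(forced_stop)) {
    return(stops_reachable(codon, 3)[[1]])
  }
  forced_stop <- check_codon(forced_stop)
  if (!forced_stop %in% STOP_CODONS) {
    stop("forced_stop must be one of TAA/TAG/TGA")
  }
  pos <- which(strsplit(codon, "")[[1]] != strsplit(forced_stop, "")[[1]])
  new_substitution_plan(codon, pos, forced_stop)
}
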