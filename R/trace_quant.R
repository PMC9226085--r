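# Quantification of A-to-I editing from Sanger clone sequences: local
# pairwise alignment of each clone to a supplied reference region, then the
# percentage of reference adenosines read as guanosine.

#' Align a clone sequence to a reference region
#'
#' Affine-gap local alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1); both clone orientations are tried and the better kept, so
#' reverse-complemented clones quantify identically. Identity is the
#' fraction of clone bases aligned and matching the reference, so a clone
#' whose best local hit covers only a small fragment is rejected as
#' non-matching (below `min_identity`) even if that fragment matches
#' perfectly.
#'
#' @param clone_seq clone sequence (at least 50 nt).
#' @param ref_seq reference region sequence.
#' @param clone_id identifier carried through.
#' @param min_identity minimum alignment identity (default 0.7).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list of class `clone_alignment` with aligned strings, identity,
#'   strand, n_adenosines_reference, n_A_read_as_G, n_other_mismatch;
#'   or NULL when rejected.
#' @export
align_clone <- function(clone_seq, ref_seq, clone_id = "clone",
                        min_identity = 0.7, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1) {
  if (nchar(clone_seq) < 50L)
    stopf("clone %s shorter than 50 nt", clone_id)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln_for <- function(s) Biostrings::pairwiseAlignment(
    pattern = s, subject = ref_seq, type = "local",
    substitutionMatrix = sm, gapOpening = -gap_open, gapExtension = -gap_extend)
  fwd <- aln_for(clone_seq)
  rev <- aln_for(revcomp(clone_seq))
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  aln <- if (use_rev) rev else fwd
  pat <- str_chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- str_chars(as.character(Biostrings::alignedSubject(aln)))
  ident <- sum(pat == sub & sub != "-" & pat != "-") / nchar(clone_seq)
  if (ident < min_identity) return(NULL)
  ref_A <- sub == "A" & pat != "-"   # gaps at A columns leave the denominator
  a2g <- sub == "A" & pat == "G"
  other_mm <- pat != sub & pat != "-" & sub != "-" & !a2g
  structure(list(clone_id = clone_id,
                 aligned_clone = paste(pat, collapse = ""),
                 aligned_reference = paste(sub, collapse = ""),
                 ref_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
                 strand = if (use_rev) "-" else "+",
                 identity = ident,
                 n_adenosines_reference = sum(ref_A),
                 n_A_read_as_G = sum(a2g),
                 n_other_mismatch = sum(other_mm)),
            class = "clone_alignment")
}

#' A-to-I editing percentage of an aligned clone
#'
#' 100 x (reference-A columns read as G) / (reference-A columns in the
#' aligned span); gap columns at reference adenosines are excluded from the
#' denominator. Undefined (NA, with a warning) when the span contains no
#' adenosines.
#'
#' @param aln a [align_clone()] result.
#' @return percentage in \[0, 100\].
#' @export
editing_percent <- function(aln) {
  if (aln$n_adenosines_reference == 0L) {
    warning("no reference adenosines in aligned span; editing undefined")
    return(NA_real_)
  }
  100 * aln$n_A_read_as_G / aln$n_adenosines_reference
}

#' Quantify a set of clones against one reference
#'
#' @param clones named character vector of clone sequences.
#' @param ref_seq reference region sequence.
#' @param ... passed to [align_clone()].
#' @return list with `per_clone` (data.frame: clone_id, identity, strand,
#'   n_A, n_A_to_G, percent; rejected clones carry NA) and `pooled`
#'   (percentage over all accepted clones' A columns pooled).
#' @export
quantify_clones <- function(clones, ref_seq, ...) {
  rows <- lapply(seq_along(clones), function(i) {
    id <- if (!is.null(names(clones))) names(clones)[i] else paste0("clone", i)
    aln <- align_clone(clones[i], ref_seq, clone_id = id, ...)
    if (is.null(aln))
      return(data.frame(clone_id = id, identity = NA_real_,
                        strand = NA_character_, n_A = NA_integer_,
                        n_A_to_G = NA_integer_, percent = NA_real_,
                        accepted = FALSE, stringsAsFactors = FALSE))
    data.frame(clone_id = id, identity = aln$identity, strand = aln$strand,
               n_A = aln$n_adenosines_reference, n_A_to_G = aln$n_A_read_as_G,
               percent = suppressWarnings(editing_percent(aln)),
               accepted = TRUE, stringsAsFactors = FALSE)
  })
  per_clone <- do.call(rbind, rows)
  acc <- per_clone[per_clone$accepted, , drop = FALSE]
  pooled <- if (nrow(acc) && sum(acc$n_A) > 0)
    100 * sum(acc$n_A_to_G) / sum(acc$n_A) else NA_real_
  list(per_clone = per_clone, pooled = pooled)
}

#' Simulate Sanger clones with a per-adenosine editing probability
#'
#' Each clone is the reference with every adenosine independently read as
#' guanosine with probability `edit_prob`.
#'
#' @param ref_seq reference sequence.
#' @param n_clones number of clones.
#' @param edit_prob per-adenosine editing probability.
#' @param seed integer seed.
#' @return named character vector of clone sequences.
#' @export
simulate_clones <- function(ref_seq, n_clones, edit_prob, seed = 1L) {
  withr::with_seed(seed, {
    ch <- str_chars(ref_seq)
    a_idx <- which(ch == "A")
    vapply(seq_len(n_clones), function(i) {
      x <- ch
      flip <- a_idx[runif(length(a_idx)) < edit_prob]
      x[flip] <- "G"
      paste(x, collapse = "")
    }, "") |> setNames(sprintf("clone%03d", seq_len(n_clones)))
  })
}
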