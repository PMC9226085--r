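# Back-splice junction detection from non-linearly-mapped reads.
#
# Terminal anchors (default 20 nt) of each candidate read are aligned to the
# genome by exact k-mer lookup (1-mismatch fallback). A head-to-tail
# geometry -- the head anchor mapping downstream of the tail anchor, the
# reverse of a linear read -- marks a candidate back-splice. Anchors are
# extended inward until two genomic segments explain the full read; among
# consistent breakpoints the pair placing canonical GT..AG splice
# dinucleotides around the circularised intron boundaries is preferred,
# falling back to the leftmost consistent pair. Junctions are filtered for
# at least two unique supporting reads, anchor uniqueness with a score
# margin, and a maximum genomic span, then verified by searching the raw
# reads with an 80-bp back-spliced probe.

#' Terminal anchors of a read
#'
#' @param seq read sequence.
#' @param anchor_len anchor length (default 20).
#' @return list(head, tail) or NULL when the read is shorter than twice the
#'   anchor length.
#' @export
split_anchors <- function(seq, anchor_len = 20L) {
  n <- nchar(seq)
  if (n < 2L * anchor_len) return(NULL)
  list(head = substr(seq, 1L, anchor_len),
       tail = substr(seq, n - anchor_len + 1L, n))
}

#' Align one anchor to the genome by exact match
#'
#' Finds all exact loci of the anchor on both genome strands; when none
#' exist, retries allowing `max_mismatch` mismatches. The anchor is unique
#' when exactly one locus exists genome-wide; the score margin is the match
#' count of the best locus minus the second best (capped at the anchor
#' length when no second locus exists within tolerance).
#'
#' @param anchor anchor sequence.
#' @param genome_dna a `Biostrings::DNAString` of the contig.
#' @param genome_rc its reverse complement (computed when NULL).
#' @param max_mismatch fallback mismatch tolerance (default 1).
#' @return list(plus = 0-based plus-strand starts, n_total, is_unique,
#'   margin, mismatches).
#' @export
align_anchor <- function(anchor, genome_dna, genome_rc = NULL,
                         max_mismatch = 1L) {
  if (is.null(genome_rc)) genome_rc <- Biostrings::reverseComplement(genome_dna)
  fwd <- Biostrings::start(Biostrings::matchPattern(anchor, genome_dna))
  n_rev <- Biostrings::countPattern(anchor, genome_rc)
  mm <- 0L
  if (length(fwd) + n_rev == 0L && max_mismatch > 0L) {
    fwd <- Biostrings::start(Biostrings::matchPattern(
      anchor, genome_dna, max.mismatch = max_mismatch))
    n_rev <- Biostrings::countPattern(anchor, genome_rc,
                                      max.mismatch = max_mismatch)
    mm <- max_mismatch
  }
  n_total <- length(fwd) + n_rev
  margin <- NA_integer_
  if (n_total == 1L) {
    ## any additional locus within max_mismatch lowers the margin to the
    ## mismatch difference; none leaves the anchor effectively unambiguous
    n_loose <- Biostrings::countPattern(anchor, genome_dna,
                                        max.mismatch = max_mismatch) +
      Biostrings::countPattern(anchor, genome_rc, max.mismatch = max_mismatch)
    margin <- if (n_loose > 1L) max_mismatch - mm else nchar(anchor)
  }
  list(plus = fwd - 1L, n_total = n_total, is_unique = n_total == 1L,
       margin = margin, mismatches = mm)
}

## longest match length between a string and the genome starting at g0
## (forward) -- both must already agree on the first `known` bases
match_forward <- function(s_chars, g_chars, g0) {
  n <- length(s_chars)
  avail <- min(n, length(g_chars) - g0)
  if (avail <= 0L) return(0L)
  eq <- s_chars[seq_len(avail)] == g_chars[g0 + seq_len(avail)]
  if (all(eq)) avail else which.min(eq) - 1L
}

## longest suffix of s matching the genome ending (exclusive) at g_end0
match_backward <- function(s_chars, g_chars, g_end0) {
  n <- length(s_chars)
  avail <- min(n, g_end0)
  if (avail <= 0L) return(0L)
  eq <- s_chars[n - seq_len(avail) + 1L] == g_chars[g_end0 - seq_len(avail) + 1L]
  if (all(eq)) avail else which.min(eq) - 1L
}

splice_signal_ok <- function(g_chars, acceptor, donor, strand) {
  L <- length(g_chars)
  if (acceptor < 2L || donor + 2L > L) return(FALSE)
  after <- paste0(g_chars[donor + 1L], g_chars[donor + 2L])
  before <- paste0(g_chars[acceptor - 1L], g_chars[acceptor])
  if (strand == "+") after == "GT" && before == "AG"
  else after == "CT" && before == "AC"
}

detect_one_junction <- function(seq, genome_dna, genome_rc, g_chars,
                                anchor_len, max_mismatch) {
  n <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    an <- split_anchors(s, anchor_len)
    hh <- align_anchor(an$head, genome_dna, genome_rc, max_mismatch)
    if (!hh$is_unique || length(hh$plus) != 1L || hh$mismatches > 0L) next
    th <- align_anchor(an$tail, genome_dna, genome_rc, max_mismatch)
    if (!th$is_unique || length(th$plus) != 1L || th$mismatches > 0L) next
    g_h <- hh$plus[1]; g_t <- th$plus[1]
    if (g_h <= g_t) next   # linear order; not a back-splice on this strand
    s_chars <- str_chars(s)
    head_len <- match_forward(s_chars, g_chars, g_h)
    tail_len <- match_backward(s_chars, g_chars, g_t + anchor_len)
    p_lo <- max(anchor_len, n - tail_len)
    p_hi <- min(head_len, n - anchor_len)
    if (p_lo > p_hi) next
    ps <- p_lo:p_hi
    donors <- g_h + ps
    acceptors <- g_t + anchor_len - (n - ps)
    valid <- acceptors < donors
    if (!any(valid)) next
    ps <- ps[valid]; donors <- donors[valid]; acceptors <- acceptors[valid]
    sig <- vapply(seq_along(ps), function(i)
      splice_signal_ok(g_chars, acceptors[i], donors[i], strand), TRUE)
    pick <- if (any(sig)) which(sig)[1] else 1L
    return(data.frame(
      strand = strand, acceptor_pos = acceptors[pick], donor_pos = donors[pick],
      splice_signal = if (sig[pick]) "GT-AG" else "other",
      margin = min(hh$margin, th$margin), stringsAsFactors = FALSE))
  }
  NULL
}

#' Detect back-splice junctions from unmapped reads
#'
#' @param unmapped data.frame with read_id, seq (and optionally sample_id).
#' @param genome named character vector (single contig).
#' @param anchor_len anchor length (default 20).
#' @param max_mismatch anchor mismatch fallback tolerance (default 1).
#' @return list with `junctions` (one row per distinct breakpoint pair:
#'   chrom, strand, acceptor_pos, donor_pos, span, n_reads of distinct
#'   supporting read identities, splice_signal, margin),
#'   `support` (read-level hits) and `counters` (skipped-read accounting).
#' @export
detect_junctions <- function(unmapped, genome, anchor_len = 20L,
                             max_mismatch = 1L) {
  chrom <- names(genome)[1]
  genome_dna <- Biostrings::DNAString(genome[[1]])
  genome_rc <- Biostrings::reverseComplement(genome_dna)
  g_chars <- str_chars(toupper(genome[[1]]))
  counters <- c(too_short = 0L, no_junction = 0L)
  if (is.null(unmapped$sample_id)) unmapped$sample_id <- "pooled"
  support <- list()
  for (i in seq_len(nrow(unmapped))) {
    seq <- unmapped$seq[i]
    if (nchar(seq) < 2L * anchor_len) {
      counters["too_short"] <- counters["too_short"] + 1L
      next
    }
    j <- detect_one_junction(seq, genome_dna, genome_rc, g_chars, anchor_len,
                             max_mismatch)
    if (is.null(j)) {
      counters["no_junction"] <- counters["no_junction"] + 1L
      next
    }
    support[[length(support) + 1L]] <- cbind(
      data.frame(read_id = unmapped$read_id[i],
                 sample_id = unmapped$sample_id[i],
                 chrom = chrom, seq = seq, stringsAsFactors = FALSE), j)
  }
  empty_j <- data.frame(chrom = character(0), strand = character(0),
                        acceptor_pos = integer(0), donor_pos = integer(0),
                        span = integer(0), n_reads = integer(0),
                        splice_signal = character(0), margin = integer(0))
  if (!length(support))
    return(list(junctions = empty_j,
                support = data.frame(read_id = character(0),
                                     sample_id = character(0),
                                     seq = character(0)),
                counters = counters))
  support <- do.call(rbind, support)
  key <- paste(support$strand, support$acceptor_pos, support$donor_pos)
  junctions <- do.call(rbind, lapply(split(seq_len(nrow(support)), key),
    function(ii) {
      ## duplicate reads (identical sequence) count once as "unique reads"
      data.frame(chrom = chrom, strand = support$strand[ii[1]],
                 acceptor_pos = support$acceptor_pos[ii[1]],
                 donor_pos = support$donor_pos[ii[1]],
                 span = support$donor_pos[ii[1]] - support$acceptor_pos[ii[1]],
                 n_reads = length(unique(support$seq[ii])),
                 splice_signal = support$splice_signal[ii[1]],
                 margin = max(support$margin[ii]), stringsAsFactors = FALSE)
    }))
  rownames(junctions) <- NULL
  junctions <- junctions[order(junctions$acceptor_pos, junctions$donor_pos), ,
                         drop = FALSE]
  list(junctions = junctions, support = support, counters = counters)
}

#' Apply the junction-level filters
#'
#' Pass requires at least `min_reads` unique supporting reads, both anchors
#' unique with score margin at or above `min_margin`, and a genomic span
#' below `max_span`. Failures are recorded in `filter_status`, not dropped.
#'
#' @param junctions data.frame from [detect_junctions()].
#' @param min_reads minimum unique supporting reads (default 2).
#' @param max_span maximum genomic span in bp (default 100000).
#' @param min_margin minimum anchor score margin (default 2).
#' @return the input with `filter_status` (comma-joined failed filters, ""
#'   when clean) and `pass` columns.
#' @export
filter_junctions <- function(junctions, min_reads = 2L, max_span = 100000L,
                             min_margin = 2L) {
  status <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    failed <- character(0)
    if (junctions$n_reads[i] < min_reads) failed <- c(failed, "min_reads")
    if (is.na(junctions$margin[i]) || junctions$margin[i] < min_margin)
      failed <- c(failed, "anchor_margin")
    if (junctions$span[i] >= max_span) failed <- c(failed, "max_span")
    status[i] <- paste(failed, collapse = ",")
  }
  junctions$filter_status <- status
  junctions$pass <- status == ""
  junctions
}

#' Verify junctions against raw reads with a back-spliced probe
#'
#' Builds the back-spliced probe -- the last `flank` nt before the donor
#' breakpoint joined to the first `flank` nt from the acceptor breakpoint
#' (80 bp total by default) -- and marks the junction verified when at least
#' one raw read contains the probe (either orientation) with at most
#' `max_mismatch` mismatches. Probes near contig ends are truncated
#' symmetrically and flagged.
#'
#' @param junctions data.frame of junctions.
#' @param raw_seqs character vector of raw read sequences.
#' @param genome named character vector.
#' @param flank bases taken from each side of the joint (default 40).
#' @param max_mismatch mismatch tolerance of the probe search (default 2).
#' @return the input with `probe`, `probe_truncated` and `verified` columns.
#' @export
verify_junctions <- function(junctions, raw_seqs, genome, flank = 40L,
                             max_mismatch = 2L) {
  L <- nchar(genome[[1]])
  reads <- Biostrings::DNAStringSet(raw_seqs)
  probe <- character(nrow(junctions))
  truncated <- logical(nrow(junctions))
  verified <- logical(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    d <- junctions$donor_pos[i]; a <- junctions$acceptor_pos[i]
    h <- min(flank, d, L - a)
    truncated[i] <- h < flank
    pr <- paste0(substr0(genome[[1]], d - h, d), substr0(genome[[1]], a, a + h))
    probe[i] <- pr
    hits <- sum(Biostrings::vcountPattern(pr, reads,
                                          max.mismatch = max_mismatch)) +
      sum(Biostrings::vcountPattern(revcomp(pr), reads,
                                    max.mismatch = max_mismatch))
    verified[i] <- hits > 0L
  }
  junctions$probe <- probe
  junctions$probe_truncated <- truncated
  junctions$verified <- verified
  junctions
}

#' Per-sample BSS-spanning read counts
#'
#' Counts distinct supporting reads of each junction per sample and
#' normalises per million linearly mapped reads.
#'
#' @param support read-level support data.frame from [detect_junctions()].
#' @param samples data.frame with sample_id (and group).
#' @param n_linear named numeric vector: linearly mapped reads per sample.
#' @return list with `counts` and `cpm` matrices (junction key x sample).
#' @export
quantify_bss <- function(support, samples, n_linear) {
  key <- sprintf("%s:%d-%d:%s", support$chrom, support$acceptor_pos,
                 support$donor_pos, support$strand)
  jkeys <- sort(unique(key))
  counts <- matrix(0, nrow = length(jkeys), ncol = nrow(samples),
                   dimnames = list(jkeys, samples$sample_id))
  for (i in seq_along(jkeys)) {
    for (s in samples$sample_id) {
      ii <- key == jkeys[i] & support$sample_id == s
      counts[i, s] <- length(unique(support$seq[ii]))
    }
  }
  cpm <- sweep(counts, 2L, as.numeric(n_linear[samples$sample_id]), "/") * 1e6
  list(counts = counts, cpm = cpm)
}

#' Detect, filter and verify back-splice junctions in one call
#'
#' @param unmapped data.frame with read_id, seq, optional sample_id.
#' @param genome named character vector.
#' @param anchor_len,max_mismatch see [detect_junctions()].
#' @param min_reads,max_span,min_margin see [filter_junctions()].
#' @param flank,probe_mismatch see [verify_junctions()].
#' @param genes optional gene models for host annotation.
#' @return list(junctions, support, counters); junctions carry filter and
#'   verification columns plus host gene / origin class when `genes` given.
#' @export
detect_circs <- function(unmapped, genome, anchor_len = 20L,
                         max_mismatch = 1L, min_reads = 2L,
                         max_span = 100000L, min_margin = 2L, flank = 40L,
                         probe_mismatch = 2L, genes = NULL) {
  det <- detect_junctions(unmapped, genome, anchor_len, max_mismatch)
  j <- filter_junctions(det$junctions, min_reads, max_span, min_margin)
  j <- verify_junctions(j, unmapped$seq, genome, flank, probe_mismatch)
  if (!is.null(genes) && nrow(j)) {
    ann <- lapply(seq_len(nrow(j)), function(i)
      annotate_circ_origin(j$acceptor_pos[i], j$donor_pos[i], j$strand[i],
                           genes, j$chrom[i]))
    j$host_gene <- vapply(ann, function(a) as.character(a$gene_id), "")
    j$origin <- vapply(ann, function(a) a$origin, "")
  }
  j$circ_id <- sprintf("%s:%d-%d:%s", j$chrom, j$acceptor_pos, j$donor_pos,
                       j$strand)
  list(junctions = j, support = det$support, counters = det$counters)
}
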