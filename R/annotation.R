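# Gene segmentation, repeat context, and back-splice flanking introns.
#
# Segment labels partition every gene body: five_prime_utr / exon / intron /
# three_prime_utr inside genes, intergenic outside. UTRs are derived from an
# optional CDS span; genes without CDS have only exon/intron labels. When
# genes overlap, labels are resolved with precedence exon > UTR > intron.

SEGMENT_LEVELS <- c("five_prime_utr", "exon", "intron", "three_prime_utr",
                    "intergenic")

#' Segment table of one gene
#'
#' Splits the gene span into contiguous, non-overlapping labelled intervals
#' (0-based half-open) using the first transcript and the CDS span if present.
#'
#' @param gene a gene model.
#' @return data.frame with start, end, label.
#' @export
gene_segments <- function(gene) {
  ex <- gene_exons(gene)
  intr <- gene_introns(gene)
  segs <- list()
  add <- function(s, e, lab) {
    if (s < e) segs[[length(segs) + 1L]] <<- data.frame(start = s, end = e,
                                                        label = lab)
  }
  left_utr <- if (gene$strand == "-") "three_prime_utr" else "five_prime_utr"
  right_utr <- if (gene$strand == "-") "five_prime_utr" else "three_prime_utr"
  for (k in seq_len(nrow(ex))) {
    s <- ex$start[k]; e <- ex$end[k]
    if (is.null(gene$cds)) {
      add(s, e, "exon")
    } else {
      add(s, min(e, gene$cds[1]), left_utr)
      add(max(s, gene$cds[1]), min(e, gene$cds[2]), "exon")
      add(max(s, gene$cds[2]), e, right_utr)
    }
  }
  for (k in seq_len(nrow(intr))) add(intr$start[k], intr$end[k], "intron")
  out <- do.call(rbind, segs)
  out[order(out$start), , drop = FALSE]
}

#' Segment label of genomic positions
#'
#' @param pos integer vector of 0-based positions.
#' @param genes list of gene models.
#' @param chrom chromosome of the positions (single value).
#' @return data.frame with pos, segment, gene_id (`NA` when intergenic).
#'   Overlapping genes are resolved with precedence exon > UTR > intron.
#' @export
segment_of <- function(pos, genes, chrom = NULL) {
  n <- length(pos)
  label <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  rank <- rep(99L, n)  # lower wins
  prec <- c(exon = 1L, five_prime_utr = 2L, three_prime_utr = 2L, intron = 3L)
  for (gene in genes) {
    if (!is.null(chrom) && gene$chrom != chrom) next
    inside <- which(pos >= gene$start & pos < gene$end)
    if (!length(inside)) next
    segs <- gene_segments(gene)
    idx <- findInterval(pos[inside], segs$start)
    lab <- segs$label[idx]
    r <- prec[lab]
    take <- r < rank[inside]
    label[inside][take] <- lab[take]
    gene_id[inside][take] <- gene$gene_id
    rank[inside][take] <- r[take]
  }
  data.frame(pos = pos, segment = label, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Repeat context of genomic positions
#'
#' Classifies each position as inside an Alu element, inside a non-Alu
#' repeat, or nonrepetitive, with precedence alu > other repeat and ties
#' within a class broken by smallest element start.
#'
#' @param pos integer vector of 0-based positions.
#' @param repeats repeat data.frame from [read_bed()].
#' @param chrom chromosome of the positions.
#' @return data.frame with pos, repeat_class, family, element_start,
#'   element_strand.
#' @export
repeat_context <- function(pos, repeats, chrom = NULL) {
  if (!is.null(chrom)) repeats <- repeats[repeats$chrom == chrom, , drop = FALSE]
  ## precedence alu first, then by start, so the first overlap found wins
  o <- order(!repeats$is_alu, repeats$start)
  repeats <- repeats[o, , drop = FALSE]
  n <- length(pos)
  cls <- rep("nonrepetitive", n)
  fam <- rep(NA_character_, n)
  est <- rep(NA_integer_, n)
  estr <- rep(NA_character_, n)
  if (nrow(repeats)) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos + 1L, width = 1L),
      IRanges::IRanges(start = repeats$start + 1L, end = repeats$end),
      select = "first")
    hit <- which(!is.na(ov))
    j <- ov[hit]
    cls[hit] <- ifelse(repeats$is_alu[j], "alu", "non_alu_repeat")
    fam[hit] <- repeats$family[j]
    est[hit] <- repeats$start[j]
    estr[hit] <- repeats$strand[j]
  }
  data.frame(pos = pos, repeat_class = cls, family = fam,
             element_start = est, element_strand = estr,
             stringsAsFactors = FALSE)
}

## host gene whose exon boundaries coincide exactly with both breakpoints
find_host_gene <- function(acceptor_pos, donor_pos, genes, chrom) {
  for (gene in genes) {
    if (gene$chrom != chrom) next
    ex <- gene_exons(gene)
    if (any(ex$start == acceptor_pos) && any(ex$end == donor_pos))
      return(gene)
  }
  NULL
}

#' Introns flanking a back-splice site
#'
#' Returns the intron immediately upstream of the junction's 5' exon and the
#' intron immediately downstream of its 3' exon, in host-gene orientation
#' (genomic coordinates). A breakpoint at a terminal exon has no flank on
#' that side.
#'
#' @param acceptor_pos,donor_pos genomic breakpoints (0-based; acceptor <
#'   donor), each coinciding exactly with an exon boundary of the host gene.
#' @param genes list of gene models.
#' @param chrom chromosome of the junction.
#' @return list with `upstream` and `downstream`, each a list(start, end) or
#'   `NULL`, plus `gene_id`.
#' @export
flanking_introns <- function(acceptor_pos, donor_pos, genes, chrom) {
  gene <- find_host_gene(acceptor_pos, donor_pos, genes, chrom)
  if (is.null(gene))
    stopf("junction %s:%d-%d does not match exon boundaries of any gene",
          chrom, acceptor_pos, donor_pos)
  intr <- gene_introns(gene)
  left <- which(intr$end == acceptor_pos)    # intron ending at the left bp
  right <- which(intr$start == donor_pos)    # intron starting at the right bp
  as_flank <- function(i) if (length(i)) list(start = intr$start[i[1]],
                                              end = intr$end[i[1]]) else NULL
  if (gene$strand == "-") {
    ## transcript-upstream is genomically right of the junction
    list(upstream = as_flank(right), downstream = as_flank(left),
         gene_id = gene$gene_id)
  } else {
    list(upstream = as_flank(left), downstream = as_flank(right),
         gene_id = gene$gene_id)
  }
}

#' Genomic origin class of a circRNA candidate
#'
#' Classifies the circle's genomic span against the exon/intron structure of
#' the overlapping gene: `exonic` when the span covers only exonic sequence,
#' `exon+intron` when it also retains intronic bases, `intronic` when fully
#' inside one intron, `antisense` when the only overlapping gene is on the
#' opposite strand, `intergenic` otherwise.
#'
#' @param acceptor_pos,donor_pos genomic breakpoints (0-based half-open span).
#' @param strand strand of the junction.
#' @param genes list of gene models.
#' @param chrom chromosome.
#' @return list(origin, gene_id).
#' @export
annotate_circ_origin <- function(acceptor_pos, donor_pos, strand, genes,
                                 chrom) {
  overlapping <- Filter(function(g)
    g$chrom == chrom && g$start < donor_pos && g$end > acceptor_pos, genes)
  if (!length(overlapping)) return(list(origin = "intergenic", gene_id = NA))
  same <- Filter(function(g) g$strand == strand, overlapping)
  if (!length(same)) {
    return(list(origin = "antisense", gene_id = overlapping[[1]]$gene_id))
  }
  gene <- same[[1]]
  intr <- gene_introns(gene)
  in_intron <- nrow(intr) > 0 &&
    any(intr$start <= acceptor_pos & intr$end >= donor_pos)
  if (in_intron) return(list(origin = "intronic", gene_id = gene$gene_id))
  retains_intron <- nrow(intr) > 0 &&
    any(intr$start < donor_pos & intr$end > acceptor_pos)
  list(origin = if (retains_intron) "exon+intron" else "exonic",
       gene_id = gene$gene_id)
}
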