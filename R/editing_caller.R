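# RNA editing site calling from pileups: candidate mismatch detection with a
# sequencing-error noise guard, SNP exclusion against a known-variant set and
# matched DNA, substitution typing (A>G / T>C read out as A-to-I), and
# per-segment / per-Alu-position summaries.

#' Pileup of aligned reads over a genome
#'
#' Tallies base counts per position from linearly mapped reads. Bases below
#' `min_base_quality`, reads below `min_mapping_quality`, and positions
#' within `trim_ends` bases of either read end are excluded; insertions are
#' skipped and deletions contribute nothing.
#'
#' @param reads SAM-style data.frame from [read_alignments()].
#' @param genome named character vector (single contig supported per call).
#' @param min_base_quality minimum Phred base quality (default 25).
#' @param min_mapping_quality minimum mapping quality (default 20).
#' @param trim_ends bases masked at each read end (default 5; 0 disables).
#' @return object of class `pileup`: list with `chrom`, `ref` (character
#'   vector of reference bases), `counts` (4 x L integer matrix, rows
#'   A,C,G,T) and `n_reads_used`.
#' @export
pileup <- function(reads, genome, min_base_quality = 25L,
                   min_mapping_quality = 20L, trim_ends = 5L) {
  chrom <- names(genome)[1]
  L <- nchar(genome[[1]])
  keep <- reads$is_linear_mapped & reads$mapq >= min_mapping_quality
  bad_ref <- keep & reads$chrom != chrom
  if (any(bad_ref))
    stopf("pileup: read %s aligned to unknown reference '%s'",
          reads$read_id[bad_ref][1], reads$chrom[bad_ref][1])
  r <- reads[keep, , drop = FALSE]
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))

  simple <- grepl("^[0-9]+M$", r$cigar)
  tally <- function(pos0, qpos, seqs, quals, lens) {
    ## pos0: 0-based ref position per base; qpos: 1-based query offset
    bases <- str_chars(paste(seqs, collapse = ""))
    qv <- utf8ToInt(paste(quals, collapse = "")) - 33L
    keepb <- qv >= min_base_quality & bases %in% DNA_BASES
    if (trim_ends > 0L) {
      keepb <- keepb & qpos > trim_ends & qpos <= rep(lens, lens) - trim_ends
    }
    pos0 <- pos0[keepb]; bases <- bases[keepb]
    bi <- match(bases, DNA_BASES)
    inc <- tabulate((pos0) * 4L + bi, nbins = 4L * L)
    counts + matrix(inc, nrow = 4L)
  }

  if (any(simple)) {
    rs <- r[simple, , drop = FALSE]
    lens <- nchar(rs$seq)
    pos0 <- rep(rs$pos, lens) + (sequence(lens) - 1L)
    counts <- tally(pos0, sequence(lens), rs$seq, rs$qual, lens)
  }
  for (i in which(!simple)) {
    cg <- parse_cigar(r$cigar[i])
    rp <- r$pos[i]; qp <- 1L
    qlen <- nchar(r$seq[i])
    pos_list <- integer(0); qpos_list <- integer(0)
    for (k in seq_len(nrow(cg))) {
      op <- cg$op[k]; ln <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        pos_list <- c(pos_list, rp + seq_len(ln) - 1L)
        qpos_list <- c(qpos_list, qp + seq_len(ln) - 1L)
        rp <- rp + ln; qp <- qp + ln
      } else if (op %in% c("I", "S")) qp <- qp + ln
      else if (op %in% c("D", "N")) rp <- rp + ln
    }
    b <- str_chars(r$seq[i])[qpos_list]
    q <- (utf8ToInt(r$qual[i]) - 33L)[qpos_list]
    ok <- q >= min_base_quality & b %in% DNA_BASES
    if (trim_ends > 0L)
      ok <- ok & qpos_list > trim_ends & qpos_list <= qlen - trim_ends
    bi <- match(b[ok], DNA_BASES)
    for (j in seq_along(bi))
      counts[bi[j], pos_list[ok][j] + 1L] <- counts[bi[j], pos_list[ok][j] + 1L] + 1L
  }
  structure(list(chrom = chrom, ref = str_chars(toupper(genome[[1]])),
                 counts = counts, n_reads_used = nrow(r)),
            class = "pileup")
}

#' Non-empty pileup columns as a data.frame
#'
#' @param p a [pileup()] object.
#' @param min_depth keep columns with depth at least this (default 1).
#' @return data.frame with chrom, pos (0-based), ref, A, C, G, T, depth.
#' @export
pileup_columns <- function(p, min_depth = 1L) {
  depth <- colSums(p$counts)
  idx <- which(depth >= min_depth)
  data.frame(chrom = p$chrom, pos = idx - 1L, ref = p$ref[idx],
             A = p$counts["A", idx], C = p$counts["C", idx],
             G = p$counts["G", idx], T = p$counts["T", idx],
             depth = depth[idx], stringsAsFactors = FALSE)
}

## alt fraction of a specific base at specific positions of a pileup
pileup_alt_fraction <- function(p, pos, alt) {
  depth <- colSums(p$counts[, pos + 1L, drop = FALSE])
  altc <- p$counts[cbind(match(alt, DNA_BASES), pos + 1L)]
  list(depth = depth, alt = altc,
       fraction = ifelse(depth > 0, altc / depth, NA_real_))
}

#' Call candidate editing sites from pileup columns
#'
#' A column is a candidate when exactly one non-reference base reaches
#' `min_alt_reads`, total depth reaches `min_depth`, and all remaining
#' non-reference bases together stay at or below `max_noise` x depth (the
#' sequencing-error guard). The editing ratio is alt reads / depth.
#'
#' @param p a [pileup()] object.
#' @param min_alt_reads minimum reads carrying the variant base (default 3).
#' @param min_depth minimum column depth (default 5).
#' @param max_noise maximum tolerated fraction of other non-reference bases
#'   (default 0.05).
#' @return data.frame of candidate sites: chrom, pos, ref, alt, edited_reads,
#'   total_reads, editing_ratio.
#' @export
call_candidates <- function(p, min_alt_reads = 3L, min_depth = 5L,
                            max_noise = 0.05) {
  depth <- colSums(p$counts)
  covered <- which(depth >= min_depth & p$ref %in% DNA_BASES)
  if (!length(covered))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      edited_reads = integer(0), total_reads = integer(0),
                      editing_ratio = numeric(0)))
  cnt <- p$counts[, covered, drop = FALSE]
  ref_idx <- match(p$ref[covered], DNA_BASES)
  ref_cnt <- cnt[cbind(ref_idx, seq_along(covered))]
  alt_cnt <- cnt
  alt_cnt[cbind(ref_idx, seq_along(covered))] <- 0L
  n_strong <- colSums(alt_cnt >= min_alt_reads)
  top <- apply(alt_cnt, 2L, max)
  top_idx <- apply(alt_cnt, 2L, which.max)
  noise <- colSums(alt_cnt) - top
  ok <- n_strong == 1L & top >= min_alt_reads &
    noise <= max_noise * depth[covered]
  idx <- which(ok)
  if (!length(idx))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      edited_reads = integer(0), total_reads = integer(0),
                      editing_ratio = numeric(0)))
  data.frame(chrom = p$chrom, pos = covered[idx] - 1L,
             ref = p$ref[covered][idx], alt = DNA_BASES[top_idx[idx]],
             edited_reads = as.integer(top[idx]),
             total_reads = as.integer(depth[covered][idx]),
             editing_ratio = top[idx] / depth[covered][idx],
             stringsAsFactors = FALSE)
}

#' Exclude SNPs from candidate editing sites
#'
#' Removes candidates at known-variant positions and, when a matched DNA
#' pileup is supplied, candidates whose DNA alternative-allele fraction
#' exceeds `max_dna_alt_fraction` at DNA depth >= `min_dna_depth` (a naive
#' genotype check: a heterozygous SNP shows the variant in DNA at about 0.5,
#' a true editing site does not appear in DNA at all).
#'
#' @param candidates data.frame from [call_candidates()].
#' @param known_snps data.frame from [read_vcf_sites()] (or NULL).
#' @param dna_pileup optional [pileup()] of matched DNA reads.
#' @param max_dna_alt_fraction DNA alt fraction above which a candidate is
#'   called a SNP (default 0.1).
#' @param min_dna_depth minimum DNA depth for the check (default 10).
#' @return list with `sites` (surviving candidates) and `removed` (dropped
#'   candidates with a `reason` column: "known_vcf" or "dna_check").
#' @export
exclude_snps <- function(candidates, known_snps = NULL, dna_pileup = NULL,
                         max_dna_alt_fraction = 0.1, min_dna_depth = 10L) {
  reason <- rep(NA_character_, nrow(candidates))
  if (!is.null(known_snps) && nrow(known_snps)) {
    hit <- paste(candidates$chrom, candidates$pos) %in%
      paste(known_snps$chrom, known_snps$pos)
    reason[hit] <- "known_vcf"
  }
  if (!is.null(dna_pileup) && nrow(candidates)) {
    unresolved <- which(is.na(reason))
    if (length(unresolved)) {
      af <- pileup_alt_fraction(dna_pileup, candidates$pos[unresolved],
                                candidates$alt[unresolved])
      snp_like <- af$depth >= min_dna_depth & !is.na(af$fraction) &
        af$fraction > max_dna_alt_fraction
      reason[unresolved[snp_like]] <- "dna_check"
    }
  }
  list(sites = candidates[is.na(reason), , drop = FALSE],
       removed = cbind(candidates[!is.na(reason), , drop = FALSE],
                       reason = reason[!is.na(reason)]))
}

#' Type the substitution of called sites
#'
#' Substitutions are typed on the genomic plus strand (12 classes, A>C ...
#' T>G); A>G and T>C are the dual readout of A-to-I editing (inosine is read
#' as guanosine; T>C is the appearance of editing on the opposite strand).
#'
#' @param sites data.frame with ref and alt columns.
#' @return the input with `substitution_type` and `is_AtoI` columns added.
#' @export
type_substitution <- function(sites) {
  sites$substitution_type <- paste0(sites$ref, ">", sites$alt)
  sites$is_AtoI <- sites$substitution_type %in% c("A>G", "T>C")
  sites
}

#' Call editing sites for one sample
#'
#' Full per-sample caller: pileup, candidate calling, SNP exclusion,
#' substitution typing, and segment/repeat annotation.
#'
#' @param rna_reads SAM-style data.frame of RNA alignments.
#' @param genome named character vector.
#' @param genes list of gene models.
#' @param repeats repeat data.frame.
#' @param known_snps known-variant data.frame (or NULL).
#' @param dna_reads optional SAM-style data.frame of matched DNA alignments.
#' @param sample_id recorded on every site.
#' @param min_base_quality,min_mapping_quality,trim_ends see [pileup()].
#' @param min_alt_reads,min_depth,max_noise see [call_candidates()].
#' @param max_dna_alt_fraction,min_dna_depth see [exclude_snps()].
#' @return data.frame of editing sites with annotation columns.
#' @export
call_editing_sites <- function(rna_reads, genome, genes, repeats,
                               known_snps = NULL, dna_reads = NULL,
                               sample_id = "sample",
                               min_base_quality = 25L,
                               min_mapping_quality = 20L, trim_ends = 5L,
                               min_alt_reads = 3L, min_depth = 5L,
                               max_noise = 0.05,
                               max_dna_alt_fraction = 0.1,
                               min_dna_depth = 10L) {
  p <- pileup(rna_reads, genome, min_base_quality, min_mapping_quality,
              trim_ends)
  cand <- call_candidates(p, min_alt_reads, min_depth, max_noise)
  dna_p <- if (!is.null(dna_reads))
    pileup(dna_reads, genome, min_base_quality, min_mapping_quality, trim_ends)
  else NULL
  kept <- exclude_snps(cand, known_snps, dna_p, max_dna_alt_fraction,
                       min_dna_depth)
  sites <- type_substitution(kept$sites)
  if (nrow(sites)) {
    seg <- segment_of(sites$pos, genes, chrom = sites$chrom[1])
    rc <- repeat_context(sites$pos, repeats, chrom = sites$chrom[1])
    sites$segment <- seg$segment
    sites$gene_id <- seg$gene_id
    sites$repeat_class <- rc$repeat_class
    sites$repeat_family <- rc$family
  } else {
    sites$segment <- character(0); sites$gene_id <- character(0)
    sites$repeat_class <- character(0); sites$repeat_family <- character(0)
  }
  sites$sample_id <- rep(sample_id, nrow(sites))
  attr(sites, "removed") <- kept$removed
  rownames(sites) <- NULL
  sites
}

#' Per-gene/segment editing summaries
#'
#' For every (gene, segment) combination that carries at least one editing
#' site: the number of sites, the summed genomic length of that segment
#' class within the gene, and the mean editing ratio.
#'
#' @param sites data.frame from [call_editing_sites()] (one or more samples).
#' @param genes list of gene models.
#' @return data.frame with gene_id, segment, chrom, start, end, strand,
#'   n_sites, segment_length, mean_editing_ratio.
#' @export
summarize_segments <- function(sites, genes) {
  sites <- sites[!is.na(sites$gene_id), , drop = FALSE]
  if (!nrow(sites))
    return(data.frame(gene_id = character(0), segment = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_sites = integer(0), segment_length = integer(0),
                      mean_editing_ratio = numeric(0)))
  key <- paste(sites$gene_id, sites$segment, sep = "|")
  out <- lapply(split(seq_len(nrow(sites)), key), function(ii) {
    gid <- sites$gene_id[ii[1]]; seg <- sites$segment[ii[1]]
    gene <- genes[[gid]]
    st <- gene_segments(gene)
    st <- st[st$label == seg, , drop = FALSE]
    data.frame(gene_id = gid, segment = seg, chrom = gene$chrom,
               start = min(st$start), end = max(st$end), strand = gene$strand,
               n_sites = length(ii),
               segment_length = sum(st$end - st$start),
               mean_editing_ratio = mean(sites$editing_ratio[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene_id, out$segment), , drop = FALSE]
}

#' Per-adenosine A-to-I ratio profile along an Alu element
#'
#' For every adenosine of the element's sense strand (element-local 1-based
#' index along the sense strand), the A-to-I ratio is edited reads (G on the
#' plus strand, C on the minus strand) divided by total reads, averaged
#' across samples within each group.
#'
#' @param element one row of a repeat data.frame (start, end, strand).
#' @param pileups_by_group named list (group -> list of [pileup()] objects).
#' @param genome named character vector.
#' @return data.frame with element_pos, pos (genomic 0-based), and one ratio
#'   column per group. Zero-coverage elements yield an empty profile with a
#'   warning.
#' @export
per_position_profile <- function(element, pileups_by_group, genome) {
  seq_el <- substr0(genome[[1]], element$start, element$end)
  ch <- str_chars(seq_el)
  plus <- element$strand == "+"
  sense_A <- which(ch == if (plus) "A" else "T")      # 1-based within element
  gpos <- element$start + sense_A - 1L                # 0-based genomic
  el_pos <- if (plus) sense_A else (element$end - element$start) - sense_A + 1L
  edited_base <- if (plus) "G" else "C"
  out <- data.frame(element_pos = el_pos, pos = gpos)
  any_cov <- FALSE
  for (grp in names(pileups_by_group)) {
    ratios <- vapply(pileups_by_group[[grp]], function(p) {
      af <- pileup_alt_fraction(p, gpos, rep(edited_base, length(gpos)))
      if (any(af$depth > 0)) any_cov <<- TRUE
      mean_frac <- af$fraction
      mean_frac
    }, numeric(length(gpos)))
    ratios <- matrix(ratios, nrow = length(gpos))
    out[[paste0("ratio_", grp)]] <- rowMeans(ratios, na.rm = TRUE)
  }
  if (!any_cov) {
    warning("element has zero coverage; empty profile")
    return(out[0, , drop = FALSE])
  }
  out[order(out$element_pos), , drop = FALSE]
}

#' Mean editing events per gene and group
#'
#' Counts called editing sites per gene and sample, compares group means per
#' gene with the normality-gated test, and partitions genes into reduced /
#' increased editing by direction of the group-mean difference. Genes with
#' zero sites in all samples are excluded.
#'
#' @param sites combined per-sample sites (needs gene_id and sample_id).
#' @param samples data.frame with sample_id and group.
#' @return data.frame with gene_id, mean per group, direction
#'   ("reduced"/"increased" in the non-reference group), p_value, test.
#' @export
mean_events_per_gene <- function(sites, samples) {
  sites <- sites[!is.na(sites$gene_id), , drop = FALSE]
  genes <- unique(sites$gene_id)
  groups <- unique(samples$group)
  if (length(groups) != 2L) stopf("exactly two groups required")
  ref_grp <- groups[1]; alt_grp <- groups[2]
  out <- lapply(genes, function(g) {
    counts <- vapply(samples$sample_id, function(s)
      sum(sites$gene_id == g & sites$sample_id == s), 0L)
    v1 <- counts[samples$group == ref_grp]
    v2 <- counts[samples$group == alt_grp]
    tst <- run_group_test(list(v1, v2))
    data.frame(gene_id = g, mean_ref = mean(v1), mean_alt = mean(v2),
               direction = if (mean(v2) < mean(v1)) "reduced" else "increased",
               p_value = tst$p, test = tst$test, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[names(out) == "mean_ref"] <- paste0("mean_", ref_grp)
  names(out)[names(out) == "mean_alt"] <- paste0("mean_", alt_grp)
  out
}
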