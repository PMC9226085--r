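# Group statistics and the integration of editing with circRNA results:
# normality-gated test selection, differential circRNA analysis,
# host-independence classification, editing overlap in BSS-flanking introns,
# Alu-pair orientation counting, and correlation.

#' Choose the group-comparison test by the normality gate
#'
#' Sample values are first tested for Gaussian distribution (Shapiro-Wilk at
#' `alpha`). If every group passes: Student's t-test for two groups, one-way
#' ANOVA with Tukey's post hoc for more. Otherwise: Mann-Whitney U for two
#' unpaired groups, Wilcoxon matched-pairs signed-rank for paired, and
#' Kruskal-Wallis for more than two. Groups smaller than three values skip
#' the normality test and default to the nonparametric branch with a
#' warning.
#'
#' @param groups list of numeric vectors, one per group.
#' @param paired logical; two paired groups.
#' @param alpha normality-test significance level (default 0.05).
#' @return test name: one of "student_t", "anova_tukey", "mann_whitney",
#'   "wilcoxon_signed_rank", "kruskal_wallis".
#' @export
choose_test <- function(groups, paired = FALSE, alpha = 0.05) {
  k <- length(groups)
  stopifnot(k >= 2L)
  small <- any(vapply(groups, length, 0L) < 3L)
  normal <- FALSE
  if (small) {
    warning("group with fewer than 3 values; defaulting to nonparametric test")
  } else {
    normal <- all(vapply(groups, function(v) {
      if (length(unique(v)) == 1L) return(FALSE)  # degenerate: not Gaussian
      stats::shapiro.test(v)$p.value > alpha
    }, TRUE))
  }
  if (normal) {
    if (k == 2L) "student_t" else "anova_tukey"
  } else if (k == 2L) {
    if (paired) "wilcoxon_signed_rank" else "mann_whitney"
  } else "kruskal_wallis"
}

#' Run the normality-gated group comparison
#'
#' @param groups list of numeric vectors.
#' @param paired logical.
#' @param alpha normality gate level.
#' @return list(test, p, posthoc) where posthoc is the Tukey table for the
#'   ANOVA branch and NULL otherwise.
#' @export
run_group_test <- function(groups, paired = FALSE, alpha = 0.05) {
  if (all(vapply(groups, function(v) length(unique(v)), 0L) == 1L) &&
      length(unique(unlist(groups))) == 1L)
    return(list(test = "degenerate", p = 1, posthoc = NULL))
  test <- suppressWarnings(choose_test(groups, paired, alpha))
  p <- switch(test,
    student_t = stats::t.test(groups[[1]], groups[[2]],
                              var.equal = TRUE)$p.value,
    mann_whitney = suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE))$p.value,
    wilcoxon_signed_rank = suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], paired = TRUE,
                         exact = FALSE))$p.value,
    anova_tukey = , kruskal_wallis = {
      val <- unlist(groups)
      grp <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
      if (test == "kruskal_wallis") stats::kruskal.test(val, grp)$p.value
      else summary(stats::aov(val ~ grp))[[1]][["Pr(>F)"]][1]
    })
  posthoc <- NULL
  if (test == "anova_tukey") {
    val <- unlist(groups)
    grp <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    posthoc <- stats::TukeyHSD(stats::aov(val ~ grp))$grp
  }
  list(test = test, p = p, posthoc = posthoc)
}

#' Differential circRNA expression between two groups
#'
#' Per feature: the fold change of group means and the p-value of the
#' normality-gated test; significance at p < `alpha` with no multiple-testing
#' correction by default (a Benjamini-Hochberg option is available).
#' Features absent in all samples are excluded. A zero reference-group mean
#' with a non-zero comparison mean yields an infinite fold change, flagged.
#'
#' @param counts feature x sample numeric matrix (normalised counts).
#' @param groups character vector of group labels per column; the first
#'   unique label is the reference (fold change = mean(other)/mean(ref)).
#' @param alpha significance threshold (default 0.05).
#' @param p_adjust "none" (default) or any [stats::p.adjust()] method.
#' @return data.frame with feature_id, group means, fold_change, p_value,
#'   significant, direction, test.
#' @export
differential_circ <- function(counts, groups, alpha = 0.05,
                              p_adjust = "none") {
  glev <- unique(groups)
  stopifnot(length(glev) == 2L)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  out <- lapply(rownames(counts), function(f) {
    v1 <- counts[f, groups == glev[1]]
    v2 <- counts[f, groups == glev[2]]
    tst <- run_group_test(list(v1, v2))
    m1 <- mean(v1); m2 <- mean(v2)
    fc <- if (m1 > 0) m2 / m1 else if (m2 > 0) Inf else NA_real_
    data.frame(feature_id = f, mean_ref = m1, mean_alt = m2, fold_change = fc,
               p_value = tst$p, test = tst$test,
               direction = if (m2 >= m1) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(feature_id = character(0), mean_ref = numeric(0),
                      mean_alt = numeric(0), fold_change = numeric(0),
                      p_value = numeric(0), test = character(0),
                      direction = character(0), significant = logical(0)))
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  names(out)[names(out) == "mean_ref"] <- paste0("mean_", glev[1])
  names(out)[names(out) == "mean_alt"] <- paste0("mean_", glev[2])
  rownames(out) <- NULL
  out
}

#' Host-independence classification of regulated circRNAs
#'
#' A circRNA is host-independent when it is itself significantly regulated
#' while its host gene's mRNA is not (p >= alpha).
#'
#' @param circ_res differential table of circRNAs (feature_id, p_value,
#'   significant).
#' @param host_res differential table of host mRNAs (feature_id, p_value).
#' @param circ_host named character vector mapping circ feature_id to host
#'   gene feature_id.
#' @param alpha significance threshold.
#' @return circ_res with `host_gene`, `host_p` and `host_relation`
#'   ("host_independent", "host_coupled", or "unclassified") columns.
#' @export
host_independence <- function(circ_res, host_res, circ_host, alpha = 0.05) {
  circ_res$host_gene <- unname(circ_host[circ_res$feature_id])
  circ_res$host_p <- host_res$p_value[match(circ_res$host_gene,
                                            host_res$feature_id)]
  rel <- rep("unclassified", nrow(circ_res))
  known <- !is.na(circ_res$host_gene) & !is.na(circ_res$host_p)
  rel[known & circ_res$significant & circ_res$host_p >= alpha] <-
    "host_independent"
  rel[known & circ_res$significant & circ_res$host_p < alpha] <- "host_coupled"
  rel[known & !circ_res$significant] <- "not_regulated"
  circ_res$host_relation <- rel
  circ_res
}

#' Overlap editing events with BSS-flanking introns
#'
#' For each regulated circRNA, counts per sample the editing sites falling
#' in the upstream and downstream flanking introns (half-open intervals),
#' compares groups on the joint count with the normality-gated test, and
#' reports the split by flank. Circles at a terminal exon lack that flank;
#' they are excluded from the split view on the missing side.
#'
#' @param junctions data.frame with circ_id, chrom, acceptor_pos, donor_pos.
#' @param sites editing sites across samples (pos, sample_id).
#' @param genes gene models.
#' @param samples data.frame with sample_id, group.
#' @return list with `per_sample` (circ_id, sample_id, group, n_upstream,
#'   n_downstream, n_total) and `tests` (per circ: group means and p).
#' @export
overlap_editing_flanks <- function(junctions, sites, genes, samples) {
  per_sample <- list()
  for (i in seq_len(nrow(junctions))) {
    fl <- flanking_introns(junctions$acceptor_pos[i], junctions$donor_pos[i],
                           genes, junctions$chrom[i])
    count_in <- function(flank, s)
      if (is.null(flank)) NA_integer_ else
        sum(sites$sample_id == s & sites$pos >= flank$start &
              sites$pos < flank$end)
    for (s in samples$sample_id) {
      up <- count_in(fl$upstream, s)
      dn <- count_in(fl$downstream, s)
      per_sample[[length(per_sample) + 1L]] <- data.frame(
        circ_id = junctions$circ_id[i], sample_id = s,
        group = samples$group[match(s, samples$sample_id)],
        n_upstream = up, n_downstream = dn,
        n_total = sum(c(up, dn), na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, per_sample)
  glev <- unique(samples$group)
  tests <- do.call(rbind, lapply(unique(per_sample$circ_id), function(cid) {
    d <- per_sample[per_sample$circ_id == cid, , drop = FALSE]
    v1 <- d$n_total[d$group == glev[1]]
    v2 <- d$n_total[d$group == glev[2]]
    tst <- run_group_test(list(v1, v2))
    data.frame(circ_id = cid, mean_ref = mean(v1), mean_alt = mean(v2),
               direction = if (mean(v2) < mean(v1)) "down" else "up",
               p_value = tst$p, test = tst$test, stringsAsFactors = FALSE)
  }))
  names(tests)[names(tests) == "mean_ref"] <- paste0("mean_", glev[1])
  names(tests)[names(tests) == "mean_alt"] <- paste0("mean_", glev[2])
  list(per_sample = per_sample, tests = tests)
}

#' Alu pair orientation counts in the flanking introns of a circRNA
#'
#' Every (upstream-intron Alu, downstream-intron Alu) pair is classified by
#' the strand combination of its genomically left and right elements:
#' convergent (left +, right -; arrows facing), divergent (left -, right +),
#' or same orientation. Convergent plus divergent pairs are the inverted,
#' circularisation-competent configurations.
#'
#' @param acceptor_pos,donor_pos,chrom junction breakpoints.
#' @param repeats repeat data.frame.
#' @param genes gene models.
#' @return list(n_convergent, n_divergent, n_same_orientation, n_inverted,
#'   n_upstream_alu, n_downstream_alu).
#' @export
alu_pair_orientation <- function(acceptor_pos, donor_pos, chrom, repeats,
                                 genes) {
  fl <- flanking_introns(acceptor_pos, donor_pos, genes, chrom)
  alus_in <- function(flank) {
    if (is.null(flank))
      return(repeats[0, , drop = FALSE])
    repeats[repeats$is_alu & repeats$chrom == chrom &
              repeats$start < flank$end & repeats$end > flank$start, ,
            drop = FALSE]
  }
  up <- alus_in(fl$upstream)
  dn <- alus_in(fl$downstream)
  ## orientation is strand-pair symmetric, so count in genomic left/right
  ## order regardless of host-gene strand
  lr <- list(up, dn)
  left <- lr[[which.min(c(flank_start(fl$upstream), flank_start(fl$downstream)))]]
  right <- lr[[which.max(c(flank_start(fl$upstream), flank_start(fl$downstream)))]]
  n_conv <- sum(left$strand == "+") * sum(right$strand == "-")
  n_div <- sum(left$strand == "-") * sum(right$strand == "+")
  n_same <- sum(left$strand == "+") * sum(right$strand == "+") +
    sum(left$strand == "-") * sum(right$strand == "-")
  list(n_convergent = n_conv, n_divergent = n_div,
       n_same_orientation = n_same, n_inverted = n_conv + n_div,
       n_upstream_alu = nrow(up), n_downstream_alu = nrow(dn))
}

flank_start <- function(flank) if (is.null(flank)) Inf else flank$start

#' Correlate circRNA expression with host-gene expression
#'
#' Pearson when both vectors pass the normality gate, Spearman otherwise.
#' Requires at least five paired observations; constant vectors are flagged
#' as undefined.
#'
#' @param circ_counts,host_expr paired numeric vectors.
#' @param alpha normality gate level.
#' @return list(method, estimate, p) or list(flag = ...) when undefined.
#' @export
correlate_circ_host <- function(circ_counts, host_expr, alpha = 0.05) {
  n <- length(circ_counts)
  if (n != length(host_expr) || n < 5L)
    return(list(flag = "need at least 5 paired observations",
                method = NA, estimate = NA_real_, p = NA_real_))
  if (stats::sd(circ_counts) == 0 || stats::sd(host_expr) == 0)
    return(list(flag = "constant vector; correlation undefined",
                method = NA, estimate = NA_real_, p = NA_real_))
  normal <- all(vapply(list(circ_counts, host_expr), function(v)
    stats::shapiro.test(v)$p.value > alpha, TRUE))
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(circ_counts, host_expr,
                                         method = method, exact = FALSE))
  list(method = method, estimate = unname(ct$estimate), p = ct$p.value)
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param count fragments assigned to the gene.
#' @param length_bp transcript length in bp (> 0).
#' @param mapped_total total mapped fragments (> 0).
#' @return FPKM value(s).
#' @export
fpkm <- function(count, length_bp, mapped_total) {
  if (any(length_bp <= 0)) stopf("fpkm: length must be positive")
  if (any(mapped_total <= 0)) stopf("fpkm: mapped total must be positive")
  count / (length_bp / 1000 * mapped_total / 1e6)
}
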