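# End-to-end orchestration: simulate -> editing call -> circRNA detection ->
# integration, with all tables written to one output directory and a JSON +
# markdown report stamped with the seed and a config hash.

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, dataframe = "columns"), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes all stages in dependency order on data generated from `config`:
#' genome/annotation simulation, per-sample RNA and DNA read simulation,
#' per-sample editing-site calling with SNP exclusion, pooled back-splice
#' junction detection with filtering and probe verification, per-sample BSS
#' quantification, differential circRNA and host-gene analysis,
#' editing-overlap of BSS-flanking introns, and Alu-pair orientation counts.
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV plus a `report.json` and `report.md`.
#' @param dna use matched DNA for SNP exclusion (default TRUE).
#' @return list with every stage's results and a `report` summary list.
#' @export
run_pipeline <- function(config, out_dir = NULL, dna = TRUE) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[circedit] stage %-12s %s", name,
                    format(Sys.time(), "%H:%M:%S")))
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- stage("simulate", build_genome(config))
  samples <- sim$manifest$samples
  known <- sim$snps[sim$snps$known, c("chrom", "pos", "ref", "alt"),
                    drop = FALSE]

  rna <- list(); dna_reads <- list()
  stage("reads", for (s in samples$sample_id) {
    rna[[s]] <- simulate_rna_reads(sim, s)
    if (dna) dna_reads[[s]] <- simulate_dna_reads(sim, s)
  })
  n_linear <- vapply(rna, function(r) r$n_linear, 0)

  sites <- stage("edit-call", do.call(rbind, lapply(samples$sample_id,
    function(s) call_editing_sites(rna[[s]]$reads, sim$genome, sim$genes,
                                   sim$repeats, known,
                                   dna_reads = dna_reads[[s]],
                                   sample_id = s))))

  unmapped <- do.call(rbind, lapply(samples$sample_id, function(s)
    cbind(rna[[s]]$unmapped, sample_id = s)))
  circ <- stage("circ-detect",
                detect_circs(unmapped, sim$genome, genes = sim$genes,
                             anchor_len = config$anchor_len))
  quant <- quantify_bss(circ$support, samples, n_linear)

  integ <- stage("integrate", {
    groups <- samples$group
    circ_diff <- differential_circ(quant$cpm, groups)

    ## host mRNA expression as FPKM over each gene's pre-mRNA span
    gene_len <- vapply(sim$genes, function(g) g$end - g$start, 0)
    host_counts <- vapply(samples$sample_id, function(s) {
      r <- rna[[s]]$reads
      vapply(sim$genes, function(g)
        sum(r$pos < g$end & r$end > g$start), 0)
    }, numeric(length(sim$genes)))
    if (is.null(dim(host_counts)))   # single-gene case drops to a vector
      host_counts <- matrix(host_counts, nrow = 1L,
                            dimnames = list(names(sim$genes),
                                            samples$sample_id))
    host_fpkm <- sweep(host_counts / (gene_len / 1000), 2L,
                       n_linear[samples$sample_id] / 1e6, "/")
    host_diff <- differential_circ(host_fpkm, groups)

    pass <- circ$junctions[circ$junctions$pass, , drop = FALSE]
    circ_host <- setNames(pass$host_gene, pass$circ_id)
    circ_diff2 <- host_independence(circ_diff, host_diff,
                                    circ_host[circ_diff$feature_id])
    ## match circ feature keys (strand:acceptor:donor) back to junction ids
    flank <- if (nrow(pass))
      overlap_editing_flanks(pass, sites, sim$genes, samples) else NULL
    orientation <- if (nrow(pass)) do.call(rbind, lapply(
      seq_len(nrow(pass)), function(i) {
        o <- alu_pair_orientation(pass$acceptor_pos[i], pass$donor_pos[i],
                                  pass$chrom[i], sim$repeats, sim$genes)
        cbind(data.frame(circ_id = pass$circ_id[i]), as.data.frame(o))
      })) else NULL
    gene_events <- if (nrow(sites)) mean_events_per_gene(sites, samples)
      else NULL
    list(circ_diff = circ_diff2, host_diff = host_diff, flank = flank,
         orientation = orientation, gene_events = gene_events,
         host_fpkm = host_fpkm)
  })

  seg_summary <- summarize_segments(sites, sim$genes)
  subst_table <- as.data.frame(table(substitution = sites$substitution_type),
                               stringsAsFactors = FALSE)
  origin_table <- if (nrow(circ$junctions))
    as.data.frame(table(origin = circ$junctions$origin[circ$junctions$pass]),
                  stringsAsFactors = FALSE) else NULL

  report <- list(
    seed = config$seed, config_md5 = config_hash(config),
    n_samples = nrow(samples), genome_length = sim$manifest$genome_length,
    n_editing_sites_called = nrow(sites),
    pct_AtoI = if (nrow(sites)) 100 * mean(sites$is_AtoI) else NA,
    n_junctions_detected = nrow(circ$junctions),
    n_junctions_pass = sum(circ$junctions$pass),
    n_circ_significant = sum(integ$circ_diff$significant),
    substitution_types = subst_table, origin_classes = origin_table,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(sim = sim, rna = rna, dna = dna_reads, sites = sites,
              circ = circ, quant = quant, integration = integ,
              segment_summary = seg_summary, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(sites, file.path(out_dir, "editing_sites.tsv"))
    write_editing_bed(seg_summary, file.path(out_dir, "editing_summary.bed"))
    write_tsv(circ$junctions, file.path(out_dir, "junctions.tsv"))
    write_tsv(as.data.frame(quant$counts), file.path(out_dir, "bss_counts.tsv"))
    write_tsv(integ$circ_diff, file.path(out_dir, "circ_differential.tsv"))
    write_tsv(integ$host_diff, file.path(out_dir, "host_differential.tsv"))
    if (!is.null(integ$flank)) {
      write_tsv(integ$flank$per_sample, file.path(out_dir, "flank_overlap.tsv"))
      write_tsv(integ$flank$tests, file.path(out_dir, "flank_tests.tsv"))
    }
    if (!is.null(integ$orientation))
      write_tsv(integ$orientation, file.path(out_dir, "alu_orientation.tsv"))
    if (!is.null(integ$gene_events))
      write_tsv(integ$gene_events, file.path(out_dir, "gene_editing_events.tsv"))
    report_nodf <- report
    jsonlite::write_json(report_nodf, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    md <- c(sprintf("# circedit run (seed %d, config %s)", report$seed,
                    report$config_md5),
            sprintf("- editing sites called: %d (%.1f%% A-to-I)",
                    report$n_editing_sites_called, report$pct_AtoI),
            sprintf("- junctions: %d detected, %d passing filters",
                    report$n_junctions_detected, report$n_junctions_pass),
            sprintf("- significant circRNAs: %d", report$n_circ_significant))
    writeLines(md, file.path(out_dir, "report.md"))
  }
  invisible(res)
}

#' File-based editing call (reads every input from disk)
#'
#' Thin wrapper over [call_editing_sites()] for shell-driven use; aborts
#' with an explicit message when an input file is missing.
#'
#' @param rna_sam,genome_fa,gtf,repeats_bed,vcf,dna_sam input paths
#'   (`dna_sam` optional).
#' @param out_dir output directory for the per-site TSV and summary BED.
#' @param sample_id sample label.
#' @param ... thresholds passed to [call_editing_sites()].
#' @return the editing-site data.frame, invisibly.
#' @export
edit_call_files <- function(rna_sam, genome_fa, gtf, repeats_bed, vcf,
                            dna_sam = NULL, out_dir = ".",
                            sample_id = "sample", ...) {
  for (f in c(rna_sam, genome_fa, gtf, repeats_bed, vcf))
    if (!file.exists(f)) stopf("edit-call: required input missing: %s", f)
  genome <- read_fasta(genome_fa)
  genes <- read_gtf(gtf)
  repeats <- read_bed(repeats_bed)
  known <- read_vcf_sites(vcf)
  rna <- read_alignments(rna_sam)
  dna <- if (!is.null(dna_sam)) read_alignments(dna_sam) else NULL
  sites <- call_editing_sites(rna, genome, genes, repeats, known, dna,
                              sample_id = sample_id, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sites, file.path(out_dir, paste0("editing_sites_", sample_id,
                                             ".tsv")))
  write_editing_bed(summarize_segments(sites, genes),
                    file.path(out_dir, paste0("editing_summary_", sample_id,
                                              ".bed")))
  invisible(sites)
}
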