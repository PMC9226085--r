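# Synthetic-data generator: a miniature genome with genes, intronic Alu-like
# repeats, planted A-to-I editing (higher in controls than in the HF group),
# planted heterozygous SNPs, sequencing error, and back-splice junction reads,
# plus a machine-readable truth manifest used as the oracle by every
# downstream stage.
#
# RNA reads are drawn from contiguous pre-mRNA (total-RNA style libraries
# retain intronic coverage), so linear alignments never need spliced CIGARs.
# Editing is planted only at adenosines of the repeat's sense strand; for
# minus-strand Alu copies this appears genomically as T>C, giving the dual
# A>G / T>C readout expected of A-to-I editing.

## Fixed adenosine-rich 300-nt consensus used for every synthetic Alu-like
## insertion (each copy diverges from it by a configurable fraction).
ALU_CONSENSUS <- paste0(
  "TTATCGCACCGCTAGTTAGGTATTAGGTGTCTGCATAATCAGATGTTCTCAAGCACCAAGCTCGTAATCA",
  "AAAGACAAGAGAACCGAAAACAATTCAGCCCAAGTTCCGACTCGGGAACTAGGGCGTTACTCCTTGTACC",
  "AAGCCTATAACACGCCAAACTGCAGAGAAACGGGGATCCCTTAACCTCAAACAAAAGACCTGTGAGTGAA",
  "GCAAGTGAGTGAGTATAAAAAAAATTATGGAGAAGGAAGTAAAGACAGGCCAATGATATTACGATAAGGA",
  "GAATAAGAAATCAGAACCAA")

#' Simulation configuration
#'
#' Defines the study design emulated by the generator: a small genome of
#' multi-exon genes whose circularising exons are flanked by introns carrying
#' Alu-like repeats, per-site A-to-I editing rates that are reduced in the
#' heart-failure ("HF") group relative to controls, heterozygous SNPs (some
#' recorded in the known-variant VCF, some left for the matched-DNA check),
#' and back-splice junctions with per-group read support.
#'
#' @param seed integer master seed; every generator output is deterministic
#'   under it.
#' @param n_genes,exons_per_gene,exon_len,intron_len,utr_len,intergenic_len
#'   gene architecture (lengths in bp).
#' @param chrom contig name.
#' @param gene_strands character vector of gene strands (default alternates
#'   "+"/"-").
#' @param gene_biotypes character vector of biotypes per gene.
#' @param alu_placements data.frame(gene, intron, strand, family): transcript
#'   intron index receiving an Alu copy on the given genomic strand. Default:
#'   a convergent pair in the introns flanking the planted circRNA of each
#'   gene.
#' @param alu_divergence per-copy fraction of consensus positions mutated.
#' @param edits_per_alu planted A-to-I sites per Alu copy.
#' @param editing_rate_range control-group per-site editing rate range.
#' @param hf_editing_multiplier multiplicative change of editing rates in the
#'   HF group (default 0.5, i.e. halved).
#' @param n_snps_known,n_snps_hidden heterozygous A>G SNPs written to the
#'   known-variant VCF vs left only for the DNA-based check.
#' @param circ_plan data.frame(gene, from_exon, to_exon, reads_control,
#'   reads_hf): planted back-splice junctions (transcript exon numbering) and
#'   supporting reads per sample per group. Default: exons 2 to
#'   `exons_per_gene - 1` with 5 control / 20 HF reads (a 4x increase).
#' @param coverage,dna_coverage mean linear read coverage for RNA (over gene
#'   pre-mRNA) and DNA (over the genome).
#' @param read_len read length (must be at least twice `anchor_len`).
#' @param seq_error_rate per-base sequencing error probability.
#' @param n_control,n_hf samples per group.
#' @param base_qual_char FASTQ quality character for all bases.
#' @param anchor_len anchor length used downstream (validation only).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2L, exons_per_gene = 5L,
                       exon_len = 300L, intron_len = 700L, utr_len = 150L,
                       intergenic_len = 400L, chrom = "chr1",
                       gene_strands = NULL, gene_biotypes = NULL,
                       alu_placements = NULL, alu_divergence = 0.05,
                       edits_per_alu = 6L,
                       editing_rate_range = c(0.1, 0.5),
                       hf_editing_multiplier = 0.5,
                       n_snps_known = 3L, n_snps_hidden = 2L,
                       circ_plan = NULL,
                       coverage = 50, dna_coverage = 30, read_len = 100L,
                       seq_error_rate = 0.001,
                       n_control = 4L, n_hf = 4L,
                       base_qual_char = "F", anchor_len = 20L) {
  if (is.null(gene_strands))
    gene_strands <- rep(c("+", "-"), length.out = n_genes)
  if (is.null(gene_biotypes))
    gene_biotypes <- rep("protein_coding", n_genes)
  if (is.null(alu_placements))
    alu_placements <- data.frame(
      gene = rep(seq_len(n_genes), each = 2),
      intron = rep(c(1L, exons_per_gene - 1L), n_genes),
      strand = rep(c("+", "-"), n_genes),
      family = rep(c("AluSx3", "AluSz"), n_genes),
      stringsAsFactors = FALSE)
  if (is.null(circ_plan))
    circ_plan <- data.frame(gene = seq_len(n_genes),
                            from_exon = 2L, to_exon = exons_per_gene - 1L,
                            reads_control = 5L, reads_hf = 20L)
  cfg <- structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
    utr_len = as.integer(utr_len), intergenic_len = as.integer(intergenic_len),
    chrom = chrom, gene_strands = gene_strands, gene_biotypes = gene_biotypes,
    alu_placements = alu_placements, alu_divergence = alu_divergence,
    edits_per_alu = as.integer(edits_per_alu),
    editing_rate_range = editing_rate_range,
    hf_editing_multiplier = hf_editing_multiplier,
    n_snps_known = as.integer(n_snps_known),
    n_snps_hidden = as.integer(n_snps_hidden),
    circ_plan = circ_plan, coverage = coverage, dna_coverage = dna_coverage,
    read_len = as.integer(read_len), seq_error_rate = seq_error_rate,
    n_control = as.integer(n_control), n_hf = as.integer(n_hf),
    base_qual_char = base_qual_char, anchor_len = as.integer(anchor_len)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  alu_len <- nchar(ALU_CONSENSUS)
  if (cfg$read_len < 2L * cfg$anchor_len)
    stopf("read_len (%d) must be >= 2 x anchor_len (%d)",
          cfg$read_len, 2L * cfg$anchor_len)
  rates <- c(cfg$editing_rate_range,
             cfg$editing_rate_range * cfg$hf_editing_multiplier,
             cfg$seq_error_rate)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  ap <- cfg$alu_placements
  if (nrow(ap)) {
    if (any(ap$gene > cfg$n_genes) || any(ap$intron >= cfg$exons_per_gene) ||
        any(ap$intron < 1L))
      stopf("alu_placements refers to a gene or intron that does not exist")
    if (alu_len + 4L > cfg$intron_len)
      stopf("Alu placement (%d bp) exceeds intron length (%d bp)",
            alu_len, cfg$intron_len)
    if (!all(ap$strand %in% c("+", "-"))) stopf("Alu strand must be + or -")
  }
  cp <- cfg$circ_plan
  if (nrow(cp)) {
    if (any(cp$from_exon >= cp$to_exon) || any(cp$to_exon > cfg$exons_per_gene))
      stopf("circ_plan exon indices invalid")
  }
  invisible(cfg)
}

mutate_sequence <- function(seq, frac) {
  ch <- str_chars(seq)
  n <- max(0L, round(frac * length(ch)))
  if (n > 0) {
    idx <- sample(length(ch), n)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(ch, collapse = "")
}

## random intron sequence whose *sense* strand begins GT and ends AG
intron_seq <- function(len, gene_strand) {
  body <- random_dna(len - 4L)
  if (gene_strand == "+") paste0("GT", body, "AG") else paste0("CT", body, "AC")
}

#' Build the synthetic genome, annotation, repeats, SNPs and truth manifest
#'
#' Deterministic under `config$seed`. Genes alternate UTR/exon/intron blocks;
#' every intron carries canonical GT..AG splice dinucleotides on the gene's
#' sense strand; Alu-like copies (5% diverged from a fixed adenosine-rich
#' consensus, reverse-complemented for minus-strand placements) are embedded
#' mid-intron; editing sites are planted at sense-strand adenosines of each
#' Alu; heterozygous A>G SNPs are planted at remaining genomic adenosines
#' inside Alus.
#'
#' @param config a [sim_config()] object.
#' @return object of class `circedit_sim`: list with `genome` (named character
#'   vector), `genes` (gene models), `repeats` (BED-style data.frame), `snps`
#'   (all planted SNPs), `manifest` (truth manifest) and `config`.
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), build_genome_impl(config))
}

build_genome_impl <- function(cfg) {
  alu_len <- nchar(ALU_CONSENSUS)
  n_ex <- cfg$exons_per_gene
  pieces <- character(0)
  cursor <- 0L
  genes <- list()
  repeats <- list()
  editing <- list()
  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }

  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("GENE%02d", g)
    strand <- cfg$gene_strands[g]
    add_piece(random_dna(cfg$intergenic_len))
    gene_start <- cursor
    exon_starts <- integer(n_ex); exon_ends <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      ex_len <- cfg$exon_len +
        cfg$utr_len * ((k == 1L) + (k == n_ex) * (n_ex > 1L))
      exon_starts[k] <- cursor
      add_piece(random_dna(ex_len))
      exon_ends[k] <- cursor
      if (k < n_ex) {
        ## intron k (genomic numbering); embed Alu copies requested for it
        iseq <- intron_seq(cfg$intron_len, strand)
        tx_intron <- if (strand == "+") k else n_ex - k
        rows <- which(cfg$alu_placements$gene == g &
                        cfg$alu_placements$intron == tx_intron)
        for (r in rows) {
          offset <- (cfg$intron_len - alu_len) %/% 2L
          aseq <- mutate_sequence(ALU_CONSENSUS, cfg$alu_divergence)
          astrand <- cfg$alu_placements$strand[r]
          if (astrand == "-") aseq <- revcomp(aseq)
          substr(iseq, offset + 1L, offset + alu_len) <- aseq
          repeats[[length(repeats) + 1L]] <- data.frame(
            chrom = cfg$chrom, start = cursor + offset,
            end = cursor + offset + alu_len,
            family = cfg$alu_placements$family[r], score = 0,
            strand = astrand, gene = gid, tx_intron = tx_intron,
            stringsAsFactors = FALSE)
        }
        add_piece(iseq)
      }
    }
    gene_end <- cursor
    cds <- c(gene_start + cfg$utr_len, gene_end - cfg$utr_len)
    tx <- data.frame(start = exon_starts, end = exon_ends)
    genes[[gid]] <- new_gene_model(gid, cfg$gene_biotypes[g], cfg$chrom,
                                   gene_start, gene_end, strand,
                                   setNames(list(tx), paste0(gid, ".t1")), cds)
  }
  add_piece(random_dna(cfg$intergenic_len))
  genome_seq <- paste(pieces, collapse = "")
  genome <- setNames(genome_seq, cfg$chrom)
  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               family = character(0), score = numeric(0), strand = character(0),
               gene = character(0), tx_intron = integer(0))
  repeats$is_alu <- startsWith(repeats$family, "Alu")

  gchars <- str_chars(genome_seq)

  ## plant editing sites at sense-strand adenosines of each Alu copy
  for (r in seq_len(nrow(repeats))) {
    rs <- repeats$start[r]; re <- repeats$end[r]
    sense_A <- if (repeats$strand[r] == "+") "A" else "T"
    cand <- which(gchars[(rs + 1L):re] == sense_A) + rs - 1L  # 0-based
    cand <- cand[cand >= rs + 3L & cand < re - 3L]
    n_pick <- min(cfg$edits_per_alu, length(cand))
    pos <- sort(sample(cand, n_pick))
    rate <- runif(n_pick, cfg$editing_rate_range[1], cfg$editing_rate_range[2])
    editing[[r]] <- data.frame(
      chrom = cfg$chrom, pos = pos,
      ref = gchars[pos + 1L],
      alt = ifelse(gchars[pos + 1L] == "A", "G", "C"),
      rate_control = rate, rate_hf = rate * cfg$hf_editing_multiplier,
      gene = repeats$gene[r], alu_family = repeats$family[r],
      alu_strand = repeats$strand[r], stringsAsFactors = FALSE)
  }
  editing <- if (length(editing)) do.call(rbind, editing) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), rate_control = numeric(0),
               rate_hf = numeric(0), gene = character(0),
               alu_family = character(0), alu_strand = character(0))
  rownames(editing) <- NULL

  ## heterozygous A>G SNPs at genomic adenosines inside Alus, away from
  ## planted editing sites (the hardest confounder for the editing caller)
  n_snps <- cfg$n_snps_known + cfg$n_snps_hidden
  snps <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                     alt = character(0), known = logical(0))
  if (n_snps > 0L && nrow(repeats)) {
    in_alu <- unlist(lapply(seq_len(nrow(repeats)), function(r)
      (repeats$start[r] + 3L):(repeats$end[r] - 4L)))
    cand <- in_alu[gchars[in_alu + 1L] == "A"]
    cand <- setdiff(cand, editing$pos)
    pos <- sort(sample(cand, min(n_snps, length(cand))))
    known <- rep(FALSE, length(pos))
    known[seq_len(min(cfg$n_snps_known, length(pos)))] <- TRUE
    snps <- data.frame(chrom = cfg$chrom, pos = pos, ref = "A", alt = "G",
                       known = known, stringsAsFactors = FALSE)
  }

  ## planted back-splice junctions; breakpoints at annotated exon boundaries,
  ## stored genomically with acceptor_pos < donor_pos (head-to-tail geometry)
  junctions <- list()
  for (i in seq_len(nrow(cfg$circ_plan))) {
    g <- cfg$circ_plan$gene[i]
    gid <- sprintf("GENE%02d", g)
    gene <- genes[[gid]]
    ex <- gene_exons(gene)
    strand <- gene$strand
    fe <- cfg$circ_plan$from_exon[i]; te <- cfg$circ_plan$to_exon[i]
    if (strand == "+") {
      acceptor <- ex$start[fe]; donor <- ex$end[te]
    } else {
      n <- nrow(ex)
      acceptor <- ex$start[n + 1L - te]; donor <- ex$end[n + 1L - fe]
    }
    junctions[[i]] <- data.frame(
      circ_id = sprintf("circ_%s_e%d_e%d", gid, fe, te), gene = gid,
      chrom = cfg$chrom, strand = strand,
      acceptor_pos = acceptor, donor_pos = donor,
      from_exon = fe, to_exon = te,
      reads_control = cfg$circ_plan$reads_control[i],
      reads_hf = cfg$circ_plan$reads_hf[i], stringsAsFactors = FALSE)
  }
  junctions <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame(circ_id = character(0), gene = character(0), chrom = character(0),
               strand = character(0), acceptor_pos = integer(0),
               donor_pos = integer(0), from_exon = integer(0),
               to_exon = integer(0), reads_control = integer(0),
               reads_hf = integer(0))

  samples <- data.frame(
    sample_id = c(sprintf("ctl_%d", seq_len(cfg$n_control)),
                  sprintf("hf_%d", seq_len(cfg$n_hf))),
    group = c(rep("control", cfg$n_control), rep("HF", cfg$n_hf)),
    stringsAsFactors = FALSE)

  manifest <- list(samples = samples, editing = editing, snps = snps,
                   junctions = junctions,
                   genome_length = nchar(genome_seq), seed = cfg$seed)
  structure(list(genome = genome, genes = genes, repeats = repeats,
                 snps = snps, manifest = manifest, config = cfg),
            class = "circedit_sim")
}

#' @export
print.circedit_sim <- function(x, ...) {
  cat(sprintf(paste0("<circedit_sim> genome %d bp, %d genes, %d repeats, ",
                     "%d editing sites, %d SNPs, %d junctions, %d samples\n"),
              x$manifest$genome_length, length(x$genes), nrow(x$repeats),
              nrow(x$manifest$editing), nrow(x$manifest$snps),
              nrow(x$manifest$junctions), nrow(x$manifest$samples)))
  invisible(x)
}

sample_group <- function(sim, sample_id) {
  s <- sim$manifest$samples
  i <- match(sample_id, s$sample_id)
  if (is.na(i)) stopf("unknown sample: %s", sample_id)
  s$group[i]
}

apply_allele <- function(reads, starts, read_len, pos, alt, prob) {
  covering <- which(starts <= pos & starts + read_len > pos)
  if (!length(covering)) return(reads)
  flip <- covering[rbinom(length(covering), 1L, prob) == 1L]
  if (length(flip)) {
    off <- pos - starts[flip] + 1L
    substr(reads[flip], off, off) <- alt
  }
  reads
}

apply_errors <- function(reads, read_len, rate) {
  n_bases <- length(reads) * read_len
  k <- rbinom(1L, n_bases, rate)
  if (k == 0L) return(reads)
  idx <- sample.int(n_bases, k)
  for (x in idx) {
    i <- (x - 1L) %/% read_len + 1L
    off <- (x - 1L) %% read_len + 1L
    cur <- substr(reads[i], off, off)
    substr(reads[i], off, off) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
  reads
}

#' Simulate RNA-seq reads for one sample
#'
#' Linear reads are drawn uniformly over each gene's contiguous pre-mRNA at
#' the configured coverage and carry planted editing alleles at the sample
#' group's per-site rate, heterozygous SNP alleles at rate 0.5, and
#' independent sequencing errors. Back-splice reads spanning each planted
#' circRNA head-to-tail joint are emitted only to the unmapped FASTQ, never
#' to the linear SAM.
#'
#' @param sim a [build_genome()] result.
#' @param sample_id one of the manifest sample ids.
#' @return list with `reads` (linear SAM-style data.frame), `unmapped`
#'   (FASTQ-style data.frame of back-splice reads) and `n_linear`.
#' @export
simulate_rna_reads <- function(sim, sample_id) {
  group <- sample_group(sim, sample_id)
  idx <- match(sample_id, sim$manifest$samples$sample_id)
  withr::with_seed(derive_seed(sim$config$seed, 100L + idx),
                   simulate_rna_impl(sim, sample_id, group))
}

simulate_rna_impl <- function(sim, sample_id, group) {
  cfg <- sim$config
  genome_seq <- unname(sim$genome[1])
  rl <- cfg$read_len
  rate_col <- if (group == "HF") "rate_hf" else "rate_control"
  reads_col <- if (group == "HF") "reads_hf" else "reads_control"

  starts <- integer(0)
  for (gene in sim$genes) {
    glen <- gene$end - gene$start
    n <- ceiling(cfg$coverage * glen / rl)
    if (n > 0 && glen >= rl)
      starts <- c(starts, gene$start +
                    sample.int(glen - rl + 1L, n, replace = TRUE) - 1L)
  }
  reads <- if (length(starts)) substring(genome_seq, starts + 1L, starts + rl)
    else character(0)

  ed <- sim$manifest$editing
  for (i in seq_len(nrow(ed)))
    reads <- apply_allele(reads, starts, rl, ed$pos[i], ed$alt[i], ed[[rate_col]][i])
  sn <- sim$manifest$snps
  for (i in seq_len(nrow(sn)))
    reads <- apply_allele(reads, starts, rl, sn$pos[i], sn$alt[i], 0.5)
  reads <- apply_errors(reads, rl, cfg$seq_error_rate)

  qual <- strrep(cfg$base_qual_char, rl)
  sam <- data.frame(
    read_id = sprintf("%s_r%06d", sample_id, seq_along(reads)),
    flag = rep(0L, length(reads)), chrom = rep(cfg$chrom, length(reads)),
    pos = starts, mapq = rep(60L, length(reads)),
    cigar = rep(paste0(rl, "M"), length(reads)), seq = reads,
    qual = rep(qual, length(reads)),
    is_linear_mapped = rep(TRUE, length(reads)), end = starts + rl,
    stringsAsFactors = FALSE)

  ## back-splice joint reads: tail of the donor exon followed by the head of
  ## the acceptor exon, reverse-complemented for minus-strand genes
  jn <- sim$manifest$junctions
  fq <- list()
  for (i in seq_len(nrow(jn))) {
    k <- jn[[reads_col]][i]
    if (k <= 0) next
    span_x <- rl - 2L * cfg$anchor_len + 1L
    xs <- cfg$anchor_len + ((seq_len(k) - 1L) * 7L) %% span_x
    seqs <- vapply(xs, function(x) {
      s <- paste0(substr0(genome_seq, jn$donor_pos[i] - x, jn$donor_pos[i]),
                  substr0(genome_seq, jn$acceptor_pos[i],
                          jn$acceptor_pos[i] + rl - x))
      if (jn$strand[i] == "-") revcomp(s) else s
    }, "")
    fq[[length(fq) + 1L]] <- data.frame(
      read_id = sprintf("bs_%s_%s_%03d", jn$circ_id[i], sample_id, seq_len(k)),
      seq = seqs, qual = qual, stringsAsFactors = FALSE)
  }
  unmapped <- if (length(fq)) do.call(rbind, fq) else
    data.frame(read_id = character(0), seq = character(0), qual = character(0))

  list(reads = sam, unmapped = unmapped, n_linear = nrow(sam))
}

#' Simulate whole-genome DNA reads for one individual
#'
#' Uniform genomic coverage with heterozygous SNP alleles at rate 0.5 and
#' sequencing errors; carries no editing signal (DNA is never edited).
#'
#' @param sim a [build_genome()] result.
#' @param sample_id one of the manifest sample ids (one individual each).
#' @return SAM-style data.frame of aligned DNA reads.
#' @export
simulate_dna_reads <- function(sim, sample_id) {
  idx <- match(sample_id, sim$manifest$samples$sample_id)
  if (is.na(idx)) stopf("unknown sample: %s", sample_id)
  withr::with_seed(derive_seed(sim$config$seed, 500L + idx), {
    cfg <- sim$config
    genome_seq <- unname(sim$genome[1])
    L <- nchar(genome_seq)
    rl <- cfg$read_len
    n <- ceiling(cfg$dna_coverage * L / rl)
    starts <- if (n > 0) sample.int(L - rl + 1L, n, replace = TRUE) - 1L
      else integer(0)
    reads <- if (length(starts)) substring(genome_seq, starts + 1L, starts + rl)
      else character(0)
    sn <- sim$manifest$snps
    for (i in seq_len(nrow(sn)))
      reads <- apply_allele(reads, starts, rl, sn$pos[i], sn$alt[i], 0.5)
    reads <- apply_errors(reads, rl, cfg$seq_error_rate)
    data.frame(
      read_id = sprintf("%s_d%06d", sample_id, seq_along(reads)),
      flag = 0L, chrom = cfg$chrom, pos = starts, mapq = 60L,
      cigar = paste0(rl, "M"), seq = reads,
      qual = strrep(cfg$base_qual_char, rl),
      is_linear_mapped = TRUE, end = starts + rl, stringsAsFactors = FALSE)
  })
}

#' Write all simulation outputs to a directory
#'
#' Writes genome.fa, genes.gtf, repeats.bed, known_snps.vcf, truth.json and
#' per-sample rna_<id>.sam / unmapped_<id>.fastq / dna_<id>.sam files.
#'
#' @param sim a [build_genome()] result.
#' @param dir output directory (created if needed).
#' @param dna also simulate matched DNA reads (default TRUE).
#' @return `dir`, invisibly.
#' @export
save_simulation <- function(sim, dir, dna = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- setNames(nchar(sim$genome), names(sim$genome))
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$genes, file.path(dir, "genes.gtf"))
  write_bed(sim$repeats, file.path(dir, "repeats.bed"))
  write_vcf(sim$snps[sim$snps$known, , drop = FALSE],
            file.path(dir, "known_snps.vcf"), contigs)
  write_truth(sim$manifest, file.path(dir, "truth.json"))
  for (s in sim$manifest$samples$sample_id) {
    rna <- simulate_rna_reads(sim, s)
    write_sam(rna$reads, contigs, file.path(dir, sprintf("rna_%s.sam", s)))
    write_fastq(rna$unmapped, file.path(dir, sprintf("unmapped_%s.fastq", s)))
    if (dna) {
      dnar <- simulate_dna_reads(sim, s)
      write_sam(dnar, contigs, file.path(dir, sprintf("dna_%s.sam", s)))
    }
  }
  invisible(dir)
}

#' Write / read the truth manifest as JSON
#'
#' @param manifest truth manifest list from [build_genome()].
#' @param path JSON path.
#' @export
write_truth <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("samples", "editing", "snps", "junctions"))
    m[[nm]] <- as.data.frame(m[[nm]], stringsAsFactors = FALSE)
  m
}
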