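# Shared fixtures: small simulation configs and a per-session cache so the
# heavier simulated datasets are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## one-gene desk config for fast unit tests; `...` overrides any default
tiny_cfg <- function(seed = 3, ...) {
  defaults <- list(
    seed = seed, n_genes = 1L, exons_per_gene = 4L, exon_len = 200L,
    intron_len = 500L, utr_len = 100L, intergenic_len = 200L,
    coverage = 30, dna_coverage = 25, n_control = 2L, n_hf = 2L,
    circ_plan = data.frame(gene = 1L, from_exon = 2L, to_exon = 3L,
                           reads_control = 5L, reads_hf = 20L),
    alu_placements = data.frame(gene = 1L, intron = c(1L, 3L),
                                strand = c("+", "-"),
                                family = c("AluSx3", "AluSz")))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

tiny_sim <- function() cached("tiny_sim", build_genome(tiny_cfg()))

## default two-gene simulation with reads for two samples
default_sim <- function() cached("default_sim", build_genome(sim_config(seed = 7)))

## caller-validation config: planted per-group editing ratios all >= 0.2
caller_cfg <- function(seed, error = 0.001) {
  sim_config(seed = seed, editing_rate_range = c(0.4, 0.8),
             seq_error_rate = error)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

## independent per-read pileup tally (brute force), mirroring the caller's
## masking rules but computed read by read, base by base
oracle_tally <- function(reads, genome_len, min_bq = 25L, min_mapq = 20L,
                         trim = 5L) {
  counts <- matrix(0L, nrow = 4L, ncol = genome_len,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(reads))) {
    if (!reads$is_linear_mapped[i] || reads$mapq[i] < min_mapq) next
    if (!grepl("^[0-9]+M$", reads$cigar[i])) stop("oracle expects all-M reads")
    sq <- strsplit(reads$seq[i], "")[[1]]
    qv <- utf8ToInt(reads$qual[i]) - 33L
    n <- length(sq)
    for (k in seq_len(n)) {
      if (k <= trim || k > n - trim) next
      if (qv[k] < min_bq) next
      b <- sq[k]
      if (!b %in% rownames(counts)) next
      p <- reads$pos[i] + k  # 1-based column
      counts[b, p] <- counts[b, p] + 1L
    }
  }
  counts
}

## brute-force per-base segment map over the whole genome
oracle_segment_map <- function(sim) {
  L <- sim$manifest$genome_length
  lab <- rep("intergenic", L)  # index = pos0 + 1
  for (gene in sim$genes) {
    ex <- gene$transcripts[[1]]
    for (p in gene$start:(gene$end - 1L)) {
      in_exon <- FALSE
      for (k in seq_len(nrow(ex)))
        if (p >= ex$start[k] && p < ex$end[k]) in_exon <- TRUE
      this <- if (!in_exon) "intron"
      else if (is.null(gene$cds)) "exon"
      else if (p < gene$cds[1])
        if (gene$strand == "-") "three_prime_utr" else "five_prime_utr"
      else if (p >= gene$cds[2])
        if (gene$strand == "-") "five_prime_utr" else "three_prime_utr"
      else "exon"
      lab[p + 1L] <- this
    }
  }
  lab
}

## brute-force repeat classification of one position
oracle_repeat_class <- function(p, repeats) {
  hit <- repeats[repeats$start <= p & repeats$end > p, , drop = FALSE]
  if (!nrow(hit)) return(list(cls = "nonrepetitive", fam = NA_character_))
  alu <- hit[hit$is_alu, , drop = FALSE]
  pick <- if (nrow(alu)) alu[which.min(alu$start), ] else
    hit[which.min(hit$start), ]
  list(cls = if (pick$is_alu) "alu" else "non_alu_repeat", fam = pick$family)
}

## brute-force Alu pair counts from explicit left/right interval membership
oracle_pair_counts <- function(repeats, left_flank, right_flank) {
  inside <- function(fl) repeats[repeats$is_alu & repeats$start < fl$end &
                                   repeats$end > fl$start, , drop = FALSE]
  l <- inside(left_flank); r <- inside(right_flank)
  conv <- 0L; div <- 0L; same <- 0L
  for (i in seq_len(nrow(l))) for (j in seq_len(nrow(r))) {
    if (l$strand[i] == "+" && r$strand[j] == "-") conv <- conv + 1L
    else if (l$strand[i] == "-" && r$strand[j] == "+") div <- div + 1L
    else same <- same + 1L
  }
  list(conv = conv, div = div, same = same)
}

## expected flanking introns computed structurally from the gene model
expected_flanks <- function(sim, j) {
  gene <- sim$genes[[j$gene]]
  ex <- gene$transcripts[[1]]
  intr <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
  left <- intr[intr$end == j$acceptor_pos, , drop = FALSE]
  right <- intr[intr$start == j$donor_pos, , drop = FALSE]
  to_flank <- function(d) if (nrow(d)) list(start = d$start[1], end = d$end[1])
    else NULL
  if (gene$strand == "+")
    list(upstream = to_flank(left), downstream = to_flank(right))
  else
    list(upstream = to_flank(right), downstream = to_flank(left))
}
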