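test_that("terminal anchors are the first and last anchor-length bases", {
  seq100 <- strrep("ACGT", 25)
  an <- split_anchors(seq100, 20L)
  expect_equal(an$head, substr(seq100, 1, 20))
  expect_equal(an$tail, substr(seq100, 81, 100))
  expect_null(split_anchors(strrep("A", 39), 20L))
})

test_that("anchor alignment distinguishes unique, repeated and reverse-strand anchors", {
  withr::with_seed(17, {
    g <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  })
  copy <- substr(g, 101, 120)
  g2 <- paste0(g, copy)   # duplicate that 20-mer at the end
  gd <- Biostrings::DNAString(g2)
  unique_anchor <- substr(g, 501, 520)
  hit <- align_anchor(unique_anchor, gd)
  expect_true(hit$is_unique)
  expect_equal(hit$plus, 500L)
  expect_gte(hit$margin, 2L)

  two_copy <- align_anchor(copy, gd)
  expect_false(two_copy$is_unique)
  expect_equal(two_copy$n_total, 2L)

  ## reverse-strand anchor: found once genome-wide, but with no plus locus
  rc <- oracle_revcomp(unique_anchor)
  rev_hit <- align_anchor(rc, gd)
  expect_true(rev_hit$is_unique)
  expect_length(rev_hit$plus, 0L)
})

test_that("planted junctions are recovered at exact breakpoints on both strands", {
  sim <- default_sim()    # gene 1 "+", gene 2 "-"
  rna <- lapply(c("ctl_1", "hf_1"), function(s) simulate_rna_reads(sim, s))
  unmapped <- do.call(rbind, lapply(rna, `[[`, "unmapped"))
  det <- detect_junctions(unmapped, sim$genome)
  jn <- sim$manifest$junctions
  expect_equal(nrow(det$junctions), nrow(jn))
  got <- det$junctions[order(det$junctions$acceptor_pos), ]
  want <- jn[order(jn$acceptor_pos), ]
  expect_equal(got$acceptor_pos, want$acceptor_pos)
  expect_equal(got$donor_pos, want$donor_pos)
  expect_equal(got$strand, want$strand)
  expect_true(all(got$splice_signal == "GT-AG"))

  ## a linear genomic read produces no junction
  lin <- data.frame(read_id = "lin1",
                    seq = substr(sim$genome[[1]], 2001, 2100))
  expect_equal(nrow(detect_junctions(lin, sim$genome)$junctions), 0L)
})

test_that("breakpoint homology is resolved deterministically by the GT-AG rule", {
  ## genome with 4-nt homology "GTCA" at both breakpoint flanks so several
  ## splits explain the read; only the planted pair has GT after the donor
  ## and AG before the acceptor
  withr::with_seed(23, {
    pre <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    e1_body <- paste(sample(c("A", "C", "G", "T"), 96, TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    e2_body <- paste(sample(c("A", "C", "G", "T"), 96, TRUE), collapse = "")
    post <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  })
  acceptor <- 302L                       # exon1 starts here (0-based)
  g <- paste0(pre, "AG", "GTCA", e1_body, mid, e2_body, "GTCA", "GT", post)
  donor <- 302L + 100L + 200L + 100L     # end of exon2 (0-based, exclusive)
  genome <- c(chr1 = g)
  read <- paste0(substr(g, donor - 49, donor), substr(g, acceptor + 1,
                                                      acceptor + 50))
  ## oracle: enumerate every consistent split of the read; shifting the
  ## split by d moves both breakpoints right by d
  consistent <- sapply(20:80, function(p) {
    acc_p <- acceptor + (p - 50L)   # 0-based acceptor for this split
    substr(g, donor - 49, donor - 49 + p - 1) == substr(read, 1, p) &&
      substr(g, acc_p + 1, acc_p + 100 - p) == substr(read, p + 1, 100)
  })
  expect_gte(sum(consistent), 2L)   # genuine ambiguity window
  det <- detect_junctions(data.frame(read_id = "r", seq = read), genome)
  expect_equal(det$junctions$acceptor_pos, acceptor)
  expect_equal(det$junctions$donor_pos, donor)
  expect_equal(det$junctions$splice_signal, "GT-AG")
})

test_that("filters flag low support and oversized spans independently", {
  ## one-read junction fails only the min-reads filter
  cfg1 <- tiny_cfg(seed = 41, n_control = 1L, n_hf = 1L,
                   circ_plan = data.frame(gene = 1L, from_exon = 2L,
                                          to_exon = 3L, reads_control = 1L,
                                          reads_hf = 0L))
  sim1 <- build_genome(cfg1)
  um <- simulate_rna_reads(sim1, "ctl_1")$unmapped
  res <- detect_circs(um, sim1$genome, genes = sim1$genes)
  expect_equal(nrow(res$junctions), 1L)
  expect_equal(res$junctions$filter_status, "min_reads")
  expect_false(res$junctions$pass)

  ## a >100-kb junction fails only the span filter
  cfg2 <- sim_config(seed = 43, n_genes = 1L, exons_per_gene = 3L,
                     exon_len = 300L, intron_len = 60000L, utr_len = 150L,
                     coverage = 0, dna_coverage = 0, n_control = 1L, n_hf = 1L,
                     alu_placements = data.frame(gene = integer(0),
                                                 intron = integer(0),
                                                 strand = character(0),
                                                 family = character(0)),
                     circ_plan = data.frame(gene = 1L, from_exon = 1L,
                                            to_exon = 3L, reads_control = 5L,
                                            reads_hf = 0L))
  sim2 <- build_genome(cfg2)
  jn <- sim2$manifest$junctions
  expect_gt(jn$donor_pos - jn$acceptor_pos, 100000L)
  um2 <- simulate_rna_reads(sim2, "ctl_1")$unmapped
  res2 <- detect_circs(um2, sim2$genome)
  expect_equal(nrow(res2$junctions), 1L)
  expect_equal(res2$junctions$filter_status, "max_span")
})

test_that("probe verification finds planted junctions and tolerates mismatches", {
  sim <- tiny_sim()
  um <- simulate_rna_reads(sim, "hf_1")$unmapped
  res <- detect_circs(um, sim$genome, genes = sim$genes)
  expect_true(all(res$junctions$verified))
  expect_equal(nchar(res$junctions$probe[1]), 80L)

  ## a junction at unplanted coordinates is not verified by the same reads
  fake <- data.frame(chrom = "chr1", strand = "+", acceptor_pos = 50L,
                     donor_pos = 900L, span = 850L, n_reads = 2L,
                     splice_signal = "other", margin = 20L)
  fake_v <- verify_junctions(fake, um$seq, sim$genome)
  expect_false(fake_v$verified)

  ## two mismatches inside the probe region still verify; read 5 has its
  ## joint near the read middle, so the 80-bp probe is fully contained
  mut <- um$seq[5]
  substr(mut, 45, 45) <- "N"; substr(mut, 55, 55) <- "N"
  still <- verify_junctions(res$junctions[1, ], mut, sim$genome)
  expect_true(still$verified)
})

test_that("per-sample BSS counts match the planted read numbers", {
  cfg <- tiny_cfg(seed = 47)
  sim <- build_genome(cfg)
  samples <- sim$manifest$samples
  rna <- lapply(setNames(samples$sample_id, samples$sample_id),
                function(s) simulate_rna_reads(sim, s))
  um <- do.call(rbind, lapply(names(rna), function(s)
    cbind(rna[[s]]$unmapped, sample_id = s)))
  det <- detect_junctions(um, sim$genome)
  n_linear <- vapply(rna, function(r) r$n_linear, 0)
  q <- quantify_bss(det$support, samples, n_linear)
  jn <- sim$manifest$junctions
  key <- sprintf("%s:%d-%d:%s", jn$chrom, jn$acceptor_pos, jn$donor_pos,
                 jn$strand)
  for (s in samples$sample_id) {
    want <- if (samples$group[match(s, samples$sample_id)] == "HF")
      jn$reads_hf else jn$reads_control
    expect_equal(unname(q$counts[key, s]), want)
  }
  ## per-million normalisation against the linear denominator
  expect_equal(unname(q$cpm[key[1], "ctl_1"]),
               unname(q$counts[key[1], "ctl_1"] / n_linear["ctl_1"] * 1e6))
})

test_that("detection is symmetric under reverse-complementing the locus", {
  sim <- tiny_sim()
  um <- simulate_rna_reads(sim, "ctl_1")$unmapped
  L <- nchar(sim$genome[[1]])
  mirrored <- c(chr1 = oracle_revcomp(sim$genome[[1]]))
  um_rc <- data.frame(read_id = um$read_id, seq = vapply(um$seq,
                                                         oracle_revcomp, ""))
  d1 <- detect_junctions(um, sim$genome)$junctions
  d2 <- detect_junctions(um_rc, mirrored)$junctions
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(sort(L - d1$donor_pos), sort(d2$acceptor_pos))
  expect_equal(sort(L - d1$acceptor_pos), sort(d2$donor_pos))
})
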