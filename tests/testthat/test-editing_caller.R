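make_pileup <- function(counts, ref) {
  ## hand-built pileup object for rule-level tests
  structure(list(chrom = "chr1", ref = ref, counts = counts,
                 n_reads_used = sum(counts)), class = "pileup")
}

test_that("pileup equals a brute-force per-read tally with all masks applied", {
  sim <- tiny_sim()
  rna <- simulate_rna_reads(sim, "ctl_1")
  reads <- rna$reads[1:120, ]
  ## degrade some records to exercise the masks
  reads$mapq[1:5] <- 10L
  q <- reads$qual[6]
  substr(q, 30, 40) <- strrep("#", 11)   # Q2 block mid-read
  reads$qual[6] <- q
  p <- pileup(reads, sim$genome)
  oracle <- oracle_tally(reads, sim$manifest$genome_length)
  expect_identical(unname(p$counts), unname(oracle))
  ## and with trimming off
  p0 <- pileup(reads, sim$genome, trim_ends = 0L)
  o0 <- oracle_tally(reads, sim$manifest$genome_length, trim = 0L)
  expect_identical(unname(p0$counts), unname(o0))
})

test_that("candidate rule: one strong alt, depth and noise guards", {
  L <- 6L
  ref <- c("A", "A", "A", "A", "C", "A")
  counts <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 15L; counts["G", 1] <- 5L            # candidate, 0.25
  counts["A", 2] <- 18L; counts["G", 2] <- 2L            # below min_alt_reads
  counts["A", 3] <- 11L; counts["G", 3] <- 5L; counts["C", 3] <- 4L # 2 strong alts
  counts["A", 4] <- 3L;  counts["G", 4] <- 1L            # below min_depth
  counts["C", 5] <- 14L; counts["T", 5] <- 6L            # C>T candidate
  counts["A", 6] <- 40L; counts["G", 6] <- 6L; counts["T", 6] <- 3L # noise > 5%
  p <- make_pileup(counts, ref)
  got <- call_candidates(p)
  expect_equal(got$pos, c(0L, 4L))
  expect_equal(got$alt, c("G", "T"))
  expect_equal(got$editing_ratio, c(5 / 20, 6 / 20))

  ## random-column equivalence against a restatement of the rule
  withr::with_seed(99, {
    for (rep in 1:300) {
      cnt <- matrix(rpois(4, 6), 4, 1, dimnames = list(c("A","C","G","T"), NULL))
      rb <- sample(c("A", "C", "G", "T"), 1)
      pp <- make_pileup(cnt, rb)
      got <- nrow(call_candidates(pp))
      alt <- cnt[rownames(cnt) != rb, 1]
      depth <- sum(cnt)
      want <- as.integer(sum(alt >= 3) == 1 && depth >= 5 &&
                           (sum(alt) - max(alt)) <= 0.05 * depth &&
                           max(alt) >= 3)
      expect_equal(got, want)
    }
  })
})

test_that("SNP exclusion removes known variants and DNA-supported genotypes", {
  cand <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                     ref = "A", alt = "G",
                     edited_reads = 5L, total_reads = 20L,
                     editing_ratio = 0.25, stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G")
  counts <- matrix(0L, 4, 50, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 21] <- 15L; counts["G", 21] <- 14L  # het at pos 20 (DNA ~0.5)
  counts["A", 31] <- 30L                          # clean at pos 30
  counts["A", 41] <- 5L;  counts["G", 41] <- 4L   # pos 40: DNA depth < 10
  dna <- make_pileup(counts, rep("A", 50))
  res <- exclude_snps(cand, known, dna)
  expect_equal(res$sites$pos, c(30L, 40L))
  expect_equal(res$removed$reason[res$removed$pos == 10], "known_vcf")
  expect_equal(res$removed$reason[res$removed$pos == 20], "dna_check")
})

test_that("substitution typing reads A>G and T>C as A-to-I", {
  s <- type_substitution(data.frame(ref = c("A", "T", "C", "G"),
                                    alt = c("G", "C", "T", "A")))
  expect_equal(s$substitution_type, c("A>G", "T>C", "C>T", "G>A"))
  expect_equal(s$is_AtoI, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("segment summaries count sites, lengths and mean ratios conservatively", {
  sim <- tiny_sim()
  sites <- data.frame(
    chrom = "chr1", pos = sim$manifest$editing$pos,
    editing_ratio = seq(0.2, 0.4, length.out = nrow(sim$manifest$editing)),
    stringsAsFactors = FALSE)
  ann <- segment_of(sites$pos, sim$genes, "chr1")
  sites$segment <- ann$segment
  sites$gene_id <- ann$gene_id
  sm <- summarize_segments(sites, sim$genes)
  ## all planted sites are intronic, so a single row and no exon row
  expect_equal(sm$segment, "intron")
  expect_equal(sm$n_sites, nrow(sites))          # conservation
  expect_equal(sm$mean_editing_ratio, mean(sites$editing_ratio))
  g <- sim$genes[[1]]
  intr <- circedit:::gene_introns(g)
  expect_equal(sm$segment_length, sum(intr$end - intr$start))
})

test_that("per-position Alu profiles recover planted rates in element coordinates", {
  cfg <- tiny_cfg(seed = 31, coverage = 150, seq_error_rate = 0)
  sim <- build_genome(cfg)
  pile <- function(s) pileup(simulate_rna_reads(sim, s)$reads, sim$genome)
  by_group <- list(control = list(pile("ctl_1")), HF = list(pile("hf_1")))
  for (r in seq_len(nrow(sim$repeats))) {
    el <- sim$repeats[r, ]
    prof <- per_position_profile(el, by_group, sim$genome)
    ed <- sim$manifest$editing[sim$manifest$editing$alu_strand == el$strand &
                                 sim$manifest$editing$pos >= el$start &
                                 sim$manifest$editing$pos < el$end, ]
    for (i in seq_len(nrow(ed))) {
      ## element-local index along the sense strand (strand-flip oracle)
      local <- if (el$strand == "+") ed$pos[i] - el$start + 1 else
        el$end - ed$pos[i]
      row <- prof[prof$element_pos == local, ]
      expect_equal(nrow(row), 1L)
      expect_lt(abs(row$ratio_control - ed$rate_control[i]), 0.15)
      expect_lt(abs(row$ratio_HF - ed$rate_hf[i]), 0.15)
    }
    ## unedited, non-SNP adenosines stay at the error floor (error-free here)
    un <- prof[!prof$pos %in% c(ed$pos, sim$manifest$snps$pos), ]
    expect_true(all(un$ratio_control < 0.02, na.rm = TRUE))
  }
})

test_that("per-gene event means partition genes by direction of change", {
  samples <- data.frame(sample_id = c("c1", "c2", "c3", "h1", "h2", "h3"),
                        group = rep(c("control", "HF"), each = 3))
  sites <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    n <- if (samples$group[i] == "control") 10L else 4L
    data.frame(gene_id = "G1", sample_id = samples$sample_id[i],
               pos = seq_len(n), stringsAsFactors = FALSE)
  }))
  res <- mean_events_per_gene(sites, samples)
  expect_equal(res$direction, "reduced")
  expect_equal(res$mean_control, 10)
  expect_equal(res$mean_HF, 4)
  ## a gene with zero sites everywhere is absent from the partition
  expect_false("G2" %in% res$gene_id)
})
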