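test_that("the normality gate routes to the stated tests", {
  withr::with_seed(101, {
    norm1 <- rnorm(10); norm2 <- rnorm(10) + 0.5
    heavy1 <- rcauchy(10); heavy2 <- rcauchy(10)
    norm3 <- rnorm(10) + 1
  })
  expect_equal(choose_test(list(norm1, norm2)), "student_t")
  expect_equal(choose_test(list(heavy1, heavy2)), "mann_whitney")
  expect_equal(choose_test(list(heavy1, heavy2), paired = TRUE),
               "wilcoxon_signed_rank")
  expect_equal(choose_test(list(norm1, norm2, norm3)), "anova_tukey")
  expect_equal(choose_test(list(heavy1, heavy2, rcauchy(10))),
               "kruskal_wallis")
  expect_warning(got <- choose_test(list(c(1, 2), c(3, 4))), "fewer than 3")
  expect_equal(got, "mann_whitney")
  ## the chosen test actually runs and returns a p-value
  tt <- run_group_test(list(norm1, norm2))
  expect_true(tt$p >= 0 && tt$p <= 1)
  aa <- run_group_test(list(norm1, norm2, norm3))
  expect_equal(aa$test, "anova_tukey")
  expect_false(is.null(aa$posthoc))
})

test_that("differential analysis recovers a planted four-fold increase", {
  withr::with_seed(7, {
    ctl <- rnorm(6, 100, 8); hf <- rnorm(6, 400, 20)
  })
  counts <- rbind(circA = c(ctl, hf),
                  flat = rep(50, 12) + rep(c(0, 1), 6),
                  absent = rep(0, 12))
  groups <- rep(c("control", "HF"), each = 6)
  res <- differential_circ(counts, groups)
  expect_false("absent" %in% res$feature_id)   # all-zero feature excluded
  a <- res[res$feature_id == "circA", ]
  expect_true(a$significant)
  expect_equal(a$direction, "up")
  expect_lt(abs(a$fold_change - 4), 0.5)
  expect_false(res[res$feature_id == "flat", "significant"])

  ## zero reference mean yields the infinite-fold sentinel
  counts2 <- rbind(denovo = c(rep(0, 6), rep(30, 6)))
  res2 <- differential_circ(counts2, groups)
  expect_true(is.infinite(res2$fold_change))
})

test_that("host independence separates circ-only from coupled regulation", {
  circ_res <- data.frame(feature_id = c("c1", "c2", "c3"),
                         p_value = c(0.01, 0.02, 0.8),
                         significant = c(TRUE, TRUE, FALSE))
  host_res <- data.frame(feature_id = c("g1", "g2", "g3"),
                         p_value = c(0.6, 0.001, 0.5))
  map <- c(c1 = "g1", c2 = "g2", c3 = "g3")
  res <- host_independence(circ_res, host_res, map)
  expect_equal(res$host_relation, c("host_independent", "host_coupled",
                                    "not_regulated"))
})

test_that("Alu pair orientation equals brute-force enumeration", {
  sim <- default_sim()
  jn <- sim$manifest$junctions[1, ]
  fl <- flanking_introns(jn$acceptor_pos, jn$donor_pos, sim$genes, jn$chrom)
  up_intron <- fl$upstream; down_intron <- fl$downstream
  left <- if (up_intron$start < down_intron$start) up_intron else down_intron
  right <- if (up_intron$start < down_intron$start) down_intron else up_intron

  mk_reps <- function(n_left, str_left, n_right, str_right) {
    mk <- function(n, strs, fl) if (n == 0)
      NULL else data.frame(chrom = "chr1",
                           start = fl$start + 5 + seq_len(n) * 30,
                           end = fl$start + 25 + seq_len(n) * 30,
                           family = "AluY", score = 0, strand = strs,
                           is_alu = TRUE, stringsAsFactors = FALSE)
    rbind(mk(n_left, str_left, left), mk(n_right, str_right, right))
  }

  ## 1 up(+) x 1 down(-) -> convergent only (plus-strand host gene)
  reps <- mk_reps(1, "+", 1, "-")
  got <- alu_pair_orientation(jn$acceptor_pos, jn$donor_pos, jn$chrom, reps,
                              sim$genes)
  expect_equal(got[c("n_convergent", "n_divergent", "n_same_orientation")],
               list(n_convergent = 1L, n_divergent = 0L,
                    n_same_orientation = 0L))

  ## 2x2 mixed strands -> 1 convergent, 1 divergent, 2 same
  reps2 <- mk_reps(2, c("+", "-"), 2, c("+", "-"))
  got2 <- alu_pair_orientation(jn$acceptor_pos, jn$donor_pos, jn$chrom, reps2,
                               sim$genes)
  expect_equal(got2$n_convergent, 1L)
  expect_equal(got2$n_divergent, 1L)
  expect_equal(got2$n_same_orientation, 2L)
  expect_equal(got2$n_inverted, 2L)

  ## empty flank -> all zero
  got3 <- alu_pair_orientation(jn$acceptor_pos, jn$donor_pos, jn$chrom,
                               mk_reps(2, c("+", "-"), 0, "+"), sim$genes)
  expect_equal(got3$n_inverted + got3$n_same_orientation, 0L)

  ## randomized configurations against the enumeration oracle
  withr::with_seed(77, {
    for (rep in 1:60) {
      nl <- sample(0:3, 1); nr <- sample(0:3, 1)
      reps_r <- mk_reps(nl, sample(c("+", "-"), max(nl, 1), TRUE),
                        nr, sample(c("+", "-"), max(nr, 1), TRUE))
      if (is.null(reps_r)) reps_r <- mk_reps(0, "+", 0, "+")
      if (is.null(reps_r))
        reps_r <- data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), family = character(0),
                             score = numeric(0), strand = character(0),
                             is_alu = logical(0))
      got_r <- alu_pair_orientation(jn$acceptor_pos, jn$donor_pos, jn$chrom,
                                    reps_r, sim$genes)
      o <- oracle_pair_counts(reps_r, left, right)
      expect_equal(got_r$n_convergent, o$conv)
      expect_equal(got_r$n_divergent, o$div)
      expect_equal(got_r$n_same_orientation, o$same)
    }
  })
})

test_that("editing overlap in flanking introns respects half-open boundaries", {
  sim <- default_sim()
  jn <- sim$manifest$junctions[1, ]
  jn$circ_id <- "c1"
  fl <- flanking_introns(jn$acceptor_pos, jn$donor_pos, sim$genes, jn$chrom)
  samples <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        group = c("control", "control", "HF", "HF"))
  ## one site inside the upstream flank, one exactly at its end (excluded)
  sites <- data.frame(pos = c(fl$upstream$start + 3L, fl$upstream$end),
                      sample_id = "s1", stringsAsFactors = FALSE)
  res <- overlap_editing_flanks(jn, sites, sim$genes, samples)
  s1 <- res$per_sample[res$per_sample$sample_id == "s1", ]
  expect_equal(s1$n_upstream, 1L)
  expect_equal(s1$n_total, 1L)
  expect_equal(sum(res$per_sample$n_total), 1L)
})

test_that("correlation chooses its method and flags degenerate input", {
  withr::with_seed(5, {
    x <- rnorm(30, 50, 5)
  })
  res <- correlate_circ_host(2 * x, x)
  expect_equal(res$estimate, 1, tolerance = 1e-9)
  expect_lt(res$p, 0.001)
  expect_false(is.null(res$method))

  short <- correlate_circ_host(c(1, 2, 3), c(2, 4, 6))
  expect_true(!is.null(short$flag))
  const <- correlate_circ_host(rep(2, 10), rnorm(10))
  expect_true(!is.null(const$flag))
})

test_that("FPKM follows its defining arithmetic", {
  expect_equal(fpkm(100, 2000, 1e6), 50)
  expect_equal(fpkm(0, 2000, 1e6), 0)
  expect_equal(fpkm(100, 2000, 2e6), 25)   # doubling the total halves it
  expect_error(fpkm(10, 0, 1e6), "length")
  expect_error(fpkm(10, 1000, 0), "total")
})
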