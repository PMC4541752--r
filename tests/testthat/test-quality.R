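test_that("bit scores follow the Karlin-Altschul transform", {
  sch <- scoring_scheme()  # +1/-2, lambda 1.28, K 0.46
  expect_equal(bitscore(0, sch), -log(0.46) / log(2))
  expect_true(all(diff(bitscore(0:50, sch)) > 0))
  # 100-nt exact self-match: raw score 100
  expect_equal(bitscore(100, sch), (1.28 * 100 - log(0.46)) / log(2))
  set.seed(1)
  g <- rand_dna(100)
  expect_equal(self_bits(g, sch), bitscore(100, sch))
  expect_error(scoring_scheme(match = 2, mismatch = -5), "tabulated")
})

test_that("local scores match the Smith-Waterman oracle", {
  set.seed(2)
  sch <- scoring_scheme()
  for (i in 1:25) {
    a <- rand_dna(sample(60:400, 1))
    b <- if (i %% 3 == 0) rand_dna(sample(60:400, 1)) else
      mutate_to_identity(a, runif(1, 0.85, 1), i)
    if (i %% 4 == 0) b <- substr(b, 10, max(40, nchar(b) - 25))
    mine <- consensustx:::local_score_cpp(a, b, sch$match, sch$mismatch,
                                          sch$gap_open, sch$gap_extend)
    expect_equal(mine, oracle_local_score(a, b))
  }
})

test_that("best hits rank contigs by maximal local score over both strands", {
  set.seed(3)
  g <- rand_dna(600)
  sch <- scoring_scheme()
  asm <- data.frame(
    id = c("exact", "rc_half", "junk"),
    seq = c(g, revcomp(substr(g, 1, 300)), rand_dna(400)))
  hits <- best_local_hits(g, asm, sch)
  expect_equal(hits$contig_id[1], "exact")
  expect_equal(hits$raw_score[1], 600)            # match_reward x length
  expect_equal(hits$raw_score[hits$contig_id == "rc_half"], 300)
  expect_equal(nrow(best_local_hits(g, asm[0, ], sch)), 0)
})

test_that("reconstruction ratios are self-normalised into [0, 1]", {
  set.seed(4)
  g <- rand_dna(1000)
  sch <- scoring_scheme()
  verbatim <- data.frame(id = "v", seq = g)
  qc <- reconstruction_ratio(g, verbatim, sch)
  expect_equal(qc$ratio, 1, tolerance = 1e-9)
  expect_equal(qc$best_contig_id, "v")

  none <- reconstruction_ratio(g, data.frame(id = character(),
                                             seq = character()), sch)
  expect_equal(none$ratio, 0)
  expect_true(is.na(none$best_contig_id))

  half <- data.frame(id = "h", seq = substr(g, 1, 500))
  expected <- bitscore(500, sch) / bitscore(1000, sch)
  qh <- reconstruction_ratio(g, half, sch)
  expect_equal(qh$ratio, expected, tolerance = 1e-12)
  expect_lt(abs(qh$ratio - 0.5), 0.01)  # ~0.5 for kb-scale genes

  # a local hit can never out-score the self-alignment
  for (i in 1:10) {
    contigs <- data.frame(id = "c", seq = rand_dna(1500))
    r <- reconstruction_ratio(g, contigs, sch)$ratio
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("isoform hit counting finds near-identical second copies", {
  set.seed(5)
  g <- rand_dna(1000)
  iso <- mutate_to_identity(g, 0.97, 6)
  sch <- scoring_scheme()
  both <- data.frame(id = c("g", "iso"), seq = c(g, iso))
  expect_equal(isoform_hit_count(g, both, sch), 2L)
  expect_equal(isoform_hit_count(g, both[1, ], sch), 1L)
  expect_equal(isoform_hit_count(g, both[0, ], sch), 0L)
})

test_that("quality matrix covers every gene x assembly cell", {
  genes <- generate_gene_set(3, 0, c(300, 400), seed = 17)
  asm <- list(
    full = data.frame(id = paste0(genes$gene_id, "_c"), seq = genes$seq),
    partial = data.frame(id = paste0(genes$gene_id[-2], "_c"),
                         seq = genes$seq[-2]))
  qm <- quality_matrix(genes, asm)
  expect_equal(nrow(qm), 6)
  expect_true(all(qm$ratio[qm$assembly_id == "full"] == 1))
  # dropped gene: essentially unreconstructed (chance seed-length micro-hits
  # against unrelated contigs can score marginally above zero)
  expect_lt(qm$ratio[qm$assembly_id == "partial" & qm$gene_id == "g002"],
            0.05)
  expect_true(all(qm$ratio[qm$assembly_id == "partial" &
                             qm$gene_id != "g002"] == 1))
  # with no contigs at all the cell is exactly zero
  none <- quality_matrix(genes[2, , drop = FALSE],
                         list(empty = asm$partial[0, , drop = FALSE]))
  expect_equal(none$ratio, 0)
  summ <- attr(qm, "summary")
  expect_equal(summ$mean_ratio[summ$assembly_id == "full"], 1)
})

test_that("hit-coverage tables count targets cumulatively by best coverage", {
  hits <- data.frame(
    query_id = c("q1", "q2", "q3", "q4"),
    subject_id = c("t1", "t1", "t2", "t3"),
    pct_identity = 90, aln_length = 50, mismatches = 0, gap_opens = 0,
    q_start = 1, q_end = 50,
    s_start = c(1, 1, 23, 81), s_end = c(90, 100, 77, 100),
    e_value = c(1e-30, 1e-40, 1e-25, 1e-22), bitscore = 100)
  lens <- c(t1 = 100, t2 = 100, t3 = 100)
  tab <- hit_coverage_table(hits, lens)
  # best coverages: t1 100%, t2 55%, t3 20%
  expect_equal(tab$n_targets[tab$coverage_threshold == 100], 1L)
  expect_equal(tab$n_targets[tab$coverage_threshold == 50], 2L)
  expect_equal(tab$n_targets[tab$coverage_threshold == 10], 3L)
  expect_true(!is.unsorted(tab$n_targets))  # cumulative as threshold drops

  # a single 90%-coverage hit counts at thresholds <= 90 only
  one <- hit_coverage_table(hits[1, ], lens)
  expect_equal(one$n_targets[one$coverage_threshold == 100], 0L)
  expect_equal(one$n_targets[one$coverage_threshold == 90], 1L)

  # e-value prefilter and empty input
  weak <- hits; weak$e_value <- 1e-5
  expect_equal(sum(hit_coverage_table(weak, lens)$n_targets), 0L)
  expect_equal(sum(hit_coverage_table(hits[0, ], lens)$n_targets), 0L)
  bad <- hits; bad$subject_id[1] <- "nope"
  expect_error(hit_coverage_table(bad, lens), "unknown target")
})
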