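test_that("pair identity: self, containment, mutated pair, strands", {
  set.seed(1)
  s <- rand_dna(1000)
  expect_equal(pair_identity(s, s), list(identity = 1, strand = "+"))

  # identity is over the shorter sequence: containment saturates
  frag <- substr(s, 201, 204 + 196)  # 200 nt inside s
  expect_equal(pair_identity(frag, s)$identity, 1)
  expect_equal(pair_identity(s, frag)$identity, 1)

  m <- mutate_to_identity(s, 0.97, 5)
  expect_equal(pair_identity(s, m)$identity, 0.970, tolerance = 1e-12)
  hit <- pair_identity(s, revcomp(m))
  expect_equal(hit$identity, 0.970, tolerance = 1e-12)
  expect_equal(hit$strand, "-")
  expect_error(pair_identity("", s), "empty")
})

test_that("overlap scores and match counts agree with the Biostrings oracle", {
  set.seed(7)
  p <- cluster_params()
  for (i in 1:30) {
    a <- rand_dna(sample(80:300, 1))
    b <- if (i %% 3 == 0) rand_dna(sample(80:300, 1)) else
      mutate_to_identity(a, runif(1, 0.9, 1), i)
    if (i %% 5 == 0) b <- substr(b, 20, max(60, nchar(b) - 30))
    mine <- consensustx:::overlap_align_cpp(a, b, 1L, -2L, -5L, -2L)
    orac <- oracle_overlap(a, b)
    expect_equal(unname(mine[["score"]]), orac$score)
    if (i %% 3 != 0) {
      # substitution-only pairs: near-unique optimum, match counts agree
      # (unrelated random pairs have many co-optimal degenerate paths)
      expect_lte(abs(mine[["matches"]] - orac$matches), 2)
    }
  }
})

test_that("word prescreen is conservative and rejects only hopeless pairs", {
  set.seed(9)
  a <- rand_dna(300)
  expect_true(word_filter_pass(a, a, 0.97))

  # unrelated random pairs: filter says no, and the oracle confirms
  rejected <- 0
  for (i in 1:20) {
    b <- rand_dna(200)
    if (!word_filter_pass(a, b, 0.97)) {
      rejected <- rejected + 1
      expect_lt(oracle_identity(a, b), 0.97)
    }
  }
  expect_gt(rejected, 15)

  # never false for a pair whose realized identity reaches the threshold
  # (fragments can concentrate substitutions, so gate on the measured value)
  for (i in 1:300) {
    L <- sample(100:800, 1)
    s <- rand_dna(L)
    cth <- sample(c(0.95, 0.97, 0.99), 1)
    m <- mutate_to_identity(s, cth, i)
    if (i %% 2 == 0) m <- revcomp(m)
    if (i %% 5 == 0) m <- substr(m, 1, max(100, L - 150)) # contained fragment
    if (pair_identity(s, m)$identity >= cth) {
      expect_true(word_filter_pass(s, m, cth))
    }
  }
})

test_that("greedy clustering merges by identity with length-ranked representatives", {
  set.seed(2)
  s <- rand_dna(500)
  trio <- data.frame(id = c("x", "y", "z"), seq = rep(s, 3))
  cs <- greedy_cluster(trio)
  expect_equal(length(unique(cs$members$cluster_id)), 1)
  expect_equal(cs$members$contig_id[cs$members$is_rep], "x")  # first input

  a <- rand_dna(1000)
  b <- mutate_to_identity(a, 0.97, 3)
  two <- data.frame(id = c("A", "B"), seq = c(a, b))
  cs97 <- greedy_cluster(two, cluster_params(identity_threshold = 0.97))
  expect_equal(cluster_counts(cs97)$n_clusters, 1)
  cs98 <- greedy_cluster(two, cluster_params(identity_threshold = 0.98))
  expect_equal(cluster_counts(cs98)$n_clusters, 2)

  none <- greedy_cluster(two[0, ])
  expect_equal(nrow(none$members), 0)
})

test_that("cluster sets partition the input and store verified identities", {
  genes <- generate_gene_set(6, 1, c(300, 500), seed = 31)
  sim <- generate_assemblies(genes, 4, 0.3, 0.1, 2, seed = 31)
  pooled <- pool_assemblies(sim$assemblies)
  cs <- greedy_cluster(pooled)
  m <- cs$members
  expect_setequal(m$contig_id, pooled$id)               # partition, total
  expect_equal(nrow(m), nrow(pooled))
  expect_true(all(m$identity >= 0.97))
  # representative at least as long as every member
  rep_len <- tapply(m$length[m$is_rep], m$cluster_id[m$is_rep], max)
  expect_true(all(m$length <= rep_len[as.character(m$cluster_id)]))
  # stored identities recheck against the aligner on a sample
  seqs <- setNames(pooled$seq, pooled$id)
  nonrep <- m[!m$is_rep, ]
  nonrep <- nonrep[seq_len(min(8, nrow(nonrep))), ]
  rep_of <- setNames(m$contig_id[m$is_rep], m$cluster_id[m$is_rep])
  for (i in seq_len(nrow(nonrep))) {
    got <- pair_identity(seqs[[nonrep$contig_id[i]]],
                         seqs[[rep_of[[as.character(nonrep$cluster_id[i])]]]])
    expect_equal(got$identity, nonrep$identity[i], tolerance = 1e-12)
  }
})

test_that("word-filtered clustering equals brute-force clustering on small instances", {
  for (seed in 1:5) {
    genes <- generate_gene_set(6, 1, c(300, 420), seed = seed)
    sim <- generate_assemblies(genes, 3, 0.25, 0.15, 2, seed = seed)
    pooled <- pool_assemblies(sim$assemblies)
    expect_lte(nrow(pooled), 50)
    for (cth in c(0.90, 0.96, 1.00)) {
      with_f <- greedy_cluster(pooled, cluster_params(cth))
      without <- greedy_cluster(pooled,
                                cluster_params(cth, use_word_filter = FALSE))
      expect_identical(with_f$members, without$members)
    }
  }
})

test_that("threshold scan reruns clustering per threshold", {
  set.seed(4)
  d <- data.frame(id = sprintf("u%d", 1:5),
                  seq = vapply(rep(300, 5), rand_dna, character(1)))
  scan <- cluster_threshold_scan(d, c(0.90, 0.95, 1.00))
  expect_equal(scan$threshold, c(0.90, 0.95, 1.00))
  expect_equal(scan$n_clusters, c(5, 5, 5))  # unrelated: never merge

  # duplicates and contained fragments merge even at threshold 1.0
  s <- rand_dna(600)
  dup <- data.frame(id = c("a", "b", "c"),
                    seq = c(s, s, substr(s, 100, 400)))
  scan1 <- cluster_threshold_scan(dup, 1.0)
  expect_equal(scan1$n_clusters, 1)
  expect_equal(oracle_identity(substr(s, 100, 400), s), 1)
})
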