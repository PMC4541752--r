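mk_cluster_set <- function(...) consensustx:::new_cluster_set(...)

# hand-built cluster set: cluster 0 = singleton from S1 (rep 800 nt),
# cluster 1 = three contigs from two assemblies
toy_set <- function() {
  mk_cluster_set(data.frame(
    cluster_id = c(0L, 1L, 1L, 1L),
    contig_id = c("S1|a", "S1|b", "S2|c", "S2|d"),
    length = c(800L, 400L, 350L, 300L),
    identity = c(1, 1, 0.98, 0.99),
    strand = c("+", "+", "+", "-"),
    is_rep = c(TRUE, TRUE, FALSE, FALSE),
    source = c("S1", "S1", "S2", "S2"), stringsAsFactors = FALSE))
}

test_that("cluster metrics sum FPKM over members and count sources", {
  ab <- abundance_table(matrix(c(2, 1, 0, 4, 3, 2, 0, 1), nrow = 4,
                               dimnames = list(c("S1|a", "S1|b", "S2|c",
                                                 "S2|d"), c("s1", "s2"))))
  met <- compute_metrics(toy_set(), ab)
  expect_equal(met$length, c(800L, 400L))
  expect_equal(met$n_contigs, c(1L, 3L))
  expect_equal(met$sum_fpkm, c(2 + 3, 1 + 2 + 4 + 0 + 0 + 1))
  expect_equal(met$n_sources, c(1L, 2L))

  # contig absent from the abundance table contributes 0, with a warning
  ab2 <- abundance_table(matrix(c(2, 3), 1, 2,
                                dimnames = list("S1|a", c("s1", "s2"))))
  expect_warning(met2 <- compute_metrics(toy_set(), ab2), "absent")
  expect_equal(met2$sum_fpkm, c(5, 0))
})

test_that("two-of-three rule retains clusters with at most one failed criterion", {
  combos <- expand.grid(len_ok = c(TRUE, FALSE), ctg_ok = c(TRUE, FALSE),
                        fpkm_ok = c(TRUE, FALSE))
  met <- data.frame(
    cluster_id = seq_len(nrow(combos)) - 1L,
    representative_id = sprintf("r%d", seq_len(nrow(combos))),
    length = ifelse(combos$len_ok, 600L, 300L),
    n_contigs = ifelse(combos$ctg_ok, 12L, 5L),
    sum_fpkm = ifelse(combos$fpkm_ok, 60, 10),
    n_sources = 1L, stringsAsFactors = FALSE)
  res <- apply_filter(met)
  n_fail <- 3 - rowSums(combos)
  expect_equal(res$retained, n_fail <= 1)
  expect_equal(res$n_failed, unname(n_fail))

  # boundary semantics: 500 nt passes, 10 contigs fails, FPKM 50 fails
  edge <- data.frame(cluster_id = 0L, representative_id = "r",
                     length = 500L, n_contigs = 10L, sum_fpkm = 50,
                     n_sources = 1L)
  eres <- apply_filter(edge)
  expect_true(eres$pass_length)
  expect_false(eres$pass_contigs)
  expect_false(eres$pass_fpkm)
  expect_false(eres$retained)
})

test_that("the filter is monotone in every metric", {
  set.seed(10)
  for (i in 1:50) {
    met <- data.frame(cluster_id = 0L, representative_id = "r",
                      length = sample(100:1500, 1),
                      n_contigs = sample(1:20, 1),
                      sum_fpkm = runif(1, 0, 150), n_sources = 1L)
    base <- apply_filter(met)$retained
    for (col in c("length", "n_contigs", "sum_fpkm")) {
      better <- met
      better[[col]] <- better[[col]] + 1000
      expect_true(apply_filter(better)$retained >= base)
    }
  }
})

test_that("missing abundance degrades the filter to two criteria with a warning", {
  met <- compute_metrics(toy_set(), NULL)
  expect_true(all(is.na(met$sum_fpkm)))
  expect_warning(res <- apply_filter(met), "length and contig count")
  expect_equal(res$n_failed, c(1L, 2L))  # both fail contigs; cluster 1 fails length too
  expect_equal(res$retained, c(TRUE, FALSE))
})

test_that("threshold scan counts clusters strictly below each candidate", {
  met <- data.frame(cluster_id = 0:2, representative_id = c("a", "b", "c"),
                    length = c(100L, 600L, 1200L), n_contigs = c(1L, 2L, 12L),
                    sum_fpkm = c(0, 20, 80), n_sources = 1L)
  scan <- filter_threshold_scan(met, contig_thresholds = c(0, 3),
                                fpkm_thresholds = 50,
                                length_thresholds = c(500, 2000))
  expect_equal(scan$n_below[scan$metric == "n_contigs"], c(0L, 2L))
  expect_equal(scan$n_below[scan$metric == "sum_fpkm"], 2L)
  expect_equal(scan$n_below[scan$metric == "length"], c(1L, 3L))
  # counts non-decreasing in the candidate value
  big <- filter_threshold_scan(met, contig_thresholds = 1:15)
  expect_true(!is.unsorted(big$n_below))
  expect_error(filter_threshold_scan(met), "no candidate")
})

test_that("participation matrix conserves contigs; breadth histogram sums to clusters", {
  pm <- participation_matrix(toy_set())
  expect_equal(pm["1", ], c(S1 = 1L, S2 = 2L))
  expect_equal(rowSums(pm), c("0" = 1, "1" = 3))
  expect_equal(sum(pm), 4)

  bh <- breadth_histogram(toy_set(), breadth_cutoff = 1)
  expect_equal(sum(bh$histogram$n_clusters), 2)
  expect_equal(bh$core, 1L)  # only cluster 1 spans > 1 assembly
})

test_that("assembly correlation reflects co-occurrence patterns", {
  ident <- cbind(A = c(3L, 1L, 2L, 2L), B = c(3L, 1L, 2L, 2L))
  r <- assembly_correlation(ident, cluster_sizes = rep(2, 4))
  expect_equal(r["A", "B"], 1)

  anti <- cbind(A = c(1L, 0L, 1L, 0L), B = c(0L, 1L, 0L, 1L))
  r2 <- assembly_correlation(anti, cluster_sizes = rep(2, 4))
  expect_equal(r2["A", "B"], -1)

  set.seed(5)
  rnd <- cbind(A = rpois(1000, 2), B = rpois(1000, 2))
  r3 <- assembly_correlation(rnd, cluster_sizes = rep(2, 1000))
  expect_lt(abs(r3["A", "B"]), 0.1)

  flat <- cbind(A = c(1L, 1L), B = c(0L, 1L))
  r4 <- assembly_correlation(flat, cluster_sizes = c(2, 2))
  expect_true(is.na(r4["A", "B"]))
  expect_error(assembly_correlation(ident[1, , drop = FALSE],
                                    cluster_sizes = 2), "at least 2")
})

test_that("expressed gene clusters are retained and junk clusters discarded", {
  for (seed in 1:20) {
    set.seed(seed)
    n_good <- 30; n_junk <- 30
    rows <- function(k, n, len, src_n) data.frame(
      cluster_id = rep(k, n),
      contig_id = sprintf("S%d|c%d_%d", seq_len(n) %% src_n + 1, k,
                          seq_len(n)),
      length = as.integer(len - seq_len(n) + 1), identity = 1,
      strand = "+", is_rep = c(TRUE, rep(FALSE, n - 1)),
      source = sprintf("S%d", seq_len(n) %% src_n + 1),
      stringsAsFactors = FALSE)
    good <- do.call(rbind, lapply(seq_len(n_good) - 1L, function(k)
      rows(k, sample(11:19, 1), sample(900:1500, 1), 15)))
    junk <- do.call(rbind, lapply(n_good + seq_len(n_junk) - 1L, function(k)
      rows(k, 1, sample(150:400, 1), 1)))
    cs <- mk_cluster_set(rbind(good, junk))
    fpkm_rows <- c(
      setNames(runif(nrow(good), 5, 50), good$contig_id),   # sums well > 50
      setNames(runif(nrow(junk), 0, 2), junk$contig_id))
    ab <- abundance_table(matrix(fpkm_rows, ncol = 1,
                                 dimnames = list(names(fpkm_rows), "s1")))
    res <- apply_filter(compute_metrics(cs, ab))
    is_good <- res$cluster_id < n_good
    expect_gte(mean(res$retained[is_good]), 0.95)
    expect_gte(mean(!res$retained[!is_good]), 0.95)
  }
})
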