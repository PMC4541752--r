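# Independent alignment oracle (Biostrings) and small fixture builders.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution matrix matching the package convention: N never rewards
nuc_mat <- function(match = 1, mismatch = -2) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

# end-gap-free alignment via Biostrings; independent of the package's DP
oracle_overlap <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = nuc_mat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap_extend)
  list(score = Biostrings::score(aln), matches = Biostrings::nmatch(aln))
}

oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = nuc_mat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap_extend, scoreOnly = TRUE)
}

# identity over the shorter sequence, maximised over strands, via the oracle
oracle_identity <- function(a, b) {
  sh <- min(nchar(a), nchar(b))
  fwd <- oracle_overlap(a, b)$matches / sh
  rev <- oracle_overlap(a, consensustx::revcomp(b))$matches / sh
  max(fwd, rev)
}

# random cluster set with file-representable identities (percent, 2 dp)
random_cluster_set <- function(n_clusters, max_members = 4) {
  rows <- list()
  for (k in seq_len(n_clusters) - 1L) {
    n <- sample.int(max_members, 1)
    lens <- sort(sample(100:2000, n), decreasing = TRUE)
    ids <- sprintf("SRC%d|tr%d_%d", sample(1:5, n, replace = TRUE), k,
                   seq_len(n))
    rows[[k + 1L]] <- data.frame(
      cluster_id = k, contig_id = ids, length = lens,
      identity = c(1, sample(9700:10000, n - 1, replace = TRUE) / 10000),
      strand = c("+", sample(c("+", "-"), n - 1, replace = TRUE)),
      is_rep = c(TRUE, rep(FALSE, n - 1)),
      stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, rows)
  members$source <- sub("\\|.*$", "", members$contig_id)
  consensustx:::new_cluster_set(members)
}
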