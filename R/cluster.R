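#' Clustering parameters
#'
#' Parameters of the greedy incremental clustering step. The identity
#' threshold defaults to 0.97, the value that merges cultivar alleles
#' (a handful of SNPs apart) while keeping true isoform pairs such as
#' SLS1/SLS2 (~97% identity) and T16H1/T16H2 in distinct clusters; the word
#' length defaults to 9, matching the short-word prescreen used by the
#' standard nucleotide clustering tools.
#'
#' @param identity_threshold fraction in \[0.90, 1.00\]; a contig joins a
#'   cluster only if its identity to the representative is at least this.
#' @param word_length prescreen word size (bases), in \[4, 12\].
#' @param both_strands compare both strands (default TRUE).
#' @param assign_mode `"first_match"` (greedy, default — the behaviour of the
#'   standard tool) or `"best_match"`.
#' @param match,mismatch,gap_open,gap_extend integer alignment scores used to
#'   pick the optimal end-gap-free alignment whose matched bases define
#'   identity.
#' @param use_word_filter disable only for brute-force cross-checks.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(identity_threshold = 0.97, word_length = 9,
                           both_strands = TRUE,
                           assign_mode = c("first_match", "best_match"),
                           match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L, use_word_filter = TRUE) {
  assign_mode <- match.arg(assign_mode)
  stopifnot(identity_threshold >= 0.90, identity_threshold <= 1.00,
            word_length >= 4, word_length <= 12)
  structure(list(identity_threshold = identity_threshold,
                 word_length = as.integer(word_length),
                 both_strands = isTRUE(both_strands),
                 assign_mode = assign_mode,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 use_word_filter = isTRUE(use_word_filter)),
            class = "cluster_params")
}

#' Nucleotide identity of two sequences
#'
#' Identity is the number of identically aligned bases in the optimal
#' end-gap-free (overlap) alignment, divided by the length of the shorter
#' sequence — the convention of the greedy clustering tools, under which a
#' fragment exactly contained in a longer contig scores identity 1. When
#' `both_strands` is TRUE the maximum over the forward and
#' reverse-complement orientation of `b` is returned. `N` bases never count
#' as matches.
#'
#' @param a,b DNA strings (length >= 20 recommended for meaningful words).
#' @param both_strands compare both orientations of `b`.
#' @param params a [cluster_params()] (alignment scores).
#' @return list with `identity` (fraction) and `strand` (`"+"`/`"-"`).
#' @export
pair_identity <- function(a, b, both_strands = TRUE,
                          params = cluster_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  shorter <- min(nchar(a), nchar(b))
  fwd <- overlap_align_cpp(a, b, params$match, params$mismatch,
                           params$gap_open, params$gap_extend)
  id_fwd <- fwd[["matches"]] / shorter
  if (!both_strands) return(list(identity = id_fwd, strand = "+"))
  rev <- overlap_align_cpp(a, revcomp(b), params$match, params$mismatch,
                           params$gap_open, params$gap_extend)
  id_rev <- rev[["matches"]] / shorter
  if (id_rev > id_fwd) list(identity = id_rev, strand = "-")
  else list(identity = id_fwd, strand = "+")
}

# all overlapping words of length n (positions 1..L-n+1)
seq_words <- function(seq, n) {
  L <- nchar(seq)
  if (L < n) return(character())
  substring(seq, 1:(L - n + 1), n:L)
}

# number of word positions of the shorter sequence whose word occurs in the
# other sequence
shared_word_count <- function(words_short, words_long) {
  sum(words_short %in% words_long)
}

#' Conservative shared-word prescreen
#'
#' Two sequences at identity >= `c` over the shorter length `Ls` (identity
#' measured as matched bases under end-gap-free alignment) must share at
#' least `Ls - n + 1 - n * ceiling((1 - c) * Ls)` words of length `n`: each
#' of the at most `ceiling((1-c) * Ls)` non-matching bases can destroy at
#' most `n` word positions. The filter returns FALSE only when the shared
#' count on both strands falls below this bound, so it never rejects a pair
#' the aligner would accept; it exists purely to skip hopeless alignments.
#'
#' @param a,b DNA strings.
#' @param c identity threshold (fraction).
#' @param n word length (default 9).
#' @param both_strands check the reverse complement of `b` too.
#' @return TRUE if the pair could reach identity `c`.
#' @export
word_filter_pass <- function(a, b, c, n = 9, both_strands = TRUE) {
  Ls <- min(nchar(a), nchar(b))
  bound <- Ls - n + 1 - n * ceiling((1 - c) * Ls)
  if (bound <= 0) return(TRUE)
  if (nchar(a) <= nchar(b)) { ws <- seq_words(a, n); wl <- seq_words(b, n) }
  else { ws <- seq_words(b, n); wl <- seq_words(a, n) }
  if (shared_word_count(ws, wl) >= bound) return(TRUE)
  if (both_strands) {
    wl_rc <- if (nchar(a) <= nchar(b)) seq_words(revcomp(b), n) else
      seq_words(revcomp(a), n)
    if (shared_word_count(ws, wl_rc) >= bound) return(TRUE)
  }
  FALSE
}

new_cluster_set <- function(members, params = NULL) {
  structure(list(members = members, params = params,
                 contig_to_cluster = setNames(members$cluster_id,
                                              members$contig_id)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- table(x$members$cluster_id)
  cat("cluster_set:", length(sizes), "clusters (",
      sum(sizes == 1), "singletons,", sum(sizes >= 2), "true clusters ),",
      nrow(x$members), "contigs\n")
  invisible(x)
}

#' Greedy incremental clustering of pooled contigs
#'
#' Contigs are sorted by length (descending, ties by input order) and
#' processed once. Each contig either joins an existing cluster whose
#' representative it matches at identity >= the threshold — the first such
#' representative in creation order under `assign_mode = "first_match"`, or
#' the best-identity one under `"best_match"` — or founds a new cluster with
#' itself as representative. Because of the length-descending scan every
#' representative is at least as long as each of its members. The
#' shared-word prescreen ([word_filter_pass()]) skips representative
#' candidates that provably cannot reach the threshold.
#'
#' @param contigs contig table (`id`, `seq`, optional `source`); ids unique.
#' @param params a [cluster_params()].
#' @return a `cluster_set`: `members` data.frame (`cluster_id`, `contig_id`,
#'   `length`, `identity` to representative, `strand`, `is_rep`, `source`,
#'   `seq` of representatives retained in `representatives`), `params`, and
#'   the `contig_to_cluster` map.
#' @export
greedy_cluster <- function(contigs, params = cluster_params()) {
  stopifnot(is.data.frame(contigs))
  if (anyDuplicated(contigs$id)) stop("duplicate contig ids in pooled input")
  n <- nrow(contigs)
  src <- if (!is.null(contigs$source)) contigs$source else
    contig_source(contigs$id)
  if (n == 0) {
    cs <- new_cluster_set(data.frame(
      cluster_id = integer(), contig_id = character(), length = integer(),
      identity = numeric(), strand = character(), is_rep = logical(),
      source = character(), stringsAsFactors = FALSE), params)
    cs$representatives <- data.frame(id = character(), seq = character(),
                                     stringsAsFactors = FALSE)
    return(cs)
  }
  ord <- order(-nchar(contigs$seq), seq_len(n))
  seqs <- contigs$seq[ord]
  ids <- contigs$id[ord]
  src <- src[ord]
  lens <- nchar(seqs)
  rcs <- revcomp(seqs)   # cached once; avoids per-pair reverse complements
  cth <- params$identity_threshold
  wl <- params$word_length

  rep_seq <- character(); rep_words <- list(); rep_len <- integer()
  out_cluster <- integer(n); out_ident <- numeric(n); out_strand <- character(n)
  out_isrep <- logical(n)

  for (i in seq_len(n)) {
    s <- seqs[i]
    w_f <- seq_words(s, wl)
    w_r <- seq_words(rcs[i], wl)
    assigned <- 0L; best_id <- -1; best_strand <- "+"
    nrep <- length(rep_seq)
    if (nrep > 0) {
      Ls <- lens[i]  # representatives are never shorter than the contig
      bound <- Ls - wl + 1 - wl * ceiling((1 - cth) * Ls)
      for (r in seq_len(nrep)) {
        if (params$use_word_filter && bound > 0) {
          ok <- sum(w_f %in% rep_words[[r]]) >= bound ||
            (params$both_strands && sum(w_r %in% rep_words[[r]]) >= bound)
          if (!ok) next
        }
        fwd <- overlap_align_cpp(s, rep_seq[r], params$match,
                                 params$mismatch, params$gap_open,
                                 params$gap_extend)
        ident <- fwd[["matches"]] / Ls
        strand <- "+"
        if (params$both_strands) {
          rev <- overlap_align_cpp(rcs[i], rep_seq[r], params$match,
                                   params$mismatch, params$gap_open,
                                   params$gap_extend)
          if (rev[["matches"]] / Ls > ident) {
            ident <- rev[["matches"]] / Ls
            strand <- "-"
          }
        }
        if (ident >= cth && ident > best_id) {
          assigned <- r; best_id <- ident; best_strand <- strand
          if (params$assign_mode == "first_match") break
        }
      }
    }
    if (assigned > 0L) {
      out_cluster[i] <- assigned - 1L
      out_ident[i] <- best_id
      out_strand[i] <- best_strand
    } else {
      rep_seq <- c(rep_seq, s)
      rep_words[[length(rep_seq)]] <- w_f
      rep_len <- c(rep_len, lens[i])
      out_cluster[i] <- length(rep_seq) - 1L
      out_ident[i] <- 1
      out_strand[i] <- "+"
      out_isrep[i] <- TRUE
    }
  }
  members <- data.frame(cluster_id = out_cluster, contig_id = ids,
                        length = lens, identity = out_ident,
                        strand = out_strand, is_rep = out_isrep,
                        source = src, stringsAsFactors = FALSE)
  members <- members[order(members$cluster_id, !members$is_rep,
                           -members$length), ]
  rownames(members) <- NULL
  cs <- new_cluster_set(members, params)
  cs$representatives <- data.frame(
    id = members$contig_id[members$is_rep],
    seq = rep_seq[members$cluster_id[members$is_rep] + 1L],
    stringsAsFactors = FALSE)
  cs
}

#' Summarise a cluster set
#'
#' @param cluster_set a `cluster_set`.
#' @return list with `n_clusters`, `n_singletons` (one-contig clusters),
#'   `n_true_clusters` (>= 2 contigs), `n_contigs`.
#' @export
cluster_counts <- function(cluster_set) {
  sizes <- table(cluster_set$members$cluster_id)
  list(n_clusters = length(sizes),
       n_singletons = sum(sizes == 1),
       n_true_clusters = sum(sizes >= 2),
       n_contigs = nrow(cluster_set$members))
}

#' Cluster counts across identity thresholds
#'
#' Runs a full greedy clustering per threshold and reports the number of
#' clusters, singletons and true clusters at each, the scan used to choose
#' the operating threshold.
#'
#' @param contigs pooled contig table.
#' @param thresholds identity fractions, each in \[0.90, 1.00\].
#' @param params base [cluster_params()]; the threshold is overridden per run.
#' @return data.frame with one row per threshold.
#' @export
cluster_threshold_scan <- function(contigs, thresholds,
                                   params = cluster_params()) {
  stopifnot(all(thresholds >= 0.90), all(thresholds <= 1.00))
  rows <- lapply(thresholds, function(th) {
    p <- params; p$identity_threshold <- th
    ct <- cluster_counts(greedy_cluster(contigs, p))
    data.frame(threshold = th, n_clusters = ct$n_clusters,
               n_singletons = ct$n_singletons,
               n_true_clusters = ct$n_true_clusters)
  })
  do.call(rbind, rows)
}

#' Write the contig-to-cluster map as TSV
#'
#' The map that attributes contig-level abundance to clusters, analogous to
#' a transcript-to-gene map.
#'
#' @param cluster_set a `cluster_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contig_map <- function(cluster_set, path) {
  m <- cluster_set$members
  rep_of <- setNames(m$contig_id[m$is_rep], m$cluster_id[m$is_rep])
  df <- data.frame(contig_id = m$contig_id, cluster_id = m$cluster_id,
                   representative_id = rep_of[as.character(m$cluster_id)],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
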