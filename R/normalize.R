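#' Digital normalization configuration
#'
#' @param k k-mer size, in \[11, 31\] (default 25).
#' @param max_cov coverage cap: a read is kept only while its median k-mer
#'   coverage among previously kept reads is below this (default 30; 50 is
#'   the other commonly used cap and is available here via this argument).
#' @param pair_aware treat reads as pairs (admit or reject jointly).
#' @return a `normalize_config` list.
#' @export
normalize_config <- function(k = 25, max_cov = 30, pair_aware = FALSE) {
  stopifnot(k >= 11, k <= 31, max_cov >= 1)
  structure(list(k = as.integer(k), max_cov = max_cov,
                 pair_aware = isTRUE(pair_aware)),
            class = "normalize_config")
}

# canonical form: lexicographic min of a k-mer and its reverse complement
# (reads come from both strands)
canonical_kmers <- function(seq, k) {
  w <- seq_words(seq, k)
  w <- w[!grepl("N", w, fixed = TRUE)]
  if (length(w) == 0) return(character())
  rc <- revcomp(w)
  ifelse(w <= rc, w, rc)
}

new_kmer_counter <- function() new.env(hash = TRUE, parent = emptyenv())

counter_add <- function(counter, kmers) {
  if (length(kmers) == 0) return(invisible(counter))
  tab <- table(kmers)
  for (w in names(tab)) {
    prev <- counter[[w]]
    counter[[w]] <- (if (is.null(prev)) 0L else prev) + as.integer(tab[[w]])
  }
  invisible(counter)
}

counter_get <- function(counter, kmers) {
  if (length(kmers) == 0) return(numeric())
  vapply(kmers, function(w) {
    v <- counter[[w]]
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Median k-mer coverage of a read
#'
#' The median of the counter's counts over the read's canonical k-mers;
#' k-mers absent from the counter count as 0. K-mers containing N are
#' skipped (a read with no usable k-mer has coverage 0).
#'
#' @param read DNA string, length >= `k`.
#' @param counter a k-mer counter environment.
#' @param k k-mer size.
#' @return median coverage (real).
#' @export
median_coverage <- function(read, counter, k) {
  if (nchar(read) < k) stop("read shorter than k")
  km <- canonical_kmers(read, k)
  if (length(km) == 0) return(0)
  median(counter_get(counter, km))
}

#' Streaming digital normalization of a read set
#'
#' Single pass in input order: a read is retained iff its median canonical
#' k-mer coverage, computed against the k-mers of previously retained reads,
#' is strictly below `max_cov`; the k-mers of a retained read are then added
#' to the counter. Over-represented transcripts are thus capped (an
#' identical read repeated many times keeps exactly `max_cov` copies) while
#' unique reads pass through untouched. The output is a subsequence of the
#' input and re-running on its own output changes nothing.
#'
#' In pair-aware mode `reads` and `mates` are parallel vectors; a pair is
#' admitted iff the mean of the two median coverages is below `max_cov`, so
#' pairs are never orphaned.
#'
#' @param reads character vector of read sequences (or a data.frame with a
#'   `seq` column, in which case retained rows are returned).
#' @param config a [normalize_config()].
#' @param mates optional parallel mate sequences (pair-aware mode).
#' @return retained reads in input order (same type as `reads`); attribute
#'   `retained` holds the logical keep vector.
#' @export
normalize_stream <- function(reads, config = normalize_config(),
                             mates = NULL) {
  df <- NULL
  if (is.data.frame(reads)) { df <- reads; reads <- reads$seq }
  pair <- config$pair_aware && !is.null(mates)
  if (config$pair_aware && is.null(mates) && !pair)
    pair <- FALSE
  counter <- new_kmer_counter()
  keep <- logical(length(reads))
  for (i in seq_along(reads)) {
    km <- canonical_kmers(reads[i], config$k)
    cov <- if (length(km)) median(counter_get(counter, km)) else 0
    if (pair) {
      km2 <- canonical_kmers(mates[i], config$k)
      cov2 <- if (length(km2)) median(counter_get(counter, km2)) else 0
      admit <- mean(c(cov, cov2)) < config$max_cov
      if (admit) { counter_add(counter, km); counter_add(counter, km2) }
    } else {
      admit <- cov < config$max_cov
      if (admit) counter_add(counter, km)
    }
    keep[i] <- admit
  }
  out <- if (!is.null(df)) df[keep, , drop = FALSE] else reads[keep]
  if (!is.null(df)) rownames(out) <- NULL
  attr(out, "retained") <- keep
  out
}
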