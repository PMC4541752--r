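#' Cluster filter configuration
#'
#' The retention rule applied to the clustered dataset: each cluster is
#' tested against three criteria — representative length >= `min_length`
#' (inclusive: a 500 bp cluster passes), number of contigs strictly greater
#' than `min_contigs_exclusive` (10 contigs fails), and summed FPKM strictly
#' greater than `min_sum_fpkm_exclusive` (FPKM 50 fails) — and discarded
#' only when at least two criteria fail. Tolerating one failure protects
#' weakly expressed genes and rare isoforms that a conjunctive filter would
#' drop.
#'
#' @param min_length minimal representative length in bases (pass is `>=`).
#' @param min_contigs_exclusive contig-count bound (pass is `>`).
#' @param min_sum_fpkm_exclusive summed-FPKM bound (pass is `>`).
#' @param max_failures_allowed failures tolerated before discarding
#'   (default 1: discard iff >= 2 criteria fail).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_length = 500, min_contigs_exclusive = 10,
                          min_sum_fpkm_exclusive = 50,
                          max_failures_allowed = 1) {
  stopifnot(min_length >= 0, min_contigs_exclusive >= 0,
            min_sum_fpkm_exclusive >= 0, max_failures_allowed >= 0)
  structure(list(min_length = min_length,
                 min_contigs_exclusive = min_contigs_exclusive,
                 min_sum_fpkm_exclusive = min_sum_fpkm_exclusive,
                 max_failures_allowed = max_failures_allowed),
            class = "filter_config")
}

#' Per-cluster metrics for the retention filter
#'
#' For each cluster: representative length, number of member contigs,
#' summed FPKM (over all member contigs and all samples), and the number of
#' distinct source assemblies among members. Contigs missing from the
#' abundance table contribute 0 FPKM; their number is reported in a warning
#' and in the `n_missing_abundance` attribute.
#'
#' @param cluster_set a `cluster_set`.
#' @param abundance an `abundance_table` in FPKM mode, or NULL (metrics then
#'   carry `sum_fpkm = NA` and the filter runs on the two remaining
#'   criteria).
#' @return data.frame `cluster_id`, `representative_id`, `length`,
#'   `n_contigs`, `sum_fpkm`, `n_sources`.
#' @export
compute_metrics <- function(cluster_set, abundance = NULL) {
  m <- cluster_set$members
  ids <- sort(unique(m$cluster_id))
  rep_rows <- m[m$is_rep, ]
  rep_of <- setNames(rep_rows$contig_id, rep_rows$cluster_id)
  len_of <- setNames(rep_rows$length, rep_rows$cluster_id)
  n_contigs <- as.integer(table(factor(m$cluster_id, levels = ids)))
  src <- ifelse(is.na(m$source), "?", m$source)
  n_sources <- as.integer(tapply(src, factor(m$cluster_id, levels = ids),
                                 function(s) length(unique(s))))
  n_missing <- 0L
  if (is.null(abundance)) {
    sum_fpkm <- rep(NA_real_, length(ids))
  } else {
    if (abundance$mode != "fpkm")
      stop("abundance must be in FPKM mode; convert counts first")
    per_contig <- rowSums(abundance$values)
    hit <- m$contig_id %in% names(per_contig)
    n_missing <- sum(!hit)
    if (n_missing > 0) {
      warning(n_missing,
              " member contig(s) absent from the abundance table; ",
              "they contribute 0 FPKM")
    }
    v <- ifelse(hit, per_contig[m$contig_id], 0)
    sum_fpkm <- as.numeric(tapply(v, factor(m$cluster_id, levels = ids), sum))
  }
  out <- data.frame(cluster_id = ids,
                    representative_id = rep_of[as.character(ids)],
                    length = as.integer(len_of[as.character(ids)]),
                    n_contigs = n_contigs, sum_fpkm = sum_fpkm,
                    n_sources = n_sources, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_missing_abundance") <- n_missing
  out
}

#' Apply the two-of-three retention rule
#'
#' Evaluates the three criteria of [filter_config()] per cluster and
#' discards a cluster iff its number of failed criteria exceeds
#' `max_failures_allowed`. When `sum_fpkm` is NA for every cluster (no
#' abundance supplied) the expression criterion is excluded and the rule is
#' applied over the remaining two criteria, with a warning.
#'
#' @param metrics output of [compute_metrics()].
#' @param config a [filter_config()].
#' @return `metrics` with added logical columns `pass_length`,
#'   `pass_contigs`, `pass_fpkm`, integer `n_failed` and logical `retained`.
#' @export
apply_filter <- function(metrics, config = filter_config()) {
  two_mode <- all(is.na(metrics$sum_fpkm))
  if (two_mode && nrow(metrics) > 0) {
    warning("no abundance available: filtering on length and contig count only")
  }
  out <- metrics
  out$pass_length <- metrics$length >= config$min_length
  out$pass_contigs <- metrics$n_contigs > config$min_contigs_exclusive
  out$pass_fpkm <- if (two_mode) NA else
    metrics$sum_fpkm > config$min_sum_fpkm_exclusive
  fails <- (!out$pass_length) + (!out$pass_contigs) +
    (if (two_mode) 0L else !out$pass_fpkm)
  out$n_failed <- as.integer(fails)
  out$retained <- out$n_failed <= config$max_failures_allowed
  out
}

#' Count clusters falling below candidate thresholds
#'
#' For each candidate value, the number of clusters strictly below it, per
#' metric — the scan used to place the filter thresholds where the count of
#' removed clusters stops changing quickly.
#'
#' @param metrics output of [compute_metrics()].
#' @param contig_thresholds,fpkm_thresholds,length_thresholds candidate
#'   values (any may be NULL to skip that metric).
#' @return data.frame `metric`, `threshold`, `n_below`.
#' @export
filter_threshold_scan <- function(metrics, contig_thresholds = NULL,
                                  fpkm_thresholds = NULL,
                                  length_thresholds = NULL) {
  if (is.null(contig_thresholds) && is.null(fpkm_thresholds) &&
      is.null(length_thresholds))
    stop("no candidate thresholds supplied")
  one <- function(vals, th, name) {
    if (is.null(th)) return(NULL)
    data.frame(metric = name, threshold = th,
               n_below = vapply(th, function(t) sum(vals < t), integer(1)))
  }
  out <- rbind(one(metrics$n_contigs, contig_thresholds, "n_contigs"),
               one(metrics$sum_fpkm, fpkm_thresholds, "sum_fpkm"),
               one(metrics$length, length_thresholds, "length"))
  rownames(out) <- NULL
  out
}

#' Cluster x source-assembly participation matrix
#'
#' Cell (k, s) counts the members of cluster k contributed by source s; row
#' sums equal cluster sizes and the grand total is the pooled contig count.
#'
#' @param cluster_set a `cluster_set`.
#' @return integer matrix, rows = cluster ids, columns = source tags.
#' @export
participation_matrix <- function(cluster_set) {
  m <- cluster_set$members
  src <- ifelse(is.na(m$source), "?", m$source)
  tab <- table(factor(m$cluster_id, levels = sort(unique(m$cluster_id))),
               src)
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  mat
}

#' Pearson correlation of assemblies over cluster participation
#'
#' Two assemblies are strongly correlated when their contigs land in the
#' same clusters. Computed over true clusters (>= 2 members) by default,
#' since singleton membership carries no co-occurrence signal. Assemblies
#' with zero-variance participation get NA correlations.
#'
#' @param participation matrix from [participation_matrix()].
#' @param cluster_sizes optional vector of cluster sizes (row sums used if
#'   missing).
#' @param true_clusters_only restrict to clusters with >= 2 members.
#' @return symmetric source x source correlation matrix (diagonal 1).
#' @export
assembly_correlation <- function(participation, cluster_sizes = NULL,
                                 true_clusters_only = TRUE) {
  sizes <- if (is.null(cluster_sizes)) rowSums(participation) else
    cluster_sizes
  mat <- if (true_clusters_only)
    participation[sizes >= 2, , drop = FALSE] else participation
  if (nrow(mat) < 2) stop("need at least 2 clusters for correlations")
  zerovar <- apply(mat, 2, var) == 0
  r <- suppressWarnings(cor(mat))
  r[zerovar, ] <- NA
  r[, zerovar] <- NA
  diag(r) <- ifelse(zerovar, NA, 1)
  r
}

#' Histogram of cluster source breadth and the core set
#'
#' Tabulates clusters by the number of distinct source assemblies their
#' members come from, and lists the core clusters — those drawing contigs
#' from more than `breadth_cutoff` assemblies, the consensus core that many
#' independent samples support.
#'
#' @param cluster_set a `cluster_set`.
#' @param breadth_cutoff core membership requires `n_sources >` this
#'   (default 10).
#' @return list with `histogram` (data.frame `n_sources`, `n_clusters`) and
#'   `core` (integer vector of core cluster ids).
#' @export
breadth_histogram <- function(cluster_set, breadth_cutoff = 10) {
  m <- cluster_set$members
  src <- ifelse(is.na(m$source), "?", m$source)
  ids <- sort(unique(m$cluster_id))
  breadth <- as.integer(tapply(src, factor(m$cluster_id, levels = ids),
                               function(s) length(unique(s))))
  tab <- table(breadth)
  list(histogram = data.frame(n_sources = as.integer(names(tab)),
                              n_clusters = as.integer(tab)),
       core = ids[breadth > breadth_cutoff])
}
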