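#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = fragments * 1e9 / (effective_length * total_mapped)`.
#'
#' @param fragments fragment count(s), >= 0.
#' @param effective_length transcript effective length(s), bases, > 0.
#' @param total_mapped library size (mapped fragments), > 0.
#' @return FPKM value(s).
#' @export
fpkm <- function(fragments, effective_length, total_mapped) {
  if (any(effective_length <= 0)) stop("effective_length must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  fragments * 1e9 / (effective_length * total_mapped)
}

#' Convert a counts abundance table to FPKM
#'
#' Per-sample library sizes default to the column sums of the count matrix.
#'
#' @param abundance an `abundance_table` in counts mode with lengths.
#' @param total_mapped optional per-sample library sizes.
#' @return an `abundance_table` in FPKM mode.
#' @export
counts_to_fpkm <- function(abundance, total_mapped = NULL) {
  stopifnot(inherits(abundance, "abundance_table"))
  if (abundance$mode != "counts") stop("abundance is not in counts mode")
  if (is.null(abundance$lengths)) stop("counts table has no contig lengths")
  if (is.null(total_mapped)) total_mapped <- colSums(abundance$values)
  lens <- abundance$lengths[rownames(abundance$values)]
  vals <- sweep(abundance$values * 1e9 / lens, 2, total_mapped, "/")
  abundance_table(vals, lengths = abundance$lengths, mode = "fpkm")
}

#' Aggregate contig-level FPKM to clusters
#'
#' Cluster-level expression is the sum of member-contig FPKM per sample,
#' attributed to the cluster (i.e. its representative) through the
#' contig-to-cluster map — the transcript-to-gene-map analogue at cluster
#' granularity. Contigs absent from the map are dropped with a warning;
#' per-sample totals over mapped contigs are conserved exactly.
#'
#' @param contig_fpkm an `abundance_table` in FPKM mode.
#' @param contig_to_cluster named vector (or 2-column data.frame
#'   `contig_id`, `cluster_id`) mapping contig ids to cluster ids.
#' @return a `cluster_expression` object: list with `values` (cluster x
#'   sample matrix), `n_unmapped` and the map used.
#' @export
aggregate_to_clusters <- function(contig_fpkm, contig_to_cluster) {
  stopifnot(inherits(contig_fpkm, "abundance_table"))
  if (contig_fpkm$mode != "fpkm") stop("contig abundance must be FPKM")
  if (is.data.frame(contig_to_cluster)) {
    contig_to_cluster <- setNames(contig_to_cluster$cluster_id,
                                  contig_to_cluster$contig_id)
  }
  ids <- rownames(contig_fpkm$values)
  mapped <- ids %in% names(contig_to_cluster)
  if (any(!mapped)) {
    warning(sum(!mapped), " contig(s) not in the contig-to-cluster map; dropped")
  }
  vals <- contig_fpkm$values[mapped, , drop = FALSE]
  grp <- factor(contig_to_cluster[rownames(vals)])
  agg <- rowsum(vals, grp)
  structure(list(values = agg, n_unmapped = sum(!mapped),
                 contig_to_cluster = contig_to_cluster),
            class = "cluster_expression")
}

#' @export
print.cluster_expression <- function(x, ...) {
  cat("cluster_expression:", nrow(x$values), "clusters x", ncol(x$values),
      "samples (", x$n_unmapped, "unmapped contigs dropped )\n")
  invisible(x)
}

#' Normalise cluster expression to a reference cluster
#'
#' Divides every cell by the reference (housekeeping) cluster's value in
#' the same sample, the RPS9-style normalisation applied before comparing
#' with qPCR.
#'
#' @param cluster_expr a `cluster_expression` or a plain matrix.
#' @param reference_cluster_id row id of the reference cluster.
#' @return normalised matrix (reference row becomes all 1).
#' @export
normalize_to_reference <- function(cluster_expr, reference_cluster_id) {
  vals <- if (inherits(cluster_expr, "cluster_expression"))
    cluster_expr$values else cluster_expr
  ref_id <- as.character(reference_cluster_id)
  if (!ref_id %in% rownames(vals))
    stop("reference cluster '", ref_id, "' not present")
  ref <- vals[ref_id, ]
  zero <- ref == 0
  if (any(zero)) {
    stop("reference FPKM is zero in ", colnames(vals)[which(zero)[1]])
  }
  sweep(vals, 2, ref, "/")
}

#' qPCR / RNA-seq concordance of matched expression values
#'
#' Ordinary least squares of `log2(rnaseq)` on `log2(qpcr)` over the
#' matched (gene, sample) pairs shared by the two matrices. Pairs where
#' either value is 0 are excluded (and counted) unless `log_floor > 0`, in
#' which case the floor is added inside the log. Reports slope, intercept
#' and the adjusted r-squared of the simple linear model,
#' `1 - (1 - r2) * (n - 1) / (n - 2)`.
#'
#' @param qpcr gene x sample matrix of (normalised) qPCR copy numbers.
#' @param rnaseq gene x sample matrix of matching (normalised) FPKM.
#' @param log_floor additive floor applied before log2 (default 0 =
#'   exclusion of zero pairs).
#' @return list (`ConcordanceResult`): `slope`, `intercept`, `r2_adjusted`,
#'   `n_points`, `excluded_zero_pairs`.
#' @export
concordance <- function(qpcr, rnaseq, log_floor = 0) {
  genes <- intersect(rownames(qpcr), rownames(rnaseq))
  samples <- intersect(colnames(qpcr), colnames(rnaseq))
  if (length(genes) == 0 || length(samples) == 0)
    stop("no matched (gene, sample) pairs")
  q <- as.vector(qpcr[genes, samples, drop = FALSE])
  r <- as.vector(rnaseq[genes, samples, drop = FALSE])
  excluded <- 0L
  if (log_floor > 0) {
    q <- q + log_floor
    r <- r + log_floor
  } else {
    zero <- q == 0 | r == 0
    excluded <- sum(zero)
    q <- q[!zero]; r <- r[!zero]
  }
  if (length(q) < 3) stop("fewer than 3 usable pairs for the concordance model")
  fit <- lm(log2(r) ~ log2(q))
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2_adjusted = s$adj.r.squared, n_points = length(q),
       excluded_zero_pairs = excluded)
}
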