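#' Local alignment scoring scheme with Karlin-Altschul constants
#'
#' Integer match/mismatch/affine-gap scores plus the Karlin-Altschul
#' `lambda` (nats per score unit) and `K` used to express raw scores in
#' bits. When `lambda`/`K` are not supplied they are looked up from a small
#' table of nominal ungapped values for common reward/penalty pairs.
#' Because every reconstruction ratio is self-normalised (best-hit bits over
#' self-alignment bits) the ratios are largely insensitive to these
#' constants; they matter only for the absolute bit values.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores; a gap of length
#'   g costs `gap_open + g * gap_extend`.
#' @param lambda,K optional Karlin-Altschul constants.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L, lambda = NULL, K = NULL) {
  stopifnot(match > 0, mismatch < 0)
  if (is.null(lambda) || is.null(K)) {
    # nominal ungapped constants by (reward, penalty)
    tab <- list("1/-2" = c(1.28, 0.46), "1/-3" = c(1.374, 0.711),
                "1/-4" = c(1.383, 0.738), "2/-3" = c(0.634, 0.408),
                "1/-1" = c(1.098, 0.333))
    key <- paste0(match, "/", mismatch)
    ka <- tab[[key]]
    if (is.null(ka))
      stop("no tabulated lambda/K for scores ", key,
           "; supply lambda and K explicitly")
    lambda <- ka[1]; K <- ka[2]
  }
  stopifnot(lambda > 0, K > 0, K < 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Convert a raw local-alignment score to bits
#'
#' `bits = (lambda * raw - ln K) / ln 2`, the standard normalised score;
#' strictly increasing in the raw score.
#'
#' @param raw_score raw score(s) under `scheme`.
#' @param scheme a [scoring_scheme()].
#' @return bit score(s).
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Self-alignment bitscore of a reference gene
#'
#' The bitscore of the sequence locally aligned to itself — the "ideal
#' reconstruction" that normalises every ratio to 1.
#'
#' @param residues reference DNA string.
#' @param scheme a [scoring_scheme()].
#' @return bits.
#' @export
self_bits <- function(residues, scheme = scoring_scheme()) {
  bitscore(local_score_cpp(residues, residues, scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend), scheme)
}

#' Best local-alignment hits of a gene in an assembly
#'
#' Per contig, the maximum Smith-Waterman score of the gene over both
#' strands (exact affine-gap dynamic programming). Contigs sharing fewer
#' than `min_seed_words` exact words of length `seed_length` with the gene
#' (either strand) are skipped as score 0 — hits without a seed word are
#' not reportable, the usual seeded-search behaviour; set `min_seed_words =
#' 0` for exhaustive alignment of every contig.
#'
#' @param gene reference DNA string.
#' @param contigs contig table (`id`, `seq`) or empty.
#' @param scheme a [scoring_scheme()].
#' @param min_seed_words word prescreen count (default 1).
#' @param seed_length prescreen word size (default 11).
#' @return data.frame `contig_id`, `raw_score`, `bits`, sorted by descending
#'   score (bits reported only for positive raw scores; otherwise 0 raw).
#' @export
best_local_hits <- function(gene, contigs, scheme = scoring_scheme(),
                            min_seed_words = 1, seed_length = 11) {
  if (is.null(contigs) || nrow(contigs) == 0) {
    return(data.frame(contig_id = character(), raw_score = numeric(),
                      bits = numeric(), stringsAsFactors = FALSE))
  }
  consider <- rep(TRUE, nrow(contigs))
  if (min_seed_words > 0) {
    gw <- seq_words(gene, seed_length)
    gw_rc <- seq_words(revcomp(gene), seed_length)
    consider <- vapply(contigs$seq, function(s) {
      cw <- seq_words(s, seed_length)
      sum(cw %in% gw) >= min_seed_words ||
        sum(cw %in% gw_rc) >= min_seed_words
    }, logical(1), USE.NAMES = FALSE)
  }
  raw <- numeric(nrow(contigs))
  if (any(consider)) {
    fwd <- local_score_batch_cpp(gene, contigs$seq[consider], scheme$match,
                                 scheme$mismatch, scheme$gap_open,
                                 scheme$gap_extend)
    rev <- local_score_batch_cpp(gene, revcomp(contigs$seq[consider]),
                                 scheme$match, scheme$mismatch,
                                 scheme$gap_open, scheme$gap_extend)
    raw[consider] <- pmax(fwd, rev)
  }
  out <- data.frame(contig_id = contigs$id, raw_score = raw,
                    bits = bitscore(raw, scheme),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$raw_score), ]
  rownames(out) <- NULL
  out
}

#' Reconstruction quality of one gene in one assembly
#'
#' The best-hit bitscore divided by the gene's self-alignment bitscore: 1
#' means the assembly contains a contig reconstructing the gene as well as
#' the reference itself; a half-length exact fragment scores about 0.5 for
#' kb-scale genes. Assemblies with no positive-scoring local alignment get
#' ratio 0 and no best contig.
#'
#' @param gene reference DNA string.
#' @param contigs contig table of the assembly.
#' @param scheme a [scoring_scheme()].
#' @param gene_self_bits precomputed [self_bits()] (computed if NULL).
#' @param hit_threshold ratio above which a contig counts as a hit
#'   (default 0.8, the isoform-detection threshold).
#' @param ... passed to [best_local_hits()].
#' @return list (`QualityCell`): `ratio` in \[0, 1\], `best_contig_id`
#'   (NA when ratio is 0), `n_hits_above` (contigs with individual ratio >
#'   `hit_threshold`).
#' @export
reconstruction_ratio <- function(gene, contigs, scheme = scoring_scheme(),
                                 gene_self_bits = NULL, hit_threshold = 0.8,
                                 ...) {
  if (is.null(gene_self_bits)) gene_self_bits <- self_bits(gene, scheme)
  hits <- best_local_hits(gene, contigs, scheme, ...)
  pos <- hits[hits$raw_score > 0, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(list(ratio = 0, best_contig_id = NA_character_, n_hits_above = 0L))
  }
  ratios <- pmin(1, pmax(0, pos$bits / gene_self_bits))
  list(ratio = ratios[1],
       best_contig_id = pos$contig_id[1],
       n_hits_above = sum(ratios > hit_threshold))
}

#' Number of putative isoform hits of a gene in an assembly
#'
#' Distinct contigs whose individual bitscore ratio exceeds
#' `hit_threshold` (default 0.8); more than one hit flags a putative
#' isoform, the way near-identical isoform pairs show up as two
#' high-ratio contigs.
#'
#' @inheritParams reconstruction_ratio
#' @return integer count.
#' @export
isoform_hit_count <- function(gene, contigs, scheme = scoring_scheme(),
                              hit_threshold = 0.8, gene_self_bits = NULL,
                              ...) {
  reconstruction_ratio(gene, contigs, scheme, gene_self_bits,
                       hit_threshold, ...)$n_hits_above
}

#' Gene x assembly reconstruction-quality matrix
#'
#' The heatmap behind assembly comparison: per gene and assembly the
#' bitscore ratio, the best contig, and the number of hits above the
#' isoform threshold, plus per-assembly min/mean summaries.
#'
#' @param genes gene table (`gene_id`, `seq`).
#' @param assemblies named list of contig tables.
#' @param scheme a [scoring_scheme()].
#' @param hit_threshold isoform hit threshold (default 0.8).
#' @param ... passed to [best_local_hits()].
#' @return data.frame `gene_id`, `assembly_id`, `ratio`, `best_contig_id`,
#'   `n_hits_above`; attribute `summary` holds per-assembly min/mean ratio.
#' @export
quality_matrix <- function(genes, assemblies, scheme = scoring_scheme(),
                           hit_threshold = 0.8, ...) {
  stopifnot(nrow(genes) > 0, length(assemblies) > 0,
            !is.null(names(assemblies)))
  selfb <- vapply(genes$seq, self_bits, numeric(1), scheme = scheme,
                  USE.NAMES = FALSE)
  rows <- list()
  for (a in names(assemblies)) {
    for (g in seq_len(nrow(genes))) {
      qc <- reconstruction_ratio(genes$seq[g], assemblies[[a]], scheme,
                                 gene_self_bits = selfb[g],
                                 hit_threshold = hit_threshold, ...)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = genes$gene_id[g], assembly_id = a, ratio = qc$ratio,
        best_contig_id = qc$best_contig_id,
        n_hits_above = qc$n_hits_above, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out$ratio, out$assembly_id),
                                function(r) data.frame(min_ratio = min(r),
                                                       mean_ratio = mean(r))))
  summ <- data.frame(assembly_id = rownames(summ), summ,
                     row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "summary") <- summ
  out
}

#' Cumulative hit-coverage table
#'
#' From an externally produced tabular hit set: hits above the e-value
#' cutoff are removed; per target the best coverage is the maximum aligned
#' target span over its length (percent); the table reports, for each
#' coverage threshold, the cumulative number of targets whose best coverage
#' reaches at least that threshold (non-decreasing as the threshold drops).
#'
#' @param hits data.frame as from [read_hits()].
#' @param target_lengths named numeric vector of target lengths (bases).
#' @param coverage_thresholds percents (default 100, 90, ..., 10).
#' @param evalue_cutoff keep hits with `e_value <=` this (default 1e-20).
#' @return data.frame `coverage_threshold`, `n_targets`.
#' @export
hit_coverage_table <- function(hits, target_lengths,
                               coverage_thresholds = seq(100, 10, by = -10),
                               evalue_cutoff = 1e-20) {
  unknown <- setdiff(unique(hits$subject_id), names(target_lengths))
  if (length(unknown))
    stop("hit references unknown target: ", unknown[1])
  keep <- hits$e_value <= evalue_cutoff
  h <- hits[keep, , drop = FALSE]
  best <- numeric(0)
  if (nrow(h) > 0) {
    span <- abs(h$s_end - h$s_start) + 1
    cov <- 100 * span / target_lengths[h$subject_id]
    best <- tapply(cov, h$subject_id, max)
  }
  data.frame(coverage_threshold = coverage_thresholds,
             n_targets = vapply(coverage_thresholds,
                                function(t) sum(best >= t), integer(1)))
}
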