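canonical_stages <- c("simulate", "normalize", "merge_cluster", "filter",
                      "quality", "quantify")

stage_deps <- list(simulate = character(), normalize = "simulate",
                   merge_cluster = "simulate", filter = "merge_cluster",
                   quality = "simulate", quantify = c("merge_cluster",
                                                      "filter"))

#' Pipeline configuration
#'
#' Bundles every stage's parameters plus the single top-level seed that is
#' fanned out to per-stage child seeds by fixed arithmetic, so a rerun with
#' the same config is bit-identical and each stage is individually
#' reproducible. `stages` must respect the canonical order
#' simulate, normalize, merge_cluster, filter, quality, quantify (any
#' downstream suffix may be omitted; `normalize` is an optional pre-stage).
#'
#' @param seed top-level integer seed.
#' @param stages character vector of stages to run.
#' @param n_genes,n_isoform_pairs,length_range,isoform_identity gene-set
#'   parameters ([generate_gene_set()]).
#' @param n_assemblies,fragmentation_prob,dropout_prob,allele_rate assembly
#'   simulation parameters ([generate_assemblies()]).
#' @param n_samples,lognormal_mu,lognormal_sigma expression parameters
#'   ([generate_expression()]); the last gene of the set acts as the
#'   constant housekeeping reference.
#' @param simulate_abundance set FALSE to run the filter without expression
#'   (two-criteria degradation, with warning).
#' @param read_length,duplication_factor read simulation for the
#'   normalization stage.
#' @param cluster a [cluster_params()].
#' @param filter a [filter_config()].
#' @param normalize a [normalize_config()].
#' @param scheme a [scoring_scheme()].
#' @param hit_threshold isoform hit threshold (default 0.8).
#' @param quality_panel_size genes scored in the quality stage (isoform
#'   members and the reference first).
#' @param qpcr_sigma log-normal noise of the synthetic qPCR measurements.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, stages = canonical_stages,
                            n_genes = 12, n_isoform_pairs = 2,
                            length_range = c(900, 1500),
                            isoform_identity = 0.96, n_assemblies = 5,
                            fragmentation_prob = 0.3, dropout_prob = 0.1,
                            allele_rate = 2, n_samples = 6,
                            lognormal_mu = 3, lognormal_sigma = 1,
                            simulate_abundance = TRUE, read_length = 100,
                            duplication_factor = 1,
                            cluster = cluster_params(),
                            filter = filter_config(),
                            normalize = normalize_config(),
                            scheme = scoring_scheme(),
                            hit_threshold = 0.8, quality_panel_size = 6,
                            qpcr_sigma = 0.1) {
  stages <- match.arg(stages, canonical_stages, several.ok = TRUE)
  idx <- match(stages, canonical_stages)
  if (is.unsorted(idx, strictly = TRUE))
    stop("stages must follow the canonical order: ",
         paste(canonical_stages, collapse = ", "))
  for (s in stages) {
    miss <- setdiff(stage_deps[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage(s): ", paste(miss, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), stages = stages, n_genes = n_genes,
                 n_isoform_pairs = n_isoform_pairs,
                 length_range = length_range,
                 isoform_identity = isoform_identity,
                 n_assemblies = n_assemblies,
                 fragmentation_prob = fragmentation_prob,
                 dropout_prob = dropout_prob, allele_rate = allele_rate,
                 n_samples = n_samples, lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 simulate_abundance = isTRUE(simulate_abundance),
                 read_length = read_length,
                 duplication_factor = duplication_factor, cluster = cluster,
                 filter = filter, normalize = normalize, scheme = scheme,
                 hit_threshold = hit_threshold,
                 quality_panel_size = quality_panel_size,
                 qpcr_sigma = qpcr_sigma),
            class = "pipeline_config")
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

#' Run the consensus-transcriptome pipeline
#'
#' Executes the configured stages in order, writing every stage's outputs
#' (FASTA/TSV/.clstr/FASTQ/JSON) under `out_dir` before the next stage
#' starts, and a machine-readable `summary.json` at the end. A rerun with
#' the same config (same seed) produces identical outputs. A stage failure
#' aborts with the failing stage named; earlier outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return the summary list, invisibly; also written as
#'   `out_dir/summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  env <- new.env()
  summary <- list(seed = config$seed, stages = st)
  run_stage <- function(name, fun) {
    if (!name %in% st) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    d <- file.path(out_dir, "simulate")
    dir.create(d, showWarnings = FALSE)
    genes <- generate_gene_set(config$n_genes, config$n_isoform_pairs,
                               config$length_range, config$isoform_identity,
                               seed = child_seed(config$seed, 1))
    sim <- generate_assemblies(genes, config$n_assemblies,
                               config$fragmentation_prob,
                               config$dropout_prob, config$allele_rate,
                               seed = child_seed(config$seed, 2))
    env$genes <- genes
    env$assemblies <- sim$assemblies
    env$contig_map <- sim$contig_map
    env$reference_gene <- genes$gene_id[nrow(genes)]
    write_fasta(data.frame(id = genes$gene_id, seq = genes$seq),
                file.path(d, "genes.fasta"))
    for (tag in names(sim$assemblies))
      write_fasta(sim$assemblies[[tag]], file.path(d, paste0(tag, ".fasta")))
    write.table(sim$contig_map, file.path(d, "truth_contig_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (config$simulate_abundance) {
      expr <- generate_expression(genes, sim$contig_map, config$n_samples,
                                  config$lognormal_mu,
                                  config$lognormal_sigma,
                                  reference_gene_id = env$reference_gene,
                                  seed = child_seed(config$seed, 3))
      env$gene_fpkm <- expr$gene_fpkm
      env$abundance <- expr$abundance
      write_abundance(expr$abundance, file.path(d, "abundance.tsv"))
    }
    if ("normalize" %in% st) {
      env$reads <- generate_reads(genes, config$read_length,
                                  duplication_factor =
                                    config$duplication_factor,
                                  seed = child_seed(config$seed, 4))
      write_fastq(env$reads, file.path(d, "reads.fastq"))
    }
    stage_log("simulate", nrow(genes),
              sum(vapply(sim$assemblies, nrow, integer(1))))
    summary$simulate <<- list(
      n_genes = nrow(genes),
      n_contigs = sum(vapply(sim$assemblies, nrow, integer(1))),
      reference_gene = env$reference_gene)
  })

  run_stage("normalize", function() {
    d <- file.path(out_dir, "normalize")
    dir.create(d, showWarnings = FALSE)
    kept <- normalize_stream(env$reads, config$normalize)
    write_fastq(kept, file.path(d, "reads.normalized.fastq"))
    stage_log("normalize", nrow(env$reads), nrow(kept))
    summary$normalize <<- list(n_in = nrow(env$reads), n_out = nrow(kept))
  })

  run_stage("merge_cluster", function() {
    d <- file.path(out_dir, "merge_cluster")
    dir.create(d, showWarnings = FALSE)
    pooled <- pool_assemblies(env$assemblies)
    cs <- greedy_cluster(pooled, config$cluster)
    env$pooled <- pooled
    env$cluster_set <- cs
    write_clstr(cs, file.path(d, "clusters.clstr"))
    write_fasta(cs$representatives, file.path(d, "representatives.fasta"))
    write_contig_map(cs, file.path(d, "contig_to_cluster.tsv"))
    ct <- cluster_counts(cs)
    stage_log("merge_cluster", nrow(pooled), ct$n_clusters)
    summary$merge_cluster <<- ct
  })

  run_stage("filter", function() {
    d <- file.path(out_dir, "filter")
    dir.create(d, showWarnings = FALSE)
    ab <- if (config$simulate_abundance) env$abundance else NULL
    metrics <- compute_metrics(env$cluster_set, ab)
    flt <- apply_filter(metrics, config$filter)
    env$filtered <- flt
    write.table(flt, file.path(d, "filter_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    scan <- filter_threshold_scan(
      metrics, contig_thresholds = c(2, 3, 5, 10, 15),
      fpkm_thresholds = if (config$simulate_abundance)
        c(5, 10, 25, 50, 100) else NULL,
      length_thresholds = c(200, 300, 500, 1000))
    write.table(scan, file.path(d, "filter_threshold_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    reps <- env$cluster_set$representatives
    keep_ids <- flt$representative_id[flt$retained]
    write_fasta(reps[reps$id %in% keep_ids, , drop = FALSE],
                file.path(d, "retained.fasta"))
    pm <- participation_matrix(env$cluster_set)
    write.table(data.frame(cluster_id = rownames(pm), pm,
                           check.names = FALSE),
                file.path(d, "participation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    bh <- breadth_histogram(env$cluster_set)
    write.table(bh$histogram, file.path(d, "breadth_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("filter", nrow(flt), sum(flt$retained))
    summary$filter <<- list(n_clusters = nrow(flt),
                            retained = sum(flt$retained),
                            discarded = sum(!flt$retained))
  })

  run_stage("quality", function() {
    d <- file.path(out_dir, "quality")
    dir.create(d, showWarnings = FALSE)
    genes <- env$genes
    pref <- unique(c(which(genes$role == "isoform_member"),
                     which(genes$gene_id == env$reference_gene)))
    panel_idx <- head(unique(c(pref, seq_len(nrow(genes)))),
                      config$quality_panel_size)
    panel <- genes[sort(panel_idx), , drop = FALSE]
    qm <- quality_matrix(panel, env$assemblies, config$scheme,
                         hit_threshold = config$hit_threshold,
                         min_seed_words = 1)
    env$quality <- qm
    write.table(qm, file.path(d, "quality_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(attr(qm, "summary"), file.path(d, "quality_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("quality", nrow(panel), nrow(qm))
    summary$quality <<- list(
      n_genes = nrow(panel), mean_ratio = mean(qm$ratio),
      min_ratio = min(qm$ratio),
      mean_hits_above = mean(qm$n_hits_above))
  })

  run_stage("quantify", function() {
    d <- file.path(out_dir, "quantify")
    dir.create(d, showWarnings = FALSE)
    if (!config$simulate_abundance) {
      stage_log("quantify", 0L, 0L)
      summary$quantify <<- list(skipped = "no abundance simulated")
      return(invisible(NULL))
    }
    cs <- env$cluster_set
    clexpr <- aggregate_to_clusters(env$abundance, cs$contig_to_cluster)
    write.table(data.frame(cluster_id = rownames(clexpr$values),
                           clexpr$values, check.names = FALSE),
                file.path(d, "cluster_fpkm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    # cluster carrying each gene = cluster of its longest truth contig
    cmap <- env$contig_map
    cmap$len <- cmap$end - cmap$start + 1
    cmap <- cmap[order(cmap$gene_id, -cmap$len), ]
    gene_cluster <- setNames(
      as.character(cs$contig_to_cluster[cmap$pooled_id[!duplicated(cmap$gene_id)]]),
      cmap$gene_id[!duplicated(cmap$gene_id)])
    if (!env$reference_gene %in% names(gene_cluster))
      stop("reference gene absent from every assembly; cannot normalise")
    ref_cluster <- gene_cluster[[env$reference_gene]]
    norm <- normalize_to_reference(clexpr, ref_cluster)
    present <- intersect(rownames(env$gene_fpkm), names(gene_cluster))
    rnaseq <- norm[gene_cluster[present], , drop = FALSE]
    rownames(rnaseq) <- present
    set.seed(as.integer(child_seed(config$seed, 5)))
    noise <- matrix(rlnorm(length(env$gene_fpkm), 0, config$qpcr_sigma),
                    nrow = nrow(env$gene_fpkm))
    qpcr <- env$gene_fpkm * noise
    qpcr <- sweep(qpcr, 2, qpcr[env$reference_gene, ], "/")
    conc <- concordance(qpcr, rnaseq)
    env$concordance <- conc
    write.table(data.frame(stat = names(unlist(conc)),
                           value = unlist(conc)),
                file.path(d, "concordance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stage_log("quantify", nrow(env$abundance$values), nrow(clexpr$values))
    summary$quantify <<- conc
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Human-readable report of a pipeline run
#'
#' Collects the run's headline tables — the filter threshold scan, the
#' quality matrix with hit counts, the source-breadth histogram and the
#' filter accounting — from a completed run directory. Stages that were not
#' run are listed as absent rather than failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list of tables (and `absent`, the missing pieces); printed
#'   summary as a side effect.
#' @export
report <- function(run_dir) {
  out <- list(absent = character())
  grab <- function(name, path, reader = function(p)
    read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)) {
    if (file.exists(path)) out[[name]] <<- reader(path)
    else out$absent <<- c(out$absent, name)
  }
  grab("threshold_scan", file.path(run_dir, "filter",
                                   "filter_threshold_scan.tsv"))
  grab("quality_matrix", file.path(run_dir, "quality", "quality_matrix.tsv"))
  grab("breadth_histogram", file.path(run_dir, "filter",
                                      "breadth_histogram.tsv"))
  grab("filter_report", file.path(run_dir, "filter", "filter_report.tsv"))
  grab("summary", file.path(run_dir, "summary.json"),
       function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  if (!is.null(out$filter_report)) {
    fr <- out$filter_report
    out$filter_accounting <- data.frame(
      total = nrow(fr), retained = sum(fr$retained),
      discarded = sum(!fr$retained))
    cat(sprintf("clusters: %d total, %d retained, %d discarded\n",
                nrow(fr), sum(fr$retained), sum(!fr$retained)))
  }
  if (length(out$absent))
    cat("absent:", paste(out$absent, collapse = ", "), "\n")
  out
}
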