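#' Mutate a sequence to a target identity by substitutions
#'
#' Introduces exactly `round((1 - target_identity) * L)` substitutions at
#' distinct positions (each to a different base, no indels), the way true
#' isoform pairs such as the two secologanin synthase genes differ at the
#' nucleotide level. Deterministic for a fixed seed.
#'
#' @param residues DNA string.
#' @param target_identity fraction in (0.5, 1\]; 1 returns the input.
#' @param seed integer seed.
#' @return mutated DNA string.
#' @export
mutate_to_identity <- function(residues, target_identity, seed) {
  stopifnot(target_identity > 0.5, target_identity <= 1)
  if (target_identity == 1) return(residues)
  L <- nchar(residues)
  k <- round((1 - target_identity) * L)
  if (k == 0) return(residues)
  set.seed(as.integer(seed %% 2147483647))
  pos <- sample.int(L, k)
  chars <- strsplit(residues, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a ground-truth gene set
#'
#' Builds `n_genes` random coding-length DNA sequences; the first
#' `2 * n_isoform_pairs` of them are organised into isoform pairs, the
#' second member of each pair derived from the first by
#' [mutate_to_identity()] at `isoform_identity` (default 0.96, the kind of
#' divergence seen between true isoforms that clustering must keep apart).
#'
#' @param n_genes total genes (>= `2 * n_isoform_pairs`).
#' @param n_isoform_pairs number of isoform pairs.
#' @param length_range integer range of gene lengths (bases, min 300).
#' @param isoform_identity target identity within a pair.
#' @param seed integer seed; output is byte-identical for equal seeds.
#' @return data.frame `gene_id`, `seq`, `length`, `role`
#'   (`ordinary`/`isoform_member`), `family_id` (NA unless paired).
#' @export
generate_gene_set <- function(n_genes, n_isoform_pairs = 0,
                              length_range = c(900, 1500),
                              isoform_identity = 0.96, seed = 1) {
  if (n_genes < 2 * n_isoform_pairs)
    stop("n_genes must be at least 2 * n_isoform_pairs")
  stopifnot(length_range[1] >= 300, isoform_identity >= 0.90,
            isoform_identity <= 0.99)
  set.seed(as.integer(seed %% 2147483647))
  lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  role <- rep("ordinary", n_genes)
  family <- rep(NA_character_, n_genes)
  if (n_isoform_pairs > 0) {
    for (p in seq_len(n_isoform_pairs)) {
      a <- 2 * p - 1; b <- 2 * p
      seqs[b] <- mutate_to_identity(seqs[a], isoform_identity,
                                    child_seed(seed, 100 + p))
      lens[b] <- lens[a]
      role[c(a, b)] <- "isoform_member"
      family[c(a, b)] <- sprintf("fam%02d", p)
    }
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)), seq = seqs,
             length = lens, role = role, family_id = family,
             stringsAsFactors = FALSE)
}

# Cultivar polymorphism model: per gene a fixed panel of segregating sites
# (each with one alternative base) is drawn at `rate_per_kb`; each cultivar
# carries the alternative allele at each site with probability 1/2. Alleles
# of one gene across cultivars therefore differ at only the sites where
# their draws disagree, keeping pairwise identity high at low rates.
draw_polymorphic_sites <- function(seq, rate_per_kb) {
  L <- nchar(seq)
  k <- rbinom(1, L, min(1, rate_per_kb / 1000))
  if (k == 0) {
    return(data.frame(pos = integer(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  pos <- sample.int(L, k)
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
    USE.NAMES = FALSE)
  data.frame(pos = pos, alt = alt, stringsAsFactors = FALSE)
}

apply_allele <- function(seq, sites) {
  if (nrow(sites) == 0) return(seq)
  carry <- runif(nrow(sites)) < 0.5
  if (!any(carry)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  chars[sites$pos[carry]] <- sites$alt[carry]
  paste(chars, collapse = "")
}

# slice a gene into k fragments, each >= min_fragment bases; k == 1 yields a
# single partial transcript
fragment_slices <- function(L, k, min_fragment = 100) {
  if (k == 1) {
    len <- sample(min_fragment:max(min_fragment, L - 50), 1)
    start <- sample.int(L - len + 1, 1)
    return(cbind(start = start, end = start + len - 1))
  }
  # partition the full length into k contiguous pieces of >= min_fragment
  cuts <- sort(sample.int(L - k * min_fragment + k - 1, k - 1))
  starts <- c(1, cuts + min_fragment * seq_len(k - 1) -
                seq_len(k - 1) + 1)
  ends <- c(starts[-1] - 1, L)
  cbind(start = starts, end = ends)
}

#' Generate per-sample assemblies from a truth gene set
#'
#' Emulates multi-cultivar single assemblies: per assembly, each gene is
#' dropped with probability `dropout_prob`; otherwise a cultivar allele is
#' produced (per gene a panel of segregating sites is drawn at
#' `allele_rate` per kb and each cultivar carries the alternative base at
#' each site with probability 1/2) and, with probability
#' `fragmentation_prob`, emitted as 1–3 partial fragments (each at least
#' `min_fragment` bases) instead of the full-length allele — the partial
#' reconstructions that shallowly sequenced samples yield.
#'
#' @param genes gene set from [generate_gene_set()].
#' @param n_assemblies number of single assemblies.
#' @param fragmentation_prob probability a reconstruction is fragmented.
#' @param dropout_prob probability a gene is missing from an assembly.
#' @param allele_rate density of segregating cultivar sites per kb.
#' @param seed integer seed.
#' @param min_fragment minimum fragment length (bases).
#' @return list with `assemblies` (named list of contig tables, tags
#'   `ASM01`, ...), and `contig_map` (data.frame `pooled_id`, `contig_id`,
#'   `source`, `gene_id`, `is_fragment`, `start`, `end`) mapping every
#'   emitted contig to exactly one truth gene.
#' @export
generate_assemblies <- function(genes, n_assemblies = 5,
                                fragmentation_prob = 0.3, dropout_prob = 0.1,
                                allele_rate = 2, seed = 1,
                                min_fragment = 100) {
  stopifnot(fragmentation_prob >= 0, fragmentation_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1, allele_rate >= 0)
  assemblies <- list()
  map <- list()
  set.seed(as.integer(child_seed(seed, 0)))
  sites <- lapply(seq_len(nrow(genes)), function(g)
    draw_polymorphic_sites(genes$seq[g], allele_rate))
  for (a in seq_len(n_assemblies)) {
    set.seed(as.integer(child_seed(seed, a)))
    tag <- sprintf("ASM%02d", a)
    ids <- character(); seqs <- character()
    m_gene <- character(); m_frag <- logical()
    m_start <- integer(); m_end <- integer()
    for (g in seq_len(nrow(genes))) {
      if (runif(1) < dropout_prob) next
      allele <- apply_allele(genes$seq[g], sites[[g]])
      L <- nchar(allele)
      if (runif(1) < fragmentation_prob && L >= 3 * min_fragment) {
        k <- sample(1:3, 1)
        sl <- fragment_slices(L, k, min_fragment)
        for (f in seq_len(nrow(sl))) {
          ids <- c(ids, sprintf("%s_c%d", genes$gene_id[g], f))
          seqs <- c(seqs, substr(allele, sl[f, "start"], sl[f, "end"]))
          m_gene <- c(m_gene, genes$gene_id[g]); m_frag <- c(m_frag, TRUE)
          m_start <- c(m_start, sl[f, "start"]); m_end <- c(m_end, sl[f, "end"])
        }
      } else {
        ids <- c(ids, sprintf("%s_c0", genes$gene_id[g]))
        seqs <- c(seqs, allele)
        m_gene <- c(m_gene, genes$gene_id[g]); m_frag <- c(m_frag, FALSE)
        m_start <- c(m_start, 1L); m_end <- c(m_end, L)
      }
    }
    assemblies[[tag]] <- data.frame(id = ids, seq = seqs,
                                    length = nchar(seqs),
                                    source = rep(tag, length(ids)),
                                    stringsAsFactors = FALSE)
    map[[tag]] <- data.frame(pooled_id = if (length(ids))
                               paste(tag, ids, sep = "|") else character(),
                             contig_id = ids,
                             source = rep(tag, length(ids)),
                             gene_id = m_gene,
                             is_fragment = m_frag, start = m_start,
                             end = m_end, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map)
  rownames(map) <- NULL
  list(assemblies = assemblies, contig_map = map)
}

#' Generate a gene- and contig-level expression matrix
#'
#' True gene-level FPKM are drawn log-normally per gene and sample; the
#' designated reference (housekeeping) gene is held constant at
#' `exp(lognormal_mu)` across samples. Contig-level FPKM are obtained by
#' splitting each gene's value across its contigs proportionally to contig
#' length, so per gene and sample the contig values sum exactly to the gene
#' value.
#'
#' @param genes gene set.
#' @param contig_map contig-to-gene map from [generate_assemblies()].
#' @param n_samples number of samples.
#' @param lognormal_mu,lognormal_sigma log-scale mean and sd of true FPKM.
#' @param reference_gene_id housekeeping gene held constant.
#' @param seed integer seed.
#' @return list with `gene_fpkm` (gene x sample matrix) and `abundance`
#'   (contig-level `abundance_table`, FPKM mode, pooled contig ids).
#' @export
generate_expression <- function(genes, contig_map, n_samples = 6,
                                lognormal_mu = 3, lognormal_sigma = 1,
                                reference_gene_id = NULL, seed = 1) {
  if (!is.null(reference_gene_id) &&
      !reference_gene_id %in% genes$gene_id)
    stop("reference_gene_id not in gene set")
  set.seed(as.integer(child_seed(seed, 7)))
  samples <- sprintf("S%02d", seq_len(n_samples))
  gf <- matrix(rlnorm(nrow(genes) * n_samples, lognormal_mu,
                      lognormal_sigma),
               nrow = nrow(genes), dimnames = list(genes$gene_id, samples))
  if (!is.null(reference_gene_id))
    gf[reference_gene_id, ] <- exp(lognormal_mu)
  clen <- contig_map$end - contig_map$start + 1
  w <- clen / ave(clen, contig_map$gene_id, FUN = sum)
  cf <- gf[contig_map$gene_id, , drop = FALSE] * w
  rownames(cf) <- contig_map$pooled_id
  list(gene_fpkm = gf,
       abundance = abundance_table(cf, lengths = setNames(clen,
                                                          contig_map$pooled_id),
                                   mode = "fpkm"))
}

#' Generate uniform tiling reads with optional duplication
#'
#' Reads tile each gene at a fixed step; `duplication_factor` (scalar or a
#' named per-gene vector) repeats every tile of a gene, emulating
#' over-represented transcripts for the digital-normalization stage. Total
#' read count is the sum over genes of tiles x duplication.
#'
#' @param genes gene set.
#' @param read_length read length (<= shortest gene).
#' @param step tile step (default `read_length %/% 2`).
#' @param duplication_factor integer scalar or named vector by gene_id.
#' @param seed integer seed (fixes nothing here beyond the contract; tiling
#'   is deterministic).
#' @return data.frame `id`, `seq`, `qual`.
#' @export
generate_reads <- function(genes, read_length = 100,
                           step = read_length %/% 2,
                           duplication_factor = 1, seed = 1) {
  if (read_length > min(genes$length))
    stop("read_length exceeds the shortest gene")
  dup <- if (length(duplication_factor) == 1)
    setNames(rep(duplication_factor, nrow(genes)), genes$gene_id) else
      duplication_factor
  ids <- character(); seqs <- character()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    starts <- seq(1, genes$length[g] - read_length + 1, by = step)
    tiles <- substring(genes$seq[g], starts, starts + read_length - 1)
    d <- dup[[gid]]
    seqs <- c(seqs, rep(tiles, each = d))
    ids <- c(ids, sprintf("%s_r%d_d%d", gid,
                          rep(seq_along(tiles), each = d),
                          sequence(rep(d, length(tiles)))))
  }
  data.frame(id = ids, seq = seqs, qual = strrep("I", read_length),
             stringsAsFactors = FALSE)
}
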