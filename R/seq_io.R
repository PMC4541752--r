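#' Read a multi-FASTA file of contigs
#'
#' Sequences are uppercased on input and validated against the DNA alphabet
#' A/C/G/T/N. When `source_tag` is given, every id is prefixed
#' `"<source_tag>|"` so that contigs pooled from several assemblies keep
#' their provenance and occupy a collision-free namespace (the naming scheme
#' used throughout the pipeline, e.g. `"SRR648707|TR19558|c0_g2_i4"`).
#'
#' @param path path to a FASTA file.
#' @param source_tag optional assembly tag (e.g. a run accession) prepended
#'   to every record id.
#' @return a `data.frame` with columns `id`, `seq`, `length`, `source`
#'   (the contig table used by all downstream functions), rows in file order.
#' @export
read_fasta <- function(path, source_tag = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), seq = character(),
                      length = integer(), source = character(),
                      stringsAsFactors = FALSE))
  }
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        lines <- readLines(path)
        bad <- which(!startsWith(lines, ">") &
                       grepl("[^ACGTNacgtn]", lines))[1]
        hdrs <- which(startsWith(lines[seq_len(bad)], ">"))
        hdr <- sub("^>", "", sub("\\s.*$", "",
                                 lines[hdrs[length(hdrs)]]))
        stop("illegal residue at line ", bad, " in record '", hdr, "' of ",
             path, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal residue in record '", ids[which(bad)[1]], "' of ", path,
         call. = FALSE)
  }
  if (any(ids == "")) stop("empty FASTA header in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate id '", ids[anyDuplicated(ids)], "' in ", path,
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("zero-length sequence '", ids[which(nchar(seqs) == 0)[1]], "' in ",
         path, call. = FALSE)
  }
  if (!is.null(source_tag)) ids <- paste(source_tag, ids, sep = "|")
  data.frame(id = ids, seq = unname(seqs), length = nchar(seqs),
             source = if (is.null(source_tag)) contig_source(ids) else
               rep(source_tag, length(ids)),
             stringsAsFactors = FALSE)
}

#' Write a contig table to FASTA
#'
#' @param contigs contig table (`id`, `seq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$id))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Pool several assemblies into one contig table
#'
#' Ids are prefixed with the assembly's source tag so the pooled namespace is
#' collision free.
#'
#' @param assemblies named list of contig tables; names are the source tags.
#' @return single contig table with prefixed ids and a `source` column.
#' @export
pool_assemblies <- function(assemblies) {
  stopifnot(is.list(assemblies), !is.null(names(assemblies)))
  if (anyDuplicated(names(assemblies)))
    stop("duplicate source tags in assembly list")
  pooled <- do.call(rbind, lapply(names(assemblies), function(tag) {
    a <- assemblies[[tag]]
    if (nrow(a) == 0) return(NULL)
    pref <- startsWith(a$id, paste0(tag, "|"))
    id <- ifelse(pref, a$id, paste(tag, a$id, sep = "|"))
    data.frame(id = id, seq = a$seq, length = nchar(a$seq), source = tag,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled)) {
    return(data.frame(id = character(), seq = character(),
                      length = integer(), source = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(pooled$id)) stop("id collision after source-tag prefixing")
  rownames(pooled) <- NULL
  pooled
}

#' Write a cluster set as a CD-HIT-style .clstr file
#'
#' One block per cluster: a `>Cluster k` header, then one line per member,
#' `i<TAB><len>nt, ><id>... at <strand>/<pct>%`, with the representative line
#' ending in `*` instead of the strand/identity suffix. The layout is the
#' widely used cluster-file dialect, so external tooling can read the output;
#' [read_clstr()] inverts it losslessly (identities are stored as percent
#' with two decimals).
#'
#' @param cluster_set a `cluster_set` object from [greedy_cluster()] or
#'   [read_clstr()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(cluster_set, path) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  m <- cluster_set$members
  con <- file(path, "w")
  on.exit(close(con))
  for (k in unique(m$cluster_id)) {
    rows <- m[m$cluster_id == k, , drop = FALSE]
    writeLines(sprintf(">Cluster %d", k), con)
    for (i in seq_len(nrow(rows))) {
      if (rows$is_rep[i]) {
        writeLines(sprintf("%d\t%dnt, >%s... *", i - 1L, rows$length[i],
                           rows$contig_id[i]), con)
      } else {
        writeLines(sprintf("%d\t%dnt, >%s... at %s/%.2f%%", i - 1L,
                           rows$length[i], rows$contig_id[i], rows$strand[i],
                           100 * rows$identity[i]), con)
      }
    }
  }
  invisible(path)
}

#' Read a CD-HIT-style .clstr file
#'
#' @param path path to a `.clstr` file written by [write_clstr()] or by the
#'   common clustering tools using this dialect.
#' @return a `cluster_set` object (member table only; no sequences).
#' @export
read_clstr <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- grepl("^>Cluster ", lines)
  cluster_id <- cumsum(header) - 1L
  mem <- lines[!header]
  memk <- cluster_id[!header]
  if (length(mem) == 0) {
    return(new_cluster_set(data.frame(
      cluster_id = integer(), contig_id = character(), length = integer(),
      identity = numeric(), strand = character(), is_rep = logical(),
      source = character(), stringsAsFactors = FALSE)))
  }
  re <- "^([0-9]+)\t([0-9]+)nt, >(.*)\\.\\.\\. (\\*|at ([+-])/([0-9.]+)%)$"
  ok <- grepl(re, mem)
  if (any(!ok)) {
    stop("unparseable .clstr member line ", which(!ok)[1], ": ",
         mem[which(!ok)[1]])
  }
  is_rep <- grepl("\\*$", mem)
  len <- as.integer(sub(re, "\\2", mem))
  id <- sub(re, "\\3", mem)
  strand <- ifelse(is_rep, "+", sub(re, "\\5", mem))
  ident <- ifelse(is_rep, 1, suppressWarnings(
    as.numeric(sub(re, "\\6", mem)) / 100))
  new_cluster_set(data.frame(
    cluster_id = memk, contig_id = id, length = len, identity = ident,
    strand = strand, is_rep = is_rep, source = contig_source(id),
    stringsAsFactors = FALSE))
}

#' Read a per-contig per-sample abundance table
#'
#' Tab-separated, first column the contig id, one numeric column per sample;
#' an optional `length` column carries per-contig lengths. The table's mode
#' (raw fragment counts vs FPKM) is inferred from the header: any sample
#' column name containing `"count"` (case-insensitive) marks a counts table,
#' otherwise the table is taken as FPKM. Missing cells are set to 0.
#'
#' @param path TSV path.
#' @return an `abundance_table`: list with `values` (contig x sample numeric
#'   matrix), `lengths` (named vector or NULL), `mode` (`"counts"`/`"fpkm"`).
#' @export
read_abundance <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("abundance table needs a contig column and >= 1 sample column")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate contig_id '", ids[anyDuplicated(ids)],
         "' in abundance table")
  }
  rest <- tab[, -1, drop = FALSE]
  len_col <- which(tolower(names(rest)) == "length")
  lengths <- NULL
  if (length(len_col)) {
    lengths <- setNames(as.numeric(rest[[len_col[1]]]), ids)
    rest <- rest[, -len_col, drop = FALSE]
  }
  for (j in seq_along(rest)) {
    v <- rest[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v) & nzchar(v)))
        stop("non-numeric cell in column '", names(rest)[j], "'")
      v <- num
    }
    v[is.na(v)] <- 0
    rest[[j]] <- v
  }
  values <- as.matrix(rest)
  rownames(values) <- ids
  mode <- if (any(grepl("count", names(rest), ignore.case = TRUE)))
    "counts" else "fpkm"
  abundance_table(values, lengths = lengths, mode = mode)
}

#' Construct an abundance table
#'
#' @param values contig x sample numeric matrix with dimnames.
#' @param lengths optional named per-contig lengths (bases).
#' @param mode `"counts"` or `"fpkm"`.
#' @return an `abundance_table` object.
#' @export
abundance_table <- function(values, lengths = NULL, mode = c("fpkm", "counts")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative abundance cell")
  structure(list(values = values, lengths = lengths, mode = mode),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "contigs x", ncol(x$values),
      "samples, mode =", x$mode, "\n")
  invisible(x)
}

#' Write an abundance table to TSV
#'
#' @param abundance an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(contig_id = rownames(abundance$values),
                   abundance$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(abundance$lengths)) {
    df <- cbind(df[1], length = abundance$lengths[df$contig_id], df[-1])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' The standard tabular alignment layout: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore.
#'
#' @param path TSV path (no header).
#' @return data.frame with those twelve named columns.
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bitscore")
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12) stop("expected 12 tab-separated columns, got ", ncol(tab))
  names(tab) <- cols
  tab
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `seq` and optional `qual` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (is.null(reads$qual)) strrep("I", nchar(reads$seq)) else reads$qual
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = toupper(lines[idx + 1]), qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}
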