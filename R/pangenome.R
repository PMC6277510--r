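#' Homology thresholds
#'
#' ProteinOrtho-style acceptance thresholds for pairwise protein hits:
#' e-value at most `evalue`, percent amino-acid identity at least
#' `identity`, and query coverage at least `coverage`.
#'
#' @param evalue maximum e-value (default `1e-3`).
#' @param identity minimum percent identity (default 20).
#' @param coverage minimum aligned fraction of the query (default 0.30).
#' @return A named list.
#' @export
homology_thresholds <- function(evalue = 1e-3, identity = 20,
                                coverage = 0.30) {
  list(evalue = evalue, identity = identity, coverage = coverage)
}

# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# the standard protein-search statistics.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' All-versus-all protein homology
#'
#' Aligns every pair of genes from different (and the same) genomes with
#' local (Smith-Waterman) alignment under BLOSUM62 (gap open 11, extend 1),
#' assigns e-values by Karlin-Altschul statistics, and emits only hits
#' passing all thresholds. Each passing pair yields two rows, one per
#' direction, with the coverage of the respective query.
#'
#' @param genes tibble of gene records: columns `genome`, `gene`
#'   (ids unique within genome), `seq` (amino-acid sequence).
#' @param thresholds a [homology_thresholds()] list.
#' @param cross_genome_only if `TRUE` (default), skip within-genome pairs;
#'   set `FALSE` to also detect paralogs.
#' @return Tibble of hits: `query`, `subject`, `identity`, `coverage_q`,
#'   `coverage_s`, `score`, `evalue`, `taxonomy` (`NA`; internal alignments
#'   carry no taxonomy).
#' @export
all_vs_all_homology <- function(genes, thresholds = homology_thresholds(),
                                cross_genome_only = TRUE) {
  check_gene_table(genes)
  n <- nrow(genes)
  if (length(unique(genes$genome)) < 2) abort("need at least 2 genomes")
  seqs <- Biostrings::AAStringSet(setNames(genes$seq, genes$gene))
  lens <- Biostrings::width(seqs)
  mat <- "BLOSUM62"
  rows <- list()
  for (j in seq_len(n)) {
    is <- seq_len(j - 1L)
    if (cross_genome_only) is <- is[genes$genome[is] != genes$genome[j]]
    if (!length(is)) next
    aln <- Biostrings::pairwiseAlignment(
      seqs[is], seqs[[j]], type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    score <- Biostrings::score(aln)
    pid <- Biostrings::pid(aln)
    wq <- Biostrings::width(Biostrings::pattern(aln))
    ws <- Biostrings::width(Biostrings::subject(aln))
    ev <- KA_K * lens[is] * lens[j] * exp(-KA_LAMBDA * score)
    covq <- wq / lens[is]
    covs <- ws / lens[j]
    ok <- ev <= thresholds$evalue & pid >= thresholds$identity &
      covq >= thresholds$coverage & covs >= thresholds$coverage
    if (any(ok)) {
      qs <- genes$gene[is[ok]]
      rows[[length(rows) + 1L]] <- tibble(
        query = c(qs, rep(genes$gene[j], sum(ok))),
        subject = c(rep(genes$gene[j], sum(ok)), qs),
        identity = rep(pid[ok], 2),
        coverage_q = c(covq[ok], covs[ok]),
        coverage_s = c(covs[ok], covq[ok]),
        score = rep(score[ok], 2),
        evalue = rep(ev[ok], 2),
        taxonomy = NA_character_)
    }
  }
  if (!length(rows)) {
    return(tibble(query = character(), subject = character(),
                  identity = numeric(), coverage_q = numeric(),
                  coverage_s = numeric(), score = numeric(),
                  evalue = numeric(), taxonomy = character()))
  }
  bind_rows(rows)
}

check_gene_table <- function(genes) {
  need <- c("genome", "gene", "seq")
  if (!all(need %in% names(genes))) {
    abort("`genes` needs columns genome, gene, seq")
  }
  if (any(!nzchar(genes$seq))) abort("empty sequence in gene table")
  dup <- genes |> count(.data$genome, .data$gene) |> filter(n > 1)
  if (nrow(dup)) abort("gene ids must be unique within a genome")
  empty <- setdiff(unique(genes$genome),
                   unique(genes$genome[nzchar(genes$seq)]))
  if (length(empty)) abort(paste0("empty genome: ", empty[1]))
  invisible(genes)
}

#' Read / filter BLAST tabular hits
#'
#' `read_hits()` parses BLAST `outfmt 6` TSV (12 standard columns, plus an
#' optional 13th column holding the subject taxonomy path). `filter_hits()`
#' applies [homology_thresholds()]; query coverage can only be checked when
#' query lengths are supplied.
#'
#' @param path tabular hit file; `#` comment lines are skipped.
#' @param query_lengths optional named vector of query sequence lengths,
#'   used to derive query coverage from the aligned span.
#' @return Tibble of hits in the same shape as [all_vs_all_homology()], plus
#'   `bitscore`.
#' @export
read_hits <- function(path, query_lengths = NULL) {
  cols <- c("query", "subject", "identity", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "taxonomy")
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 12)) abort("expected at least 12 tab-separated columns")
  get <- function(i) vapply(parts, function(p) p[i] %||% NA_character_,
                            character(1))
  out <- tibble(
    query = get(1), subject = get(2),
    identity = as.numeric(get(3)),
    qstart = as.integer(get(7)), qend = as.integer(get(8)),
    sstart = as.integer(get(9)), send = as.integer(get(10)),
    evalue = as.numeric(get(11)), bitscore = as.numeric(get(12)),
    taxonomy = if (any(nc >= 13)) get(13) else NA_character_)
  out$score <- out$bitscore
  out$coverage_q <- if (!is.null(query_lengths)) {
    (abs(out$qend - out$qstart) + 1) / unname(query_lengths[out$query])
  } else NA_real_
  out$coverage_s <- NA_real_
  out
}

#' @rdname read_hits
#' @param hits a hit tibble.
#' @param thresholds a [homology_thresholds()] list.
#' @export
filter_hits <- function(hits, thresholds = homology_thresholds()) {
  keep <- hits$evalue <= thresholds$evalue &
    hits$identity >= thresholds$identity
  if (!all(is.na(hits$coverage_q))) {
    keep <- keep & hits$coverage_q >= thresholds$coverage
  }
  hits[keep, , drop = FALSE]
}

#' Build gene families from reciprocal hits
#'
#' Families are the connected components of the graph whose vertices are all
#' genes and whose edges join pairs with *reciprocal* passing hits (a hit in
#' each direction). Genes with no edges become singleton (unique) families.
#'
#' @param hits passing hits (e.g. from [all_vs_all_homology()]).
#' @param genes gene table as in [all_vs_all_homology()]; defines the vertex
#'   set, including hit-less genes.
#' @return Tibble: `family`, `gene`, `genome`, `span` (number of genomes the
#'   family touches).
#' @export
build_families <- function(hits, genes) {
  check_gene_table(genes)
  unknown <- setdiff(unique(c(hits$query, hits$subject)), genes$gene)
  if (length(unknown)) {
    abort(paste0("hit references unknown gene(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  dirs <- unique(paste(hits$query, hits$subject, sep = "\r"))
  revs <- vapply(strsplit(dirs, "\r", fixed = TRUE),
                 function(p) paste(p[2], p[1], sep = "\r"), character(1))
  recip <- dirs[dirs %in% revs]       # both directions present
  ab0 <- do.call(rbind, strsplit(recip, "\r", fixed = TRUE))
  edges <- if (is.null(ab0)) character(0) else {
    unique(paste(pmin(ab0[, 1], ab0[, 2]), pmax(ab0[, 1], ab0[, 2]),
                 sep = "\r"))
  }
  edges <- edges[!vapply(strsplit(edges, "\r", fixed = TRUE),
                         function(p) p[1] == p[2], logical(1))]  # no self-loops
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(genes), name = genes$gene)
  if (length(edges)) {
    ab <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, t(cbind(match(ab[, 1], genes$gene),
                                      match(ab[, 2], genes$gene))))
  }
  comp <- igraph::components(g)$membership
  fam_id <- sprintf("F%04d", match(comp, unique(comp)))
  out <- tibble(family = fam_id, gene = genes$gene, genome = genes$genome)
  span <- out |> group_by(.data$family) |>
    summarise(span = dplyr::n_distinct(.data$genome), .groups = "drop")
  left_join(out, span, by = "family")
}

#' Partition a multi-genome gene set into core / shared / unique
#'
#' Classifies each genome's genes by the genome span of their family:
#' *core* genes belong to families present in all genomes; `n_span3` counts
#' genes in families spanning exactly three genomes (homologs in two of the
#' three other microbes); `n_shared_any` counts genes in families spanning
#' at least two genomes; *unique* genes sit in single-genome families.
#' Percentages are of the genome's gene total, reported to one decimal
#' (half away from zero).
#'
#' @param families tibble from [build_families()].
#' @return Object of class `truc_pangenome`: `per_genome` tibble (`genome`,
#'   `total`, `n_core`, `n_span3`, `n_shared_any`, `n_unique`, `pct_core`,
#'   `pct_span3`, `pct_shared_any`), and `global` list
#'   (`pangenome_families`, `core_families`, `n_genomes`).
#' @export
partition_pangenome <- function(families) {
  n_genomes <- length(unique(families$genome))
  per_genome <- families |>
    group_by(.data$genome) |>
    summarise(total = dplyr::n(),
              n_core = sum(.data$span == n_genomes),
              n_span3 = sum(.data$span == 3),
              n_shared_any = sum(.data$span >= 2),
              n_unique = sum(.data$span == 1),
              .groups = "drop") |>
    partition_percentages()
  fam <- families |> distinct(.data$family, .data$span)
  structure(list(
    per_genome = per_genome,
    global = list(pangenome_families = nrow(fam),
                  core_families = sum(fam$span == n_genomes),
                  n_genomes = n_genomes)),
    class = "truc_pangenome")
}

#' Percentage report from partition counts
#'
#' The reporting step of the pangenome partition, usable directly on printed
#' count tables: adds `pct_core`, `pct_span3` and `pct_shared_any`, each
#' `100 * count / total` rounded to one decimal, half away from zero.
#'
#' @param counts tibble with columns `genome`, `total`, `n_core`, `n_span3`,
#'   `n_shared_any` (extra columns pass through).
#' @return The tibble with percentage columns appended.
#' @export
partition_percentages <- function(counts) {
  counts |>
    mutate(pct_core = pct1(.data$n_core, .data$total),
           pct_span3 = pct1(.data$n_span3, .data$total),
           pct_shared_any = pct1(.data$n_shared_any, .data$total))
}

#' @export
print.truc_pangenome <- function(x, ...) {
  cat(sprintf("<truc_pangenome> %d genomes, %d families (%d core)\n",
              x$global$n_genomes, x$global$pangenome_families,
              x$global$core_families))
  print(x$per_genome, ...)
  invisible(x)
}

#' Write a pangenome partition report
#'
#' @param partition a [partition_pangenome()] result.
#' @param path output path (`.tsv` or `.json` by `format`).
#' @param format `"tsv"` or `"json"`.
#' @param seed optional seed recorded in the provenance header (TSV only).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, format = c("tsv", "json"),
                            seed = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(per_genome = partition$per_genome,
                              global = partition$global),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    pg <- partition$per_genome
    lines <- c(paste(names(pg), collapse = "\t"),
               do.call(paste, c(lapply(pg, format_tsv_col), sep = "\t")),
               sprintf("# pangenome_families\t%d",
                       partition$global$pangenome_families),
               sprintf("# core_families\t%d", partition$global$core_families))
    write_lines_with_header(lines, path, seed = seed, extra = "pangenome")
  }
  invisible(path)
}

#' Write / read gene records as FASTA
#'
#' One FASTA file per call; headers are `gene genome=<id>` so genome
#' membership round-trips.
#'
#' @param genes gene table (`genome`, `gene`, `seq`).
#' @param path output path.
#' @return `path` invisibly; `read_fasta_genes()` returns a gene tibble.
#' @export
write_fasta_genes <- function(genes, path) {
  check_gene_table(genes)
  seqs <- Biostrings::AAStringSet(setNames(genes$seq, paste0(
    genes$gene, " genome=", genes$genome)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta_genes
#' @param genome genome id assigned to all records when headers carry no
#'   `genome=` tag.
#' @export
read_fasta_genes <- function(path, genome = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  gene <- sub("\\s.*$", "", hdr)
  gm <- ifelse(grepl("genome=", hdr),
               sub(".*genome=(\\S+).*", "\\1", hdr),
               genome %||% NA_character_)
  if (anyNA(gm)) abort("no genome= tag in headers and no `genome` given")
  tibble(genome = gm, gene = gene, seq = as.character(seqs))
}
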