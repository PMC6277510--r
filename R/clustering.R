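#' Pearson distance between phyletic profiles
#'
#' `d(i, j) = 1 - r(profile_i, profile_j)` with `r` the Pearson correlation
#' of the two taxa's 0/1 feature profiles (profiles are centred by the
#' correlation itself, the literal reading of "Pearson distance" on binary
#' data). Distances lie in `[0, 2]`: identical profiles give 0,
#' complementary profiles give 2.
#'
#' @inheritParams pa_taxa
#' @return A symmetric, zero-diagonal distance matrix with taxon dimnames.
#' @export
pearson_distance <- function(pa) {
  cells <- as_pa_cells(pa)
  sds <- apply(cells, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant profile (correlation undefined) for taxa: ",
                 paste(rownames(cells)[sds == 0], collapse = ", ")))
  }
  d <- 1 - cor(t(cells))
  d[d < 0] <- 0            # clip -1e-16 style numerical noise
  diag(d) <- 0
  d
}

#' Hierarchical clustering of phyletic profiles
#'
#' Agglomerative clustering (via [stats::hclust()]) of a distance matrix,
#' with average (UPGMA, default), complete or single linkage. Agglomeration
#' is deterministic; ties are resolved by `hclust`'s fixed lowest-index
#' rule. Heights are non-decreasing along merges for these monotone
#' linkages.
#'
#' @param d a distance matrix or `dist`, e.g. from [pearson_distance()].
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` object (leaves = taxa), also writable as Newick via
#'   [write_dendrogram_newick()].
#' @export
phyletic_cluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm)) abort("`d` must be a square distance matrix")
  hclust(as.dist(dm), method = linkage)
}

#' Group purity at the four-cluster cut
#'
#' Cuts a dendrogram into 4 clusters and reports, per cluster, the majority
#' group and its share, plus overall purity (fraction of taxa whose group is
#' their cluster's majority group). A perfectly recovered four-branch
#' topology has purity 1.
#'
#' @param dendrogram an `hclust` from [phyletic_cluster()].
#' @param groups named character vector of group labels per taxon.
#' @param k number of clusters to cut (default 4, the four-branch check).
#' @return A list of class `truc_fourbranch`: `clusters` (tibble `taxon`,
#'   `group`, `cluster`), `summary` (tibble `cluster`, `n`,
#'   `majority_group`, `majority_n`) and `purity`.
#' @export
four_branch_check <- function(dendrogram, groups, k = 4) {
  cl <- cutree(dendrogram, k = k)
  clusters <- tibble(taxon = names(cl),
                     group = unname(groups[names(cl)]),
                     cluster = unname(cl))
  summary <- clusters |>
    group_by(.data$cluster) |>
    summarise(n = dplyr::n(),
              majority_group = names(which.max(table(.data$group))),
              majority_n = max(table(.data$group)),
              .groups = "drop")
  purity <- sum(summary$majority_n) / nrow(clusters)
  structure(list(clusters = clusters, summary = summary, purity = purity),
            class = "truc_fourbranch")
}

#' @export
print.truc_fourbranch <- function(x, ...) {
  cat(sprintf("<truc_fourbranch> %d clusters, purity %.3f\n",
              nrow(x$summary), x$purity))
  print(x$summary, ...)
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' @param dendrogram an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param d distance matrix or `dist`.
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path, seed = NULL) {
  dm <- as.matrix(d)
  lines <- c(paste(c("taxon", colnames(dm)), collapse = "\t"),
             vapply(seq_len(nrow(dm)), function(i) {
               paste(c(rownames(dm)[i], sprintf("%.8g", dm[i, ])),
                     collapse = "\t")
             }, character(1)))
  write_lines_with_header(lines, path, seed = seed, extra = "distance_matrix")
}
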