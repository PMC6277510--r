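#' Bootstrap support for the splits of a reference tree
#'
#' Resamples characters with replacement, repeats the parsimony search on
#' each pseudo-replicate, and reports for every non-trivial split of the
#' reference tree the percentage of replicate trees that contain it.
#' Supports are attached to the reference tree (not a consensus).
#'
#' @inheritParams tree_length
#' @param tree reference unrooted tree whose splits are scored (typically the
#'   best tree from [mp_search()]).
#' @param reps number of bootstrap replicates.
#' @param seed integer seed; fixed seed gives reproducible supports.
#' @param rearrangement rearrangement used in per-replicate searches;
#'   defaults to `"NNI"`, which keeps replicate searches fast.
#' @param n_starts random-addition starts per replicate.
#' @return An object of class `truc_boot`: list with `splits` (tibble:
#'   `split` key, `tips` list-column of taxon names, `support` in
#'   `[0, 100]`), `tree` (the reference `phylo` with node labels set to
#'   support values), and `reps`.
#' @export
bootstrap_support <- function(pa, tree, reps = 1000, seed = 1,
                              rearrangement = c("NNI", "SPR"), n_starts = 1) {
  rearrangement <- match.arg(rearrangement)
  if (reps < 1) abort("`reps` must be at least 1")
  cells <- as_pa_cells(pa)
  cells <- cells[tree$tip.label, , drop = FALSE]
  taxa <- rownames(cells)
  n <- nrow(cells)
  ref_tr <- tr_from_phylo(tree, taxa)
  ref_splits <- tr_splits(ref_tr)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  neighbors <- switch(rearrangement, NNI = tr_nni_neighbors,
                      SPR = tr_spr_neighbors)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(ncol(cells), replace = TRUE)
      cw <- compress_columns(cells[, idx, drop = FALSE])
      best_tr <- NULL; best_len <- Inf
      for (s in seq_len(n_starts)) {
        tr <- stepwise_addition(sample.int(n), cw$codes, cw$weights, n)
        res <- hill_climb(tr, cw$codes, cw$weights, rearrangement)
        if (res$length < best_len) {
          best_len <- res$length
          best_tr <- res$trees[[1]]
        }
      }
      sp <- tr_splits(best_tr)
      hit <- ref_splits %in% sp
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / reps
  splits <- tibble(
    split = ref_splits,
    tips = lapply(strsplit(ref_splits, ",", fixed = TRUE),
                  function(i) taxa[as.integer(i)]),
    support = unname(support)
  )
  out_tree <- tree
  out_tree$node.label <- node_support_labels(tree, taxa, support)
  structure(list(splits = splits, tree = out_tree, reps = reps),
            class = "truc_boot")
}

#' @export
print.truc_boot <- function(x, ...) {
  cat(sprintf("<truc_boot> %d replicates, %d non-trivial splits\n",
              x$reps, nrow(x$splits)))
  print(x$splits, ...)
  invisible(x)
}

# Per-internal-node support labels for a phylo, from a named split->support
# vector keyed like tr_splits() output (global tip ids relative to `taxa`).
node_support_labels <- function(phy, taxa, support) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  gid <- match(phy$tip.label, taxa)
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- gid[i]
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  all_ids <- sort(unlist(below[[ntip + 1L]]))
  labs <- character(phy$Nnode)
  for (v in seq_len(phy$Nnode)) {
    tips <- sort(below[[ntip + v]])
    key1 <- paste(tips, collapse = ",")
    key2 <- paste(setdiff(all_ids, tips), collapse = ",")
    s <- support[key1]
    if (is.na(s)) s <- support[key2]
    labs[v] <- if (is.na(s)) "" else sprintf("%g", s)
  }
  # labels are stored in the original node order; reorder back
  labs
}

#' Bootstrap support for the monophyly of the four taxon groups
#'
#' Convenience extraction: percentage of bootstrap trees in which each group
#' (archaea, bacteria, eukaryota, megavirales) forms a clade of the
#' reference tree's splits.
#'
#' @param boot a [bootstrap_support()] result.
#' @param groups named character vector of group labels per taxon (e.g.
#'   [pa_groups()]).
#' @return Tibble with `group`, `in_reference` (is the group a split of the
#'   reference tree) and `support`.
#' @export
group_support <- function(boot, groups) {
  taxa <- boot$tree$tip.label
  purrr::map_dfr(TRUC_GROUPS, function(g) {
    members <- sort(taxa[groups[taxa] == g])
    row <- boot$splits[vapply(boot$splits$tips,
                              function(t) setequal(t, members) ||
                                setequal(t, setdiff(taxa, members)),
                              logical(1)), ]
    tibble(group = g,
           in_reference = nrow(row) > 0,
           support = if (nrow(row)) row$support[1] else 0)
  })
}
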