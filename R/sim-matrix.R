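#' Simulate a four-group presence/absence matrix on a known tree
#'
#' Evolves binary characters on a balanced truth tree with the four groups
#' (archaea, bacteria, eukaryota, megavirales) as clades joined by a
#' ((A,B),(E,V)) backbone. Each character originates as a gain at a known
#' internal node (drawn uniformly, or the root when `origin = "root"`), is
#' inherited down the tree, and is perturbed by per-branch flip noise:
#' absent states gain with `gain_rate`, present states are lost with
#' `loss_rate`. The character's age `nd` is the depth of its gain node
#' scaled to `[0, 1]` (0 = root, most ancient) plus Gaussian jitter of sd
#' `age_noise`, clipped to `[0, 1]`; with zero noise, ages are strictly
#' monotone in gain-node depth.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `truc_sim_matrix`: `pa` (a [pa_matrix()] with
#'   ages), `tree` (rooted truth `phylo`), `truth` (tibble: `feature`,
#'   `origin` node label, `origin_depth`, `nd_true`, `nd`).
#' @export
sim_presence_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "truc_sim_config"))
  tree <- ape::read.tree(text = truth_tree_newick(cfg$n_taxa_per_group))
  tree$node.label <- sprintf("n%02d", seq_len(tree$Nnode))
  labs <- group_taxa_labels(cfg$n_taxa_per_group)
  groups <- setNames(rep(TRUC_GROUPS, each = cfg$n_taxa_per_group),
                     unlist(labs))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  phy <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  depth <- integer(nnode)
  root <- ntip + 1L
  for (e in seq_len(nrow(phy$edge))) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + 1L
  }
  internal_nodes <- root:nnode
  nchar <- cfg$n_characters
  with_seed(cfg$seed, {
    origin <- if (cfg$origin == "root") {
      rep(root, nchar)
    } else {
      sample(internal_nodes, nchar, replace = TRUE)
    }
    states <- matrix(0L, nchar, nnode)
    states[origin == root, root] <- 1L
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      s <- states[, p]
      flip_up <- s == 0L & runif(nchar) < cfg$gain_rate
      flip_dn <- s == 1L & runif(nchar) < cfg$loss_rate
      s[flip_up] <- 1L
      s[flip_dn] <- 0L
      s[origin == ch] <- 1L       # the planted gain event
      states[, ch] <- s
    }
    max_depth <- max(depth[internal_nodes])
    nd_true <- if (max_depth > 0) depth[origin] / max_depth else
      rep(0, nchar)
    nd <- pmin(1, pmax(0, nd_true + rnorm(nchar, 0, cfg$age_noise)))
  })
  features <- sprintf("FSF%04d", seq_len(nchar))
  cells <- t(states[, seq_len(ntip), drop = FALSE])
  rownames(cells) <- phy$tip.label
  colnames(cells) <- features
  ages <- setNames(nd, features)
  pa <- pa_matrix(cells[unlist(labs), , drop = FALSE], groups, ages)
  origin_label <- c(phy$tip.label, phy$node.label)[origin]
  origin_depth <- depth[origin]
  truth <- tibble(feature = features, origin = origin_label,
                  origin_depth = origin_depth,
                  nd_true = nd_true, nd = nd)
  structure(list(pa = pa, tree = tree, truth = truth),
            class = "truc_sim_matrix")
}

#' @export
print.truc_sim_matrix <- function(x, ...) {
  cat("<truc_sim_matrix>\n")
  print(x$pa)
  invisible(x)
}

#' Do the four groups form clades of a tree?
#'
#' Checks, per group, whether the group's taxa form a split of the given
#' (unrooted) tree — the planted-truth recovery check for simulated
#' matrices.
#'
#' @param tree a `phylo`.
#' @param groups named group labels per taxon.
#' @return Tibble with `group` and `monophyletic`.
#' @export
groups_monophyletic <- function(tree, groups) {
  taxa <- tree$tip.label
  tr <- tr_from_phylo(tree, taxa)
  splits <- tr_splits(tr)
  all_ids <- seq_along(taxa)
  purrr::map_dfr(TRUC_GROUPS, function(g) {
    ids <- sort(which(groups[taxa] == g))
    comp <- setdiff(all_ids, ids)
    tibble(group = g,
           monophyletic = length(ids) > 0 &&
             (length(comp) <= 1 || length(ids) <= 1 ||
                split_key(ids) %in% splits || split_key(comp) %in% splits))
  })
}
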