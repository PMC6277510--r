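#' Lundberg a-posteriori rooting
#'
#' Roots an unrooted parsimony tree by attaching a hypothetical all-character
#' ancestor to every branch in turn and keeping the placement that increases
#' total tree length the least. With the default all-absent ancestor, domain
#' absence is treated as the ancestral condition, which reproduces a
#' generality-criterion style polarity.
#'
#' Ties between branches are broken deterministically by branch enumeration
#' order (the engine's edge order, stable for a given tree) and flagged via
#' the `tie` attribute of the result.
#'
#' @inheritParams tree_length
#' @param ancestor `"zeros"` (default), `"ones"`, or a full binary vector of
#'   ancestral states, one per character (named by feature or in matrix
#'   column order).
#' @return A rooted `phylo` tree (degree-2 root on the chosen branch) with
#'   attributes `root_lengths` (tibble: one row per candidate branch with the
#'   resulting total length), `tie` (logical) and `parsimony_length` (length
#'   of the rooted tree including the hypothetical ancestor).
#' @export
lundberg_root <- function(tree, pa, ancestor = "zeros") {
  cells <- as_pa_cells(pa)
  cells <- cells[tree$tip.label, , drop = FALSE]
  n_char <- ncol(cells)
  anc <- if (identical(ancestor, "zeros")) {
    rep(0L, n_char)
  } else if (identical(ancestor, "ones")) {
    rep(1L, n_char)
  } else {
    if (!is.null(names(ancestor))) ancestor <- ancestor[colnames(cells)]
    if (length(ancestor) != n_char || anyNA(ancestor) ||
        !all(ancestor %in% c(0, 1))) {
      abort(sprintf("`ancestor` must be a binary vector of length %d", n_char))
    }
    as.integer(ancestor)
  }
  taxa <- rownames(cells)
  n <- length(taxa)
  tr <- tr_from_phylo(tree, taxa)
  # shift ids so the hypothetical ancestor can live at tip id n + 1
  anc_id <- n + 1L
  tr2 <- tr
  tr2$edge[tr2$edge > n] <- tr2$edge[tr2$edge > n] + 1L
  tr2$ntip_global <- n + 1L
  tr2$next_id <- max(tr2$edge) + 1L
  codes <- rbind(cbind(codes_from_cells(cells), anc + 1L))
  w <- rep(1L, n_char)
  lens <- vapply(seq_len(nrow(tr2$edge)), function(i) {
    tr_fitch(tr_attach(tr2, i, anc_id), codes, w)
  }, numeric(1))
  best <- which(lens == min(lens))
  rooted <- root_on_edge(tr, best[1], taxa)
  attr(rooted, "root_lengths") <- tibble(branch = seq_along(lens),
                                         length = as.integer(lens))
  attr(rooted, "tie") <- length(best) > 1
  attr(rooted, "parsimony_length") <- as.integer(min(lens))
  rooted
}

# Insert a degree-2 root in the middle of edge row `i` and return a rooted
# phylo. The set of splits is exactly that of the unrooted input.
root_on_edge <- function(tr, i, taxa) {
  u <- tr$edge[i, 1]; v <- tr$edge[i, 2]
  r <- tr$next_id
  edge <- rbind(tr$edge[-i, , drop = FALSE], c(r, u), c(r, v))
  ori <- tr_orient(edge, r)
  bfs <- ori$bfs; parent <- ori$parent
  tips <- sort(tr$tips)
  ntip <- length(tips)
  internals <- bfs[bfs > tr$ntip_global]
  new_id <- integer(max(edge))
  new_id[tips] <- seq_len(ntip)
  new_id[internals] <- ntip + seq_along(internals)   # root r first (bfs[1])
  children <- bfs[-1]
  phy <- structure(list(
    edge = cbind(new_id[parent[children]], new_id[children]),
    tip.label = taxa[tips],
    Nnode = length(internals)
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}
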