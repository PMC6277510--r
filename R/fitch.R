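# Character-state encoding: Fitch state sets as bitmasks, 1 = {0}, 2 = {1}.
codes_from_cells <- function(cells) {
  codes <- t(cells) + 1L
  storage.mode(codes) <- "integer"
  codes
}

as_pa_cells <- function(pa) {
  if (inherits(pa, "truc_pa")) pa$cells else as.matrix(pa)
}

check_states <- function(states, taxa) {
  if (!is.null(names(states))) {
    miss <- setdiff(taxa, names(states))
    if (length(miss)) {
      abort(paste0("state missing for taxa: ", paste(miss, collapse = ", ")))
    }
    states <- states[taxa]
  } else if (length(states) != length(taxa)) {
    abort("`states` must be named by taxon or match the number of tips")
  }
  if (anyNA(states) || !all(states %in% c(0, 1))) {
    abort("states must be binary (0/1) with no missing values")
  }
  as.integer(states)
}

#' Fitch parsimony steps for one binary character
#'
#' Counts the minimum number of state changes a binary character requires on
#' a fixed unrooted topology, by a single Fitch post-order pass. The count
#' is independent of where the pass is rooted.
#'
#' @param tree an unrooted `phylo` tree (a rooted tree is unrooted first).
#' @param states binary vector of tip states, named by taxon or ordered as
#'   `tree$tip.label`.
#' @return Integer number of steps.
#' @seealso [sankoff_steps()] for the independent dynamic-programming
#'   reference, [tree_length()] for whole-matrix sums.
#' @export
fitch_steps <- function(tree, states) {
  taxa <- tree$tip.label
  states <- check_states(states, taxa)
  tr <- tr_from_phylo(tree, taxa)
  codes <- matrix(states + 1L, nrow = 1)
  as.integer(tr_fitch(tr, codes, weights = 1))
}

#' Parsimony length of a tree on a character matrix
#'
#' @inheritParams fitch_steps
#' @param pa a [pa_matrix()] (or plain binary matrix with taxon rownames);
#'   taxa must match the tree's tips.
#' @return Integer: sum of Fitch steps over all characters.
#' @export
tree_length <- function(tree, pa) {
  cells <- as_pa_cells(pa)
  cells <- cells[tree$tip.label, , drop = FALSE]
  if (ncol(cells) == 0) return(0L)
  tr <- tr_from_phylo(tree, rownames(cells))
  as.integer(tr_fitch(tr, codes_from_cells(cells),
                      weights = rep(1L, ncol(cells))))
}

#' Unit-cost Sankoff steps (dynamic-programming reference)
#'
#' Independent implementation of minimum changes for a binary character via
#' the Sankoff dynamic program with unit substitution costs, working
#' directly on the `phylo` edge table. Used as the reference against which
#' the Fitch engine is validated; the two must agree on every instance.
#'
#' @inheritParams fitch_steps
#' @return Integer number of steps.
#' @export
sankoff_steps <- function(tree, states) {
  taxa <- tree$tip.label
  states <- check_states(states, taxa)
  phy <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(taxa)
  nnode <- ntip + phy$Nnode
  cost <- matrix(Inf, nnode, 2)
  tip_state <- states[match(phy$tip.label, taxa)]
  cost[cbind(seq_len(ntip), tip_state + 1L)] <- 0
  cost[unique(phy$edge[, 1]), ] <- 0
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    # min over child states of child cost + unit substitution cost
    add0 <- min(cost[ch, 1], cost[ch, 2] + 1)
    add1 <- min(cost[ch, 2], cost[ch, 1] + 1)
    cost[p, 1] <- cost[p, 1] + add0
    cost[p, 2] <- cost[p, 2] + add1
  }
  root <- phy$edge[nrow(phy$edge), 1]
  as.integer(min(cost[root, ]))
}

#' Exhaustive maximum-parsimony search (enumeration oracle)
#'
#' Scores every unrooted binary topology over the matrix taxa (3, 15, 105,
#' 945, 10395 trees for 4..8 taxa) and returns the optimum. Exact but
#' factorial; refuse more than 8 taxa and use [mp_search()] instead.
#'
#' @inheritParams tree_length
#' @return A list with `length` (best parsimony length), `trees` (all
#'   optimal topologies as `phylo` objects) and `n_topologies` scored.
#' @export
exhaustive_mp <- function(pa) {
  cells <- as_pa_cells(pa)
  n <- nrow(cells)
  if (n < 4) abort("need at least 4 taxa")
  if (n > 8) abort("more than 8 taxa: enumeration is factorial, use mp_search()")
  codes <- codes_from_cells(cells)
  w <- rep(1L, ncol(cells))
  trees <- tr_all_topologies(seq_len(n), n)
  lens <- vapply(trees, tr_fitch, numeric(1), codes = codes, weights = w)
  best <- min(lens)
  list(length = as.integer(best),
       trees = lapply(trees[lens == best], tr_to_phylo, taxa = rownames(cells)),
       n_topologies = length(trees))
}
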