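# Internal tree engine -------------------------------------------------------
#
# Unrooted binary trees are held as plain undirected edge lists so that the
# parsimony search can attach, prune and regraft without paying `phylo`
# bookkeeping costs. Node ids: tips use the taxon's row index in the
# presence/absence matrix (1..ntip_global); internal nodes use ids above
# ntip_global, gaps allowed. Conversion to/from `ape::phylo` happens only at
# the API boundary.

tr_new <- function(tips3, ntip_global) {
  w <- ntip_global + 1L
  list(edge = cbind(c(w, w, w), as.integer(tips3)),
       tips = as.integer(tips3),
       ntip_global = as.integer(ntip_global),
       next_id = ntip_global + 2L)
}

# Attach tip `tip` in the middle of edge row `i`.
tr_attach <- function(tr, i, tip) {
  u <- tr$edge[i, 1]; v <- tr$edge[i, 2]
  w <- tr$next_id
  tr$edge <- rbind(tr$edge[-i, , drop = FALSE],
                   cbind(c(u, w, w), c(w, v, as.integer(tip))))
  tr$tips <- c(tr$tips, as.integer(tip))
  tr$next_id <- w + 1L
  tr
}

# Orientation away from `root`: breadth-first order plus parent pointers.
tr_orient <- function(edge, root) {
  e1 <- edge[, 1]; e2 <- edge[, 2]
  maxid <- max(edge)
  parent <- integer(maxid)
  visited <- logical(maxid)
  bfs <- integer(nrow(edge) + 1L)
  bfs[1] <- root; visited[root] <- TRUE
  i <- 1L; nb <- 1L
  while (i <= nb) {
    v <- bfs[i]
    nbrs <- c(e2[e1 == v], e1[e2 == v])
    new <- nbrs[!visited[nbrs]]
    k <- length(new)
    if (k) {
      visited[new] <- TRUE
      parent[new] <- v
      bfs[(nb + 1L):(nb + k)] <- new
      nb <- nb + k
    }
    i <- i + 1L
  }
  list(bfs = bfs[seq_len(nb)], parent = parent)
}

# Fitch pass over all characters at once. `codes` is an n_char x ntip_global
# integer matrix holding state sets encoded as bitmasks (1 = {0}, 2 = {1}).
# Rooting the pass at an arbitrary tip leaves the count invariant.
tr_fitch <- function(tr, codes, weights = NULL, per_char = FALSE) {
  edge <- tr$edge
  root <- min(tr$tips)
  ori <- tr_orient(edge, root)
  bfs <- ori$bfs
  parent <- ori$parent
  n_char <- nrow(codes)
  maxid <- max(edge)
  acc <- vector("list", maxid)
  steps <- if (per_char) integer(n_char) else 0
  for (idx in length(bfs):2) {
    v <- bfs[idx]
    sv <- if (v <= tr$ntip_global) codes[, v] else acc[[v]]
    p <- parent[v]
    ap <- acc[[p]]
    if (is.null(ap)) {
      acc[[p]] <- sv
    } else {
      a <- bitwAnd(ap, sv)
      z <- a == 0L
      if (any(z)) {
        a[z] <- bitwOr(ap, sv)[z]
        steps <- steps + if (per_char) z else sum(weights[z])
      }
      acc[[p]] <- a
    }
  }
  # root is a tip: final combine with its own state
  z <- bitwAnd(acc[[root]], codes[, root]) == 0L
  steps + if (per_char) z else sum(weights[z])
}

# All NNI neighbours (2 per internal edge).
tr_nni_neighbors <- function(tr) {
  edge <- tr$edge
  ntip <- tr$ntip_global
  internal <- edge[, 1] > ntip & edge[, 2] > ntip
  out <- list()
  for (i in which(internal)) {
    u <- edge[i, 1]; v <- edge[i, 2]
    iu <- which((edge[, 1] == u | edge[, 2] == u)); iu <- setdiff(iu, i)
    iv <- which((edge[, 1] == v | edge[, 2] == v)); iv <- setdiff(iv, i)
    # neighbour of u on edge j
    other <- function(j, node) if (edge[j, 1] == node) edge[j, 2] else edge[j, 1]
    b_edge <- iu[2]
    for (cv in iv) {
      e2 <- edge
      b <- other(b_edge, u); cc <- other(cv, v)
      e2[b_edge, ] <- c(u, cc)
      e2[cv, ] <- c(v, b)
      tr2 <- tr; tr2$edge <- e2
      out[[length(out) + 1L]] <- tr2
    }
  }
  out
}

# All SPR rearrangements: prune the subtree on the `v` side of each edge and
# regraft it onto every edge of the remaining tree.
tr_spr_neighbors <- function(tr) {
  edge <- tr$edge
  ntip <- tr$ntip_global
  m <- nrow(edge)
  out <- list()
  for (i in seq_len(m)) {
    for (dir in 1:2) {
      u <- edge[i, dir]; v <- edge[i, 3 - dir]
      if (u <= ntip) next  # anchor must be internal so it can be dissolved
      # component of v without edge i
      sub_nodes <- component_nodes(edge[-i, , drop = FALSE], v)
      rest <- edge[-i, , drop = FALSE]
      in_sub <- rest[, 1] %in% sub_nodes | rest[, 2] %in% sub_nodes
      sub_edges <- rest[in_sub, , drop = FALSE]
      rem <- rest[!in_sub, , drop = FALSE]
      # dissolve u (now degree 2 in rem)
      ju <- which(rem[, 1] == u | rem[, 2] == u)
      if (length(ju) != 2) next
      p <- if (rem[ju[1], 1] == u) rem[ju[1], 2] else rem[ju[1], 1]
      q <- if (rem[ju[2], 1] == u) rem[ju[2], 2] else rem[ju[2], 1]
      rem2 <- rbind(rem[-ju, , drop = FALSE], c(p, q))
      n_rem <- nrow(rem2)
      for (j in seq_len(n_rem - 1L)) {  # last row is (p,q): original position
        x <- rem2[j, 1]; y <- rem2[j, 2]
        e2 <- rbind(rem2[-j, , drop = FALSE],
                    cbind(c(x, u, u), c(u, y, v)),
                    sub_edges)
        tr2 <- tr; tr2$edge <- e2
        out[[length(out) + 1L]] <- tr2
      }
    }
  }
  out
}

component_nodes <- function(edge, start) {
  e1 <- edge[, 1]; e2 <- edge[, 2]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nb <- c(e2[e1 %in% frontier], e1[e2 %in% frontier])
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# Canonical topology string (rooted at the lowest tip id, children sorted);
# equal strings iff equal unrooted topologies over the same tip set.
tr_canon <- function(tr) {
  edge <- tr$edge
  root <- min(tr$tips)
  ori <- tr_orient(edge, root)
  bfs <- ori$bfs; parent <- ori$parent
  maxid <- max(edge)
  lab <- rep(NA_character_, maxid)
  kids <- vector("list", maxid)
  for (idx in length(bfs):2) {
    v <- bfs[idx]
    sv <- if (v <= tr$ntip_global) as.character(v) else {
      paste0("(", paste(sort(unlist(kids[[v]])), collapse = ","), ")")
    }
    p <- parent[v]
    kids[[p]] <- c(kids[[p]], sv)
  }
  paste0(root, "|", paste(sort(unlist(kids[[root]])), collapse = ","))
}

# Non-trivial splits as canonical strings of global tip ids (the side not
# containing the lowest tip).
tr_splits <- function(tr) {
  edge <- tr$edge
  root <- min(tr$tips)
  ntot <- length(tr$tips)
  ori <- tr_orient(edge, root)
  bfs <- ori$bfs; parent <- ori$parent
  maxid <- max(edge)
  below <- vector("list", maxid)
  out <- character(0)
  for (idx in length(bfs):2) {
    v <- bfs[idx]
    tipset <- if (v <= tr$ntip_global) v else sort(unlist(below[[v]]))
    p <- parent[v]
    below[[p]] <- c(below[[p]], list(tipset))
    k <- length(tipset)
    if (k >= 2 && k <= ntot - 2) {
      out <- c(out, paste(tipset, collapse = ","))
    }
  }
  out
}

split_key <- function(tip_ids) paste(sort(tip_ids), collapse = ",")

# Conversion to ape ----------------------------------------------------------

tr_to_phylo <- function(tr, taxa) {
  edge <- tr$edge
  tips <- sort(tr$tips)
  ntip <- length(tips)
  min_tip <- tips[1]
  # root at the internal node adjacent to the lowest tip (degree-3 root =>
  # valid unrooted phylo)
  j <- which(edge[, 1] == min_tip | edge[, 2] == min_tip)[1]
  root_int <- if (edge[j, 1] == min_tip) edge[j, 2] else edge[j, 1]
  ori <- tr_orient(edge, root_int)
  bfs <- ori$bfs; parent <- ori$parent
  internals <- bfs[bfs > tr$ntip_global]
  new_id <- integer(max(edge))
  new_id[tips] <- seq_len(ntip)
  new_id[internals] <- ntip + seq_along(internals)
  children <- bfs[-1]
  phy <- structure(list(
    edge = cbind(new_id[parent[children]], new_id[children]),
    tip.label = taxa[tips],
    Nnode = length(internals)
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

tr_from_phylo <- function(phy, taxa) {
  phy <- ape::unroot(phy)
  phy <- ape::collapse.singles(phy)
  ntot <- length(taxa)
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx)) {
    abort(paste0("tree tips not in matrix taxa: ",
                 paste(phy$tip.label[is.na(idx)], collapse = ", ")))
  }
  ntip <- length(phy$tip.label)
  map <- c(idx, ntot + seq_len(phy$Nnode))
  list(edge = cbind(map[phy$edge[, 1]], map[phy$edge[, 2]]),
       tips = sort(idx),
       ntip_global = ntot,
       next_id = ntot + phy$Nnode + 1L)
}

# Exhaustive unrooted topology enumeration over the given tips (3, 15, 105,
# 945, ... trees); the oracle behind small-instance search checks.
tr_all_topologies <- function(tip_ids, ntip_global) {
  tip_ids <- as.integer(tip_ids)
  stopifnot(length(tip_ids) >= 3)
  trees <- list(tr_new(tip_ids[1:3], ntip_global))
  for (t in tip_ids[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(i) tr_attach(tr, i, t))
    }), recursive = FALSE)
  }
  trees
}
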