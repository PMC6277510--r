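# Shared fixtures, built in code.

quartet_tree <- function() ape::read.tree(text = "((A,B),(C,D));")

# Presence/absence matrix from a character-vector of 0/1 strings.
pa_from_strings <- function(rows, groups = NULL, ages = NULL,
                            taxa = names(rows)) {
  cells <- do.call(rbind, lapply(strsplit(unname(rows), ""), as.integer))
  rownames(cells) <- taxa
  colnames(cells) <- paste0("f", seq_len(ncol(cells)))
  if (is.null(groups)) {
    groups <- setNames(rep(TRUC_GROUPS, length.out = nrow(cells)), taxa)
  }
  if (!is.null(ages)) names(ages) <- colnames(cells)
  trucphylo::pa_matrix(cells, groups, ages)
}

TRUC_GROUPS <- c("archaea", "bacteria", "eukaryota", "megavirales")

# Random binary matrix with all four groups represented.
random_pa <- function(n_taxa, n_feat, seed, p = 0.5) {
  withr::with_seed(seed, {
    cells <- matrix(rbinom(n_taxa * n_feat, 1, p), n_taxa, n_feat,
                    dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                    sprintf("f%03d", seq_len(n_feat))))
    trucphylo::pa_matrix(
      cells, setNames(rep(TRUC_GROUPS, length.out = n_taxa),
                      rownames(cells)))
  })
}

# A clean (zero-homoplasy) matrix on a known 8-taxon tree: one character
# per internal clade of ((((a,b),(c,d)),((e,f),(g,h)))).
clean_eight_taxon <- function() {
  taxa <- letters[1:8]
  clades <- list(c("a", "b"), c("c", "d"), c("e", "f"), c("g", "h"),
                 c("a", "b", "c", "d"))
  # 8 copies per clade character: enough redundancy that every clade
  # pattern survives character resampling in bootstrap replicates
  cells <- sapply(clades, function(cl) as.integer(taxa %in% cl))
  cells <- cells[, rep(seq_along(clades), each = 8)]  # 40 characters
  rownames(cells) <- taxa
  colnames(cells) <- sprintf("f%02d", seq_len(ncol(cells)))
  list(pa = trucphylo::pa_matrix(
         cells, setNames(rep(TRUC_GROUPS, each = 2), taxa)),
       tree = ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));"),
       n_informative = ncol(cells))
}

# Independent split extraction via ape: set of non-trivial bipartitions as
# sorted label strings, for topology comparisons.
ape_splits <- function(phy) {
  phy <- ape::unroot(phy)
  bp <- ape::prop.part(phy)
  labs <- attr(bp, "labels")
  n <- length(labs)
  keys <- vapply(bp, function(idx) {
    side <- sort(labs[idx])
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    comp <- sort(setdiff(labs, side))
    paste(min(paste(side, collapse = "|"), paste(comp, collapse = "|")),
          collapse = "")
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

same_topology <- function(t1, t2) {
  identical(ape_splits(t1), ape_splits(t2))
}
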