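#' Select universal features
#'
#' A feature is *universal* when it occurs in at least one taxon of each of
#' the four groups (archaea, bacteria, eukaryota, megavirales). Features
#' unique to one group or shared by only two or three groups are dropped;
#' the taxon set is unchanged. The operation is idempotent.
#'
#' @inheritParams pa_taxa
#' @return A [pa_matrix()] restricted to universal features.
#' @export
select_universal <- function(pa) {
  require_groups(pa)
  per_group <- group_presence(pa)
  keep <- which(rowSums(per_group) == length(TRUC_GROUPS))
  pa_keep_features(pa, keep)
}

# features x groups logical matrix: does the feature occur in the group?
group_presence <- function(pa) {
  matrix(vapply(TRUC_GROUPS, function(g) {
    colSums(pa$cells[pa$groups == g, , drop = FALSE]) > 0
  }, logical(ncol(pa$cells))),
  ncol = length(TRUC_GROUPS),
  dimnames = list(colnames(pa$cells), TRUC_GROUPS))
}

#' Keep parsimony-informative characters
#'
#' A binary character is parsimony-informative when both states are each
#' carried by at least two taxa; constant characters and autapomorphies
#' (single-taxon presences or absences) cannot discriminate topologies under
#' parsimony and are dropped.
#'
#' @inheritParams pa_taxa
#' @return A [pa_matrix()] restricted to informative characters.
#' @export
filter_parsimony_informative <- function(pa) {
  ones <- colSums(pa$cells)
  zeros <- nrow(pa$cells) - ones
  pa_keep_features(pa, which(ones >= 2 & zeros >= 2))
}

#' Venn-style sharing-pattern counts
#'
#' Assigns every feature to the subset of groups in which it occurs at least
#' once (A = archaea, B = bacteria, E = eukaryota, V = megavirales) and
#' counts features per subset. The 15 non-empty subsets partition the
#' feature set, so counts sum to the number of features. Features occurring
#' in no taxon cannot be placed in a non-empty subset; they are dropped with
#' a warning.
#'
#' @inheritParams pa_taxa
#' @return A tibble with columns `pattern` (e.g. `"ABEV"`, `"AV"`) and `n`,
#'   covering all 15 subsets (zero counts included), ordered by subset size
#'   then alphabetically.
#' @export
sharing_patterns <- function(pa) {
  require_groups(pa)
  per_group <- group_presence(pa)
  codes <- unname(TRUC_GROUP_CODES[TRUC_GROUPS])
  pattern <- apply(per_group, 1, function(p) paste(codes[p], collapse = ""))
  empty <- pattern == ""
  if (any(empty)) {
    warn(sprintf("%d feature(s) present in no taxon were dropped", sum(empty)))
    pattern <- pattern[!empty]
  }
  all_subsets <- unlist(lapply(1:4, function(k) {
    apply(combn(codes, k), 2, paste, collapse = "")
  }))
  counts <- table(factor(pattern, levels = all_subsets))
  tibble(pattern = all_subsets, n = as.integer(counts))
}
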