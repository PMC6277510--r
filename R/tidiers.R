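#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns the per-element table of a result
#' (trees, splits, coordinates, clusters, genomes), `glance()` a one-row
#' summary.
#'
#' @param x a `truc_mp`, `truc_boot`, `truc_pcoa`, `truc_fourbranch` or
#'   `truc_pangenome` object.
#' @param ... unused.
#' @return A tibble.
#' @name truc-tidiers
NULL

#' @rdname truc-tidiers
#' @export
tidy.truc_mp <- function(x, ...) {
  tibble(tree = seq_along(x$trees),
         length = x$length,
         newick = vapply(x$trees, function(t) ape::write.tree(t),
                         character(1)))
}

#' @rdname truc-tidiers
#' @export
glance.truc_mp <- function(x, ...) {
  tibble(length = x$length, n_trees = length(x$trees),
         n_starts = x$n_starts, rearrangement = x$rearrangement)
}

#' @rdname truc-tidiers
#' @export
tidy.truc_boot <- function(x, ...) x$splits

#' @rdname truc-tidiers
#' @export
glance.truc_boot <- function(x, ...) {
  tibble(reps = x$reps, n_splits = nrow(x$splits),
         min_support = min(x$splits$support),
         mean_support = mean(x$splits$support))
}

#' @rdname truc-tidiers
#' @export
tidy.truc_pcoa <- function(x, ...) x$points

#' @rdname truc-tidiers
#' @export
glance.truc_pcoa <- function(x, ...) {
  tibble(n = nrow(x$points), k = x$k,
         var_pct_1 = x$var_pct[1],
         var_pct_2 = if (x$k >= 2) x$var_pct[2] else NA_real_,
         var_pct_3 = if (x$k >= 3) x$var_pct[3] else NA_real_)
}

#' @rdname truc-tidiers
#' @export
tidy.truc_fourbranch <- function(x, ...) x$clusters

#' @rdname truc-tidiers
#' @export
glance.truc_fourbranch <- function(x, ...) {
  tibble(k = nrow(x$summary), purity = x$purity)
}

#' @rdname truc-tidiers
#' @export
tidy.truc_pangenome <- function(x, ...) x$per_genome

#' @rdname truc-tidiers
#' @export
glance.truc_pangenome <- function(x, ...) {
  tibble(n_genomes = x$global$n_genomes,
         pangenome_families = x$global$pangenome_families,
         core_families = x$global$core_families)
}
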