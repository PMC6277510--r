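#' Age-weighted feature matrix
#'
#' Turns presence/absence into age-weighted vectors: the entry for feature
#' `f` in taxon `t` is `1 - nd_f` when present and 0 when absent, so the
#' most ancient features (nd near 0) dominate distances and the most recent
#' (nd near 1) weigh nothing. Absences contribute 0 rather than missing
#' values because Euclidean distances need complete vectors.
#'
#' @inheritParams pa_taxa
#' @return Numeric taxa-by-features matrix.
#' @export
age_weight <- function(pa) {
  if (is.null(pa$ages)) {
    abort(paste0("age_weight() needs feature ages; missing for all of: ",
                 paste(head(pa_features(pa), 5), collapse = ", "), " ..."))
  }
  sweep(pa$cells, 2, 1 - pa$ages, `*`)
}

#' Classical principal coordinate analysis
#'
#' Classical (metric) PCoA: square the distances, double-centre, and
#' eigendecompose (via [stats::cmdscale()]). For Euclidean input the
#' embedding over all positive axes reproduces the distances exactly; small
#' negative eigenvalues are numerical noise. For ingested non-Euclidean
#' matrices a Cailliez correction is available.
#'
#' Axis signs are fixed by forcing the largest-magnitude coordinate on each
#' axis to be positive, so runs are reproducible.
#'
#' @param d a `dist` object or symmetric zero-diagonal distance matrix with
#'   non-negative entries.
#' @param k number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @param groups optional named group labels per point, carried into the
#'   result.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return An object of class `truc_pcoa`: list with `points` (tibble:
#'   `taxon`, `group`, `axis_1..axis_k`), `eig` (all eigenvalues,
#'   descending), `var_pct` (% variance per positive axis, summing to 100)
#'   and `k`.
#' @export
classical_pcoa <- function(d, k = 3, groups = NULL,
                           correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8) {
    abort("`d` must be a symmetric distance matrix")
  }
  if (any(dm < 0)) abort("`d` has negative entries; not a distance matrix")
  if (any(abs(diag(dm)) > 1e-12)) abort("`d` must have a zero diagonal")
  n <- nrow(dm)
  # we ask for all n-1 axes and trim to the positive spectrum ourselves, so
  # cmdscale's "only k of the first ..." advisory is expected and muffled
  fit <- withCallingHandlers(
    cmdscale(as.dist(dm), k = n - 1, eig = TRUE,
             add = correction == "cailliez"),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(fit$eig)) * 1e-12
  npos <- sum(fit$eig > tol)
  var_pct <- 100 * eig[seq_len(npos)] / sum(eig[seq_len(npos)])
  k_eff <- min(k, npos, ncol(fit$points))
  pts <- fit$points[, seq_len(k_eff), drop = FALSE]
  # reproducible axis orientation
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  taxa <- rownames(dm) %||% paste0("p", seq_len(n))
  colnames(pts) <- paste0("axis_", seq_len(k_eff))
  points <- tibble(taxon = taxa,
                   group = if (is.null(groups)) NA_character_
                           else unname(groups[taxa])) |>
    dplyr::bind_cols(as_tibble(pts))
  structure(list(points = points, eig = eig,
                 var_pct = var_pct[seq_len(k_eff)], k = k_eff,
                 all_positive_points = fit$points[
                   , seq_len(min(npos, ncol(fit$points))), drop = FALSE]),
            class = "truc_pcoa")
}

#' Evolutionary PCoA of proteomes
#'
#' Embeds proteomes in `k` dimensions by classical PCoA of Euclidean
#' distances over age-weighted (`1 - nd`) feature vectors, so that proteome
#' dissimilarity reflects differences in the evolutionary ages of their
#' components. With all ages 0 this reduces to PCoA of raw presence/absence
#' Euclidean distances.
#'
#' @inheritParams pa_taxa
#' @param k number of axes (default 3).
#' @param correction passed to [classical_pcoa()].
#' @return A `truc_pcoa` object; see [classical_pcoa()].
#' @export
evo_pcoa <- function(pa, k = 3, correction = c("none", "cailliez")) {
  w <- age_weight(pa)
  classical_pcoa(dist(w), k = k, groups = pa$groups, correction = correction)
}

#' @export
print.truc_pcoa <- function(x, ...) {
  cat(sprintf("<truc_pcoa> %d points, %d axes (%s%% variance)\n",
              nrow(x$points), x$k,
              paste(sprintf("%.1f", x$var_pct), collapse = ", ")))
  invisible(x)
}

#' Silhouette-style group separation in an ordination
#'
#' Mean silhouette width per group over the embedded coordinates: for each
#' point, the contrast between its mean distance to its own group and to the
#' nearest other group, in `[-1, 1]`. Scores above 0.5 indicate compact,
#' well-separated clouds; scores at or below 0 indicate overlap.
#'
#' @param result a `truc_pcoa` object with group labels.
#' @return Tibble with `group`, `n` and `score`.
#' @export
group_separation <- function(result) {
  pts <- result$points
  if (all(is.na(pts$group))) abort("ordination carries no group labels")
  coords <- as.matrix(pts[, startsWith(names(pts), "axis_"), drop = FALSE])
  cl <- as.integer(factor(pts$group))
  sil <- cluster::silhouette(cl, dist(coords))
  tibble(group = levels(factor(pts$group))[sil[, "cluster"]],
         width = sil[, "sil_width"]) |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), score = mean(.data$width), .groups = "drop")
}

#' Write ordination coordinates as TSV
#'
#' Coordinates per taxon with the % variance per axis in the header comment,
#' ready for external 3D scatter plotting.
#'
#' @param result a `truc_pcoa` object.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_pcoa_tsv <- function(result, path, seed = NULL) {
  pts <- result$points
  lines <- c(paste(names(pts), collapse = "\t"),
             do.call(paste, c(lapply(pts, format_tsv_col), sep = "\t")))
  write_lines_with_header(
    lines, path, seed = seed,
    extra = sprintf("evo_pcoa var_pct=%s",
                    paste(sprintf("%.2f", result$var_pct), collapse = ",")))
}
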