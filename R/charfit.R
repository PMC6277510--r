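#' Per-character fit indices on a tree
#'
#' For every binary character, computes the quantities behind
#' homoplasy-versus-age diagnostics: `m`, the minimum steps on any tree
#' (1 when both states occur, 0 for a constant character); `s`, the Fitch
#' steps on the evaluated tree; `g`, the maximum steps on any tree (for a
#' binary character with `a` presences and `b` absences, `min(a, b)`); and
#' the derived indices
#' consistency `CI = m/s` (1 when `s = 0`), homoplasy `HI = 1 - CI`,
#' retention `RI = (g - s)/(g - m)` (undefined when `g = m`, returned as
#' `NA`), rescaled consistency `RC = CI * RI`, and Goloboff fit
#' `G = k/(k + s - m)` with concavity constant `k`.
#'
#' @inheritParams tree_length
#' @param k Goloboff concavity constant (default 2); larger `k` is more
#'   tolerant of extra steps.
#' @return A tibble of class `truc_charfit` with one row per character:
#'   `feature`, `m`, `s`, `g`, `ci`, `ri`, `rc`, `hi`, `g_fit`, `nd` (the
#'   character age, `NA` when the matrix carries no ages).
#' @seealso [fit_vs_age()] to tabulate indices against character age.
#' @export
character_fit <- function(tree, pa, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("`k` must be a single positive number")
  }
  cells <- as_pa_cells(pa)
  cells <- cells[tree$tip.label, , drop = FALSE]
  tr <- tr_from_phylo(tree, rownames(cells))
  s <- as.integer(tr_fitch(tr, codes_from_cells(cells), per_char = TRUE))
  a <- colSums(cells)
  b <- nrow(cells) - a
  m <- as.integer(a >= 1 & b >= 1)
  g <- as.integer(pmin(a, b))
  ci <- ifelse(s > 0, m / s, 1)
  hi <- 1 - ci
  ri <- ifelse(g > m, (g - s) / (g - m), NA_real_)
  rc <- ci * ri
  g_fit <- k / (k + (s - m))
  ages <- if (is.null(pa$ages)) rep(NA_real_, ncol(cells)) else
    unname(pa$ages[colnames(cells)])
  out <- tibble(feature = colnames(cells), m = m, s = s, g = g,
                ci = ci, ri = ri, rc = rc, hi = hi, g_fit = g_fit, nd = ages)
  class(out) <- c("truc_charfit", class(out))
  out
}

#' Fit indices against character age
#'
#' Reshapes a [character_fit()] table to the age-versus-index table used for
#' homoplasy-age diagnostics: one row per character, sorted by age `nd`.
#'
#' @param fit a [character_fit()] tibble.
#' @return Tibble with columns `feature`, `nd`, `ci`, `ri`, `rc`, `hi`,
#'   `g_fit`, sorted by `nd`.
#' @export
fit_vs_age <- function(fit) {
  if (all(is.na(fit$nd))) abort("no character ages available")
  fit |>
    dplyr::select("feature", "nd", "ci", "ri", "rc", "hi", "g_fit") |>
    arrange(.data$nd)
}

#' Write a fit table as TSV
#' @param fit a [character_fit()] or [fit_vs_age()] tibble.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path, seed = NULL) {
  lines <- c(paste(names(fit), collapse = "\t"),
             do.call(paste, c(lapply(fit, format_tsv_col), sep = "\t")))
  write_lines_with_header(lines, path, seed = seed, extra = "character_fit")
}

format_tsv_col <- function(x) {
  if (is.double(x)) sprintf("%.6g", x) else as.character(x)
}
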