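AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Per-site substitution with probability p; substitutions always change the
# residue, so the expected identity to the template is exactly 1 - p.
mutate_protein <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA20, a), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Simulate genomes with planted gene families
#'
#' Draws one random ancestral protein per family in `cfg$family_spec`, then
#' emits `genes_per_genome` diverged copies into every genome the family
#' spans; the per-site substitution probability (`divergence`) controls how
#' far members drift from the ancestor, so homology thresholds can be
#' exercised from both sides. Because members diverge independently from
#' the ancestor, the expected pairwise identity within a family is about
#' `(1-p)^2 + p^2/19` for divergence `p` (e.g. ~64% at the default
#' `p = 0.2`, ~40% at `p = 0.37`). Genes not meant to be shared are
#' declared as single-genome families.
#'
#' @param cfg a [sim_config()] with a non-empty `family_spec`.
#' @param genome_ids character vector of all genome ids; spans may only
#'   reference these. Defaults to the ids appearing in `family_spec`.
#' @return List of class `truc_sim_genomes`: `genes` (tibble `genome`,
#'   `gene`, `seq`) and `truth` (tibble `gene`, `genome`, `family`,
#'   `span`).
#' @export
sim_genomes <- function(cfg, genome_ids = NULL) {
  stopifnot(inherits(cfg, "truc_sim_config"))
  spec <- cfg$family_spec
  if (is.null(spec) || nrow(spec) == 0) {
    abort("`cfg$family_spec` is empty; nothing to simulate")
  }
  spans <- strsplit(spec$genomes, ";", fixed = TRUE)
  known <- genome_ids %||% unique(unlist(spans))
  bad <- setdiff(unlist(spans), known)
  if (length(bad)) {
    abort(paste0("family span references unknown genome(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  with_seed(cfg$seed, {
    rows <- purrr::pmap(
      list(spec$family, spans, spec$genes_per_genome, spec$length,
           spec$divergence),
      function(fam, span, k, len, div) {
        anc <- random_protein(len)
        purrr::map_dfr(span, function(g) {
          tibble(genome = g,
                 gene = sprintf("%s|%s.%d", g, fam, seq_len(k)),
                 seq = vapply(seq_len(k), function(i) mutate_protein(anc, div),
                              character(1)),
                 family = fam,
                 span_size = length(span))
        })
      })
  })
  all <- bind_rows(rows)
  structure(list(genes = all |> select("genome", "gene", "seq"),
                 truth = all |> select("gene", "genome", "family",
                                       span = "span_size")),
            class = "truc_sim_genomes")
}

#' @export
print.truc_sim_genomes <- function(x, ...) {
  cat(sprintf("<truc_sim_genomes> %d genes, %d genomes, %d families\n",
              nrow(x$genes), length(unique(x$genes$genome)),
              length(unique(x$truth$family))))
  invisible(x)
}
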