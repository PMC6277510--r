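#' Simulation configuration
#'
#' One validated configuration object drives all three generators: the
#' four-group character matrix ([sim_presence_matrix()]), the genomes with
#' planted gene families ([sim_genomes()]) and the truth-labeled hit tables
#' ([sim_hit_table()]). Defaults describe a conservative fold-superfamily
#' style regime: strongly retained characters (1% per-branch flip rates),
#' mild age jitter, and a Tupanvirus-like donor mix.
#'
#' @param n_taxa_per_group taxa simulated per group (archaea, bacteria,
#'   eukaryota, megavirales); at least 2.
#' @param n_characters number of binary characters.
#' @param gain_rate,loss_rate per-branch probabilities of a 0->1 (convergent
#'   gain) or 1->0 (loss) flip, both in `[0, 1]`.
#' @param age_noise standard deviation of Gaussian jitter added to character
#'   ages (ages are clipped back to `[0, 1]`).
#' @param origin `"random"`: each character's gain node is drawn uniformly
#'   from the internal nodes of the truth tree; `"root"`: all characters are
#'   ancestral (present at the root).
#' @param family_spec tibble describing planted gene families: columns
#'   `family`, `genomes` (character, `;`-separated genome ids),
#'   `genes_per_genome`, `length` (residues), and optionally `divergence`
#'   (per-site substitution probability within the family, default 0.2).
#' @param donor_props named numeric vector of donor-class proportions over
#'   `virus`, `eukaryota`, `bacteria`, `archaea`; non-negative, summing to
#'   at most 1. The remainder are ORFans.
#' @param orfan_mode `"no_hits"` (default): ORFan genes get no hits at all;
#'   `"below_threshold"`: they get hits that fail [homology_thresholds()].
#' @param decoy_self_hits if `TRUE`, every non-ORFan gene also receives a
#'   top-scoring hit from the query's own family, exercising self-relative
#'   exclusion.
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @return A validated list of class `truc_sim_config`.
#' @export
sim_config <- function(n_taxa_per_group = 8,
                       n_characters = 200,
                       gain_rate = 0.01,
                       loss_rate = 0.01,
                       age_noise = 0.05,
                       origin = c("random", "root"),
                       family_spec = NULL,
                       donor_props = c(virus = 0.51, eukaryota = 0.11,
                                       bacteria = 0.08, archaea = 0.002),
                       orfan_mode = c("no_hits", "below_threshold"),
                       decoy_self_hits = FALSE,
                       seed = 1) {
  origin <- match.arg(origin)
  orfan_mode <- match.arg(orfan_mode)
  if (!is.numeric(n_taxa_per_group) || n_taxa_per_group < 2) {
    abort("`n_taxa_per_group` must be at least 2")
  }
  if (!is.numeric(n_characters) || n_characters < 1) {
    abort("`n_characters` must be at least 1")
  }
  stopifnot_scalar_prob(gain_rate, "gain_rate")
  stopifnot_scalar_prob(loss_rate, "loss_rate")
  if (!is.numeric(age_noise) || age_noise < 0) {
    abort("`age_noise` must be a non-negative number")
  }
  if (length(donor_props)) {
    if (is.null(names(donor_props)) ||
        !all(names(donor_props) %in% setdiff(DONOR_CLASSES, "ORFan"))) {
      abort("`donor_props` must be named by donor class (virus, eukaryota, bacteria, archaea)")
    }
    if (any(donor_props < 0) || sum(donor_props) > 1 + 1e-9) {
      abort("`donor_props` must be non-negative and sum to at most 1")
    }
  }
  if (!is.null(family_spec)) {
    need <- c("family", "genomes", "genes_per_genome", "length")
    if (!all(need %in% names(family_spec))) {
      abort(paste0("`family_spec` needs columns: ",
                   paste(need, collapse = ", ")))
    }
    if (!"divergence" %in% names(family_spec)) {
      family_spec$divergence <- 0.2
    }
  }
  structure(list(n_taxa_per_group = as.integer(n_taxa_per_group),
                 n_characters = as.integer(n_characters),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 age_noise = age_noise, origin = origin,
                 family_spec = family_spec, donor_props = donor_props,
                 orfan_mode = orfan_mode, decoy_self_hits = decoy_self_hits,
                 seed = as.integer(seed)),
            class = "truc_sim_config")
}

#' @export
print.truc_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<truc_sim_config> %d taxa/group x %d characters, ",
                     "gain/loss %.3g/%.3g, seed %d\n"),
              x$n_taxa_per_group, x$n_characters, x$gain_rate, x$loss_rate,
              x$seed))
  invisible(x)
}

# Balanced rooted truth tree: ((archaea, bacteria), (eukaryota,
# megavirales)), each group a balanced clade over its taxa.
truth_tree_newick <- function(n_per_group) {
  bal <- function(labels) {
    if (length(labels) == 1) return(labels)
    h <- ceiling(length(labels) / 2)
    paste0("(", bal(labels[seq_len(h)]), ",",
           bal(labels[-seq_len(h)]), ")")
  }
  labs <- group_taxa_labels(n_per_group)
  sprintf("((%s,%s),(%s,%s));",
          bal(labs$archaea), bal(labs$bacteria),
          bal(labs$eukaryota), bal(labs$megavirales))
}

group_taxa_labels <- function(n_per_group) {
  pre <- c(archaea = "arc", bacteria = "bac", eukaryota = "euk",
           megavirales = "vir")
  lapply(pre, function(p) sprintf("%s%02d", p, seq_len(n_per_group)))
}
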