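# Representative taxonomy paths per donor class; family and genus are the
# last two elements, matching the convention of classify_best_hits().
DONOR_TAXONOMY <- c(
  virus = "Viruses;Varidnaviria;Phycodnaviridae;Chlorovirus",
  eukaryota = "Eukaryota;Opisthokonta;Saccharomycetaceae;Saccharomyces",
  bacteria = "Bacteria;Proteobacteria;Rickettsiaceae;Rickettsia",
  archaea = "Archaea;Euryarchaeota;Methanomassiliicoccaceae;Methanomassiliicoccus"
)

# Query organism taxonomy used by the simulators (a mimivirus-like giant
# virus); decoy self-hits are planted inside the same family.
SIM_QUERY_TAXONOMY <- "Viruses;Megavirales;Mimiviridae;Tupanvirus"
SELF_FAMILY_TAXONOMY <- "Viruses;Megavirales;Mimiviridae;Mimivirus"

#' Simulate a truth-labeled best-hit table
#'
#' Assigns every gene a donor class by sampling `cfg$donor_props`
#' (remainder: ORFan), and emits hits so that each non-ORFan gene's
#' top-scoring passing hit carries the planted donor's taxonomy, with 1-2
#' lower-scoring hits from other classes as background. ORFan genes get no
#' hits (`orfan_mode = "no_hits"`) or hits failing [homology_thresholds()]
#' (`"below_threshold"`). With `cfg$decoy_self_hits`, an even
#' higher-scoring hit from the query's own family is added to every
#' non-ORFan gene; family-rank exclusion must ignore it.
#'
#' @param cfg a [sim_config()].
#' @param genes character vector of gene ids, or a gene tibble with a
#'   `gene` column.
#' @return List of class `truc_sim_hits`: `hits` (tibble: `query`,
#'   `subject`, `identity`, `coverage_q`, `coverage_s`, `score`, `evalue`,
#'   `taxonomy`), `truth` (tibble `gene`, `donor`), and `query_taxonomy`.
#' @export
sim_hit_table <- function(cfg, genes) {
  stopifnot(inherits(cfg, "truc_sim_config"))
  if (is.data.frame(genes)) genes <- genes$gene
  n <- length(genes)
  props <- cfg$donor_props
  classes <- c(names(props), "ORFan")
  probs <- c(props, 1 - sum(props))
  with_seed(cfg$seed + 1L, {
    donor <- sample(classes, n, replace = TRUE, prob = probs)
    rows <- purrr::map(seq_len(n), function(i) {
      if (donor[i] == "ORFan") {
        if (cfg$orfan_mode == "no_hits") return(NULL)
        # below-threshold decoy: fails both e-value and identity
        return(tibble(query = genes[i],
                      subject = sprintf("junk|%05d", i),
                      identity = 10, coverage_q = 0.1, coverage_s = 0.1,
                      score = 20, evalue = 5,
                      taxonomy = DONOR_TAXONOMY[["bacteria"]]))
      }
      top_score <- 150 + round(100 * runif(1))
      others <- sample(setdiff(names(DONOR_TAXONOMY), donor[i]),
                       sample(1:2, 1))
      out <- tibble(
        query = genes[i],
        subject = c(sprintf("%s|top%05d", donor[i], i),
                    sprintf("%s|bg%05d.%s", others, i, seq_along(others))),
        identity = c(round(40 + 50 * runif(1), 1),
                     round(25 + 30 * runif(length(others)), 1)),
        coverage_q = 0.9, coverage_s = 0.9,
        score = c(top_score,
                  top_score - 10 - round(40 * runif(length(others)))),
        evalue = 10^(-runif(1 + length(others), 10, 50)),
        taxonomy = unname(DONOR_TAXONOMY[c(donor[i], others)]))
      if (cfg$decoy_self_hits) {
        out <- bind_rows(tibble(
          query = genes[i], subject = sprintf("self|%05d", i),
          identity = 95, coverage_q = 0.99, coverage_s = 0.99,
          score = top_score + 50, evalue = 1e-80,
          taxonomy = SELF_FAMILY_TAXONOMY), out)
      }
      out
    })
  })
  structure(list(hits = bind_rows(rows),
                 truth = tibble(gene = genes, donor = donor),
                 query_taxonomy = SIM_QUERY_TAXONOMY),
            class = "truc_sim_hits")
}

#' @export
print.truc_sim_hits <- function(x, ...) {
  cat(sprintf("<truc_sim_hits> %d hits for %d genes\n",
              nrow(x$hits), nrow(x$truth)))
  invisible(x)
}

#' Simulate hits for a planted chimeric gene
#'
#' Builds a per-fragment hit table for one gene whose N-terminal part
#' descends from one donor pool and whose C-terminal part from another: a
#' fragment's best hit carries the N-donor taxonomy when the fragment
#' midpoint lies before `junction` (0-based residue index), the C-donor
#' taxonomy otherwise. Used to test junction localisation in fragment
#' rhizomes.
#'
#' @param seq amino-acid sequence of the gene.
#' @param junction 0-based residue position where donor ancestry switches.
#' @param donor_n,donor_c donor classes of the N- and C-terminal parts.
#' @inheritParams fragment_protein
#' @return List: `hits` (per-fragment, `query` = fragment id), `truth`
#'   (tibble `fragment`, `donor`), `query_taxonomy`.
#' @export
sim_chimeric_hits <- function(seq, junction, donor_n = "eukaryota",
                              donor_c = "virus", window = 40, step = 20,
                              min_len = 20) {
  frags <- fragment_protein(seq, window = window, step = step,
                            min_len = min_len)
  mid <- (frags$start + frags$end) / 2
  donor <- ifelse(mid < junction, donor_n, donor_c)
  hits <- tibble(query = as.character(frags$fragment),
                 subject = sprintf("%s|frag%03d", donor, frags$fragment),
                 identity = 60, coverage_q = 0.95, coverage_s = 0.95,
                 score = 100, evalue = 1e-20,
                 taxonomy = unname(DONOR_TAXONOMY[donor]))
  list(hits = hits,
       truth = tibble(fragment = frags$fragment, donor = donor),
       query_taxonomy = SIM_QUERY_TAXONOMY)
}
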