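#' Cut a protein into overlapping fragments
#'
#' Sliding-window fragmentation for gene-level mosaicism scans: windows of
#' `window` residues starting every `step` residues (0-based, half-open
#' coordinates). The final window is truncated at the sequence end and
#' dropped when shorter than `min_len`. Boundaries are a deterministic
#' function of the sequence length alone.
#'
#' @param seq amino-acid sequence (single string).
#' @param window window length in residues (default 40).
#' @param step offset between window starts (default 20, half-overlapping).
#' @param min_len minimum length of a kept (truncated) trailing window.
#' @return Tibble of fragments: `fragment` (id `<n>` in order), `start`,
#'   `end` (0-based, half-open), `seq`.
#' @export
fragment_protein <- function(seq, window = 40, step = 20, min_len = 20) {
  if (window <= 0 || step <= 0 || step > window) {
    abort("need window > 0 and 0 < step <= window")
  }
  len <- nchar(seq)
  if (len == 0) {
    return(tibble(fragment = integer(), start = integer(), end = integer(),
                  seq = character()))
  }
  starts <- as.integer(seq.int(0L, max(0L, len - 1L), by = step))
  starts <- starts[starts < len]
  ends <- as.integer(pmin(starts + window, len))
  keep <- (ends - starts) >= min(min_len, window)
  starts <- starts[keep]; ends <- ends[keep]
  tibble(fragment = seq_along(starts),
         start = starts, end = ends,
         seq = substring(seq, starts + 1L, ends))
}

# Parse a taxonomy path: semicolon-separated lineage, superkingdom (or
# "Viruses") first; by convention the last two elements are family and
# genus. Returns list(class, family, genus) with NAs where unknown.
parse_taxonomy <- function(path) {
  if (is.na(path) || !nzchar(path)) {
    return(list(class = NA_character_, family = NA_character_,
                genus = NA_character_))
  }
  parts <- trimws(strsplit(path, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  sk <- tolower(parts[1])
  class <- if (sk %in% c("viruses", "virus")) "virus"
  else if (sk == "eukaryota") "eukaryota"
  else if (sk == "bacteria") "bacteria"
  else if (sk == "archaea") "archaea"
  else NA_character_
  n <- length(parts)
  list(class = class,
       family = if (n >= 2) parts[max(2, n - 1)] else NA_character_,
       genus = if (n >= 2) parts[n] else NA_character_)
}

#' Classify query units by their best passing hit
#'
#' Implements best-hit donor classification for rhizome construction. Hits
#' whose subject taxonomy matches the query's own family (or genus) are
#' excluded first, so self-relatives cannot mask the donor signal; the
#' top-scoring remaining hit sets the donor class (`virus`, `eukaryota`,
#' `bacteria`, `archaea`) from the superkingdom (or Viruses root) of its
#' taxonomy path. Units with no remaining hits are ORFans. Score ties are
#' broken deterministically by higher identity, then lexicographic subject
#' id, and flagged in `tie`.
#'
#' Taxonomy paths are semicolon-separated lineages, superkingdom first,
#' with family and genus as the last two elements
#' (e.g. `"Viruses;...;Mimiviridae;Mimivirus"`). Hits with missing or
#' unclassifiable taxonomy are skipped with a warning.
#'
#' @param hits tibble with columns `query`, `subject`, `score`, `identity`,
#'   `taxonomy` (path as above).
#' @param query_taxonomy taxonomy path of the query organism (used for
#'   self-relative exclusion).
#' @param exclusion_rank `"family"` (default), `"genus"` or `"none"`.
#' @param units optional character vector of all unit ids (genes or
#'   fragments); units absent from `hits` are reported as ORFans.
#' @return Tibble: `unit`, `donor` (factor over virus/eukaryota/bacteria/
#'   archaea/ORFan), `best_subject`, `best_score`, `tie`.
#' @export
classify_best_hits <- function(hits, query_taxonomy,
                               exclusion_rank = c("family", "genus", "none"),
                               units = NULL) {
  exclusion_rank <- match.arg(exclusion_rank)
  qt <- parse_taxonomy(query_taxonomy)
  tax <- lapply(hits$taxonomy, parse_taxonomy)
  cls <- vapply(tax, `[[`, "", "class")
  bad <- is.na(cls)
  if (any(bad)) {
    warn(sprintf("%d hit(s) with missing or unclassifiable taxonomy skipped",
                 sum(bad)))
  }
  keep <- !bad
  if (exclusion_rank == "family" && !is.na(qt$family)) {
    keep <- keep & vapply(tax, `[[`, "", "family") != qt$family
  } else if (exclusion_rank == "genus" && !is.na(qt$genus)) {
    keep <- keep & vapply(tax, `[[`, "", "genus") != qt$genus
  }
  keep[is.na(keep)] <- FALSE
  h <- hits[keep, , drop = FALSE]
  h$donor <- cls[keep]
  assigned <- if (nrow(h)) {
    h |>
      group_by(.data$query) |>
      arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
              .data$subject, .by_group = TRUE) |>
      summarise(best_subject = .data$subject[1],
                best_score = .data$score[1],
                tie = dplyr::n() > 1 &&
                  any(.data$score[-1] == .data$score[1] &
                        .data$donor[-1] != .data$donor[1]),
                donor = .data$donor[1],
                .groups = "drop") |>
      rename(unit = "query") |>
      select("unit", "donor", "best_subject", "best_score", "tie")
  } else {
    tibble(unit = character(), donor = character(),
           best_subject = character(), best_score = numeric(),
           tie = logical())
  }
  if (!is.null(units)) {
    orphan <- setdiff(as.character(units), assigned$unit)
    assigned <- bind_rows(assigned,
                          tibble(unit = orphan, donor = "ORFan",
                                 best_subject = NA_character_,
                                 best_score = NA_real_, tie = FALSE))
    assigned <- assigned[match(as.character(units), assigned$unit), ]
  }
  assigned$donor <- factor(assigned$donor, levels = DONOR_CLASSES)
  assigned
}

#' Aggregate rhizome assignments for a genome
#'
#' Donor-class counts and one-decimal percentages over a genome's genes;
#' genes without an assignment row are ORFans. Counts partition the gene
#' set.
#'
#' @param assignments a [classify_best_hits()] tibble.
#' @param genome_size total number of genes in the genome (at least the
#'   number of assigned units).
#' @return Tibble of class `truc_rhizome`: `donor`, `n`, `pct`.
#' @export
aggregate_rhizome <- function(assignments, genome_size = nrow(assignments)) {
  if (genome_size < nrow(assignments)) {
    abort("`genome_size` smaller than the number of assigned units")
  }
  counts <- table(factor(assignments$donor, levels = DONOR_CLASSES))
  counts["ORFan"] <- counts["ORFan"] + (genome_size - nrow(assignments))
  out <- tibble(donor = DONOR_CLASSES, n = as.integer(counts),
                pct = pct1(as.integer(counts), genome_size))
  class(out) <- c("truc_rhizome", class(out))
  out
}

#' Fragment-level rhizome of one gene
#'
#' Composition of [fragment_protein()] and [classify_best_hits()]: cuts the
#' gene into sliding windows, classifies each fragment by its best passing
#' hit, and summarises donor counts. Alternating donors along the fragments
#' indicate intragenic sequence transfer (a chimeric gene).
#'
#' @param seq amino-acid sequence of the gene.
#' @param hits per-fragment hit tibble; `query` must hold the fragment id
#'   (an integer, as produced by [fragment_protein()]).
#' @inheritParams classify_best_hits
#' @inheritParams fragment_protein
#' @return List of class `truc_gene_rhizome`: `fragments` (fragment table
#'   with `donor` etc.), `summary` (donor counts over fragments).
#' @export
fragment_rhizome <- function(seq, hits, query_taxonomy,
                             exclusion_rank = c("family", "genus", "none"),
                             window = 40, step = 20, min_len = 20) {
  frags <- fragment_protein(seq, window = window, step = step,
                            min_len = min_len)
  hits$query <- as.character(hits$query)
  cls <- classify_best_hits(hits, query_taxonomy,
                            exclusion_rank = exclusion_rank,
                            units = as.character(frags$fragment))
  fragments <- left_join(frags,
                         cls |> mutate(fragment = as.integer(.data$unit)) |>
                           select(-"unit"),
                         by = "fragment")
  summary <- fragments |>
    count(donor = factor(.data$donor, levels = DONOR_CLASSES),
          .drop = FALSE, name = "n")
  structure(list(fragments = fragments, summary = summary),
            class = "truc_gene_rhizome")
}

#' @export
print.truc_gene_rhizome <- function(x, ...) {
  cat(sprintf("<truc_gene_rhizome> %d fragments\n", nrow(x$fragments)))
  print(x$summary, ...)
  invisible(x)
}

#' Write a Circos tableviewer ribbon matrix
#'
#' One row per genome, one column per donor class, cell = gene count; the
#' tab-separated layout the Circos tableviewer ingests for circular rhizome
#' figures.
#'
#' @param aggregates named list of [aggregate_rhizome()] tibbles, one per
#'   genome (names = genome labels).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_circos_table <- function(aggregates, path, seed = NULL) {
  if (inherits(aggregates, "truc_rhizome")) {
    aggregates <- list(genome = aggregates)
  }
  header <- paste(c("labels", DONOR_CLASSES), collapse = "\t")
  body <- vapply(names(aggregates), function(g) {
    agg <- aggregates[[g]]
    paste(c(g, agg$n[match(DONOR_CLASSES, agg$donor)]), collapse = "\t")
  }, character(1))
  write_lines_with_header(c(header, body), path, seed = seed,
                          extra = "circos_tableviewer")
}
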