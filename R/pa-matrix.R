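#' Presence/absence character matrix
#'
#' `pa_matrix()` builds the central container of the package: a binary
#' taxa-by-features matrix with a group label per taxon (one of `archaea`,
#' `bacteria`, `eukaryota`, `megavirales`) and, optionally, a relative
#' evolutionary age `nd` in `[0, 1]` per feature (0 = most ancient, 1 = most
#' recent). Rows are proteomes (taxa), columns are characters such as protein
#' fold superfamilies or informational COGs.
#'
#' @param cells binary matrix (0/1 or logical) with taxon rownames and feature
#'   colnames; row and column order is preserved throughout.
#' @param groups named character vector mapping every taxon to its group, or
#'   an unnamed vector aligned with `rownames(cells)`. `NA` is allowed only
#'   for operations that do not use group labels.
#' @param ages optional named numeric vector of feature ages `nd` in `[0, 1]`.
#' @return An object of class `truc_pa`.
#' @seealso [read_assignments()], [select_universal()],
#'   [filter_parsimony_informative()], [sharing_patterns()]
#' @export
pa_matrix <- function(cells, groups, ages = NULL) {
  cells <- as.matrix(cells)
  mode(cells) <- "integer"
  if ((is.null(rownames(cells)) && nrow(cells) > 0) ||
      (is.null(colnames(cells)) && ncol(cells) > 0)) {
    abort("`cells` needs taxon rownames and feature colnames")
  }
  if (anyDuplicated(rownames(cells))) abort("duplicate taxa in `cells`")
  if (anyDuplicated(colnames(cells))) abort("duplicate features in `cells`")
  if (!all(cells %in% c(0L, 1L))) abort("`cells` must be binary (0/1)")
  if (is.null(names(groups))) {
    if (length(groups) != nrow(cells)) {
      abort("`groups` length must match the number of taxa")
    }
    groups <- setNames(as.character(groups), rownames(cells))
  }
  groups <- groups[rownames(cells)]
  bad <- !is.na(groups) & !groups %in% TRUC_GROUPS
  if (any(bad)) {
    abort(paste0("unknown group label(s): ",
                 paste(unique(groups[bad]), collapse = ", ")))
  }
  if (!is.null(ages)) {
    miss <- setdiff(colnames(cells), names(ages))
    if (length(miss)) {
      abort(paste0("ages missing for features: ", paste(miss, collapse = ", ")))
    }
    ages <- ages[colnames(cells)]
    if (any(is.na(ages)) || any(ages < 0 | ages > 1)) {
      abort("all feature ages must lie in [0, 1]")
    }
  }
  structure(list(cells = cells, groups = groups, ages = ages),
            class = "truc_pa")
}

#' @export
print.truc_pa <- function(x, ...) {
  cat(sprintf("<truc_pa> %d taxa x %d features\n",
              nrow(x$cells), ncol(x$cells)))
  tab <- table(factor(x$groups, levels = TRUC_GROUPS))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  cat("  ages:", if (is.null(x$ages)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.truc_pa <- function(x) dim(x$cells)

#' Taxa, features and group labels of a presence/absence matrix
#' @param pa a [pa_matrix()] object.
#' @return Character vectors (`pa_taxa`, `pa_features`) or a named character
#'   vector of group labels (`pa_groups`).
#' @export
pa_taxa <- function(pa) rownames(pa$cells)

#' @rdname pa_taxa
#' @export
pa_features <- function(pa) colnames(pa$cells)

#' @rdname pa_taxa
#' @export
pa_groups <- function(pa) pa$groups

#' @export
as_tibble.truc_pa <- function(x, ...) {
  tibble(
    taxon = rep(rownames(x$cells), times = ncol(x$cells)),
    group = rep(unname(x$groups), times = ncol(x$cells)),
    feature = rep(colnames(x$cells), each = nrow(x$cells)),
    present = as.integer(x$cells)
  )
}

# Subset features, keeping taxa, groups and ages aligned.
pa_keep_features <- function(pa, keep) {
  pa_matrix(pa$cells[, keep, drop = FALSE], pa$groups,
            if (is.null(pa$ages)) NULL else pa$ages[colnames(pa$cells)[keep]])
}

require_groups <- function(pa) {
  if (any(is.na(pa$groups))) {
    abort("this operation needs a group label for every taxon")
  }
  missing <- setdiff(TRUC_GROUPS, unique(pa$groups))
  if (length(missing)) {
    abort(paste0("group(s) absent from the matrix: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(pa)
}

# I/O ------------------------------------------------------------------------

#' Read a two-column assignment table into a presence/absence matrix
#'
#' Ingests SUPERFAMILY- or COG-style assignment dumps: one row per detected
#' occurrence, tab-separated `proteome_id<TAB>feature_id`, `#` comments
#' allowed. Presence is occurrence (at least one assignment row); copy number
#' is ignored and duplicate rows collapse.
#'
#' @param path path to the TSV file.
#' @param group_map named character vector or two-column data frame
#'   (`proteome_id`, `group`) covering every proteome in the file.
#' @param ages optional named numeric vector of feature ages.
#' @return A [pa_matrix()] with taxa and features in first-appearance order.
#' @export
read_assignments <- function(path, group_map, ages = NULL) {
  df <- read_tsv_commented(path, c("proteome_id", "feature_id"))
  if (nrow(df) == 0) abort(paste0("no assignment rows in ", path))
  if (is.data.frame(group_map)) {
    group_map <- setNames(as.character(group_map[[2]]),
                          as.character(group_map[[1]]))
  }
  taxa <- unique(df$proteome_id)
  feats <- unique(df$feature_id)
  unknown <- setdiff(taxa, names(group_map))
  if (length(unknown)) {
    abort(paste0("proteome(s) missing from `group_map`: ",
                 paste(unknown, collapse = ", ")))
  }
  cells <- matrix(0L, length(taxa), length(feats),
                  dimnames = list(taxa, feats))
  cells[cbind(match(df$proteome_id, taxa), match(df$feature_id, feats))] <- 1L
  pa_matrix(cells, group_map[taxa], ages)
}

#' Write a presence/absence matrix as an assignment table
#'
#' One `proteome_id<TAB>feature_id` row per 1-cell, so
#' `read_assignments(write_assignments(pa, f), pa_groups(pa))` restores the
#' matrix (taxa or features with no occurrences cannot survive the round
#' trip; the long format has nowhere to record them).
#'
#' @inheritParams pa_taxa
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(pa, path, seed = NULL) {
  idx <- which(pa$cells == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  lines <- paste(rownames(pa$cells)[idx[, "row"]],
                 colnames(pa$cells)[idx[, "col"]], sep = "\t")
  write_lines_with_header(lines, path, seed = seed, extra = "assignments")
}

#' Write / read the matrix TSV interchange format
#'
#' Taxa as rows; first two columns `taxon` and `group`, then one 0/1 column
#' per feature. Feature ages, when present, are carried in `# age` comment
#' lines so that `read_pa_tsv(write_pa_tsv(pa, f))` is the identity.
#'
#' @inheritParams write_assignments
#' @return `write_pa_tsv()` returns `path` invisibly; `read_pa_tsv()` returns
#'   a [pa_matrix()].
#' @export
write_pa_tsv <- function(pa, path, seed = NULL) {
  header <- paste(c("taxon", "group", colnames(pa$cells)), collapse = "\t")
  body <- vapply(seq_len(nrow(pa$cells)), function(i) {
    paste(c(rownames(pa$cells)[i], pa$groups[i], pa$cells[i, ]),
          collapse = "\t")
  }, character(1))
  age_lines <- if (!is.null(pa$ages)) {
    sprintf("# age\t%s\t%.10g", names(pa$ages), pa$ages)
  }
  write_lines_with_header(c(age_lines, header, body), path, seed = seed,
                          extra = "pa_matrix")
}

#' @rdname write_pa_tsv
#' @param path path of a file written by `write_pa_tsv()`.
#' @export
read_pa_tsv <- function(path) {
  raw <- readLines(path)
  age_raw <- grep("^# age\t", raw, value = TRUE)
  ages <- NULL
  if (length(age_raw)) {
    parts <- strsplit(age_raw, "\t", fixed = TRUE)
    ages <- setNames(as.numeric(vapply(parts, `[`, "", 3)),
                     vapply(parts, `[`, "", 2))
  }
  body <- raw[!startsWith(raw, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  cells <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(cells) <- df$taxon
  groups <- setNames(df$group, df$taxon)
  groups[groups == "NA" | groups == ""] <- NA
  pa_matrix(cells, groups, ages)
}

#' Write / read a NEXUS character matrix (PAUP interchange)
#'
#' Emits a `DATA` block with `FORMAT DATATYPE=STANDARD SYMBOLS="01"
#' MISSING=?`; taxon labels containing spaces or NEXUS punctuation are
#' single-quoted. The reader parses this dialect back; group labels and ages
#' are not part of NEXUS and can be resupplied.
#'
#' @inheritParams write_assignments
#' @return `write_nexus()` returns `path` invisibly; `read_nexus_pa()` a
#'   [pa_matrix()].
#' @export
write_nexus <- function(pa, path, seed = NULL) {
  quote_label <- function(x) {
    needs <- grepl("[ \t(){}\\[\\]/\\\\,;:=*'\"`+<>-]", x, perl = TRUE)
    x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
    x
  }
  labs <- quote_label(rownames(pa$cells))
  pad <- max(nchar(labs))
  rows <- sprintf("    %-*s %s", pad, labs,
                  apply(pa$cells, 1, paste, collapse = ""))
  lines <- c("#NEXUS", "",
             "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     nrow(pa$cells), ncol(pa$cells)),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
             paste0("  CHARLABELS ",
                    paste(quote_label(colnames(pa$cells)), collapse = " "),
                    ";"),
             "  MATRIX",
             rows,
             "  ;",
             "END;")
  writeLines(c(lines[1], provenance_line(seed = seed, extra = "[nexus]"),
               lines[-1]), path)
  invisible(path)
}

#' @rdname write_nexus
#' @param path NEXUS file written by `write_nexus()`.
#' @param group_map optional group mapping as in [read_assignments()].
#' @param ages optional named age vector.
#' @export
read_nexus_pa <- function(path, group_map = NULL, ages = NULL) {
  raw <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", raw, ignore.case = TRUE)[1]
  if (is.na(i0)) abort("no MATRIX line found; not a NEXUS DATA block")
  i1 <- i0 + which(grepl("^\\s*;\\s*$", raw[-seq_len(i0)]))[1]
  body <- trimws(raw[(i0 + 1):(i1 - 1)])
  body <- body[nzchar(body)]
  parse_row <- function(line) {
    if (startsWith(line, "'")) {
      # single-quoted label; '' is an escaped quote
      m <- regexpr("^'((?:[^']|'')*)'", line, perl = TRUE)
      lab <- gsub("''", "'", substr(line, 2, attr(m, "match.length") - 1))
      states <- trimws(substr(line, attr(m, "match.length") + 1, nchar(line)))
    } else {
      sp <- regexpr("\\s", line)
      lab <- substr(line, 1, sp - 1)
      states <- trimws(substr(line, sp + 1, nchar(line)))
    }
    list(lab = lab, states = gsub("\\s", "", states))
  }
  rows <- lapply(body, parse_row)
  labs <- vapply(rows, `[[`, "", "lab")
  states <- vapply(rows, `[[`, "", "states")
  cells <- do.call(rbind, lapply(strsplit(states, ""), as.integer))
  rownames(cells) <- labs
  cl <- grep("^\\s*CHARLABELS\\b", raw, ignore.case = TRUE, value = TRUE)
  colnames(cells) <- if (length(cl) == 1) {
    toks <- regmatches(cl, gregexpr("'(?:[^']|'')*'|[^\\s;]+", cl, perl = TRUE))[[1]]
    toks <- toks[-1]                       # drop the CHARLABELS keyword
    toks <- sub(";$", "", toks)
    toks <- toks[nzchar(toks)]
    gsub("''", "'", sub("^'", "", sub("'$", "", toks)))
  } else {
    paste0("c", seq_len(ncol(cells)))
  }
  groups <- if (is.null(group_map)) {
    setNames(rep(NA_character_, length(labs)), labs)
  } else if (is.data.frame(group_map)) {
    setNames(as.character(group_map[[2]]), as.character(group_map[[1]]))[labs]
  } else {
    group_map[labs]
  }
  pa_matrix(cells, groups, ages)
}
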