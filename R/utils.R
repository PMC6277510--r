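# Round half away from zero, the convention used for all reported percentages
# (base round() is round-half-even and would turn 0.25 into 0.2).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of `count` in `total`, reported to one decimal.
pct1 <- function(count, total) round_half_up(100 * count / total, 1)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Provenance comment line prepended to every text output the package writes.
provenance_line <- function(seed = NULL, extra = NULL) {
  bits <- c(sprintf("trucphylo %s",
                    as.character(utils::packageVersion("trucphylo"))),
            if (!is.null(seed)) sprintf("seed=%s", seed),
            extra)
  paste0("# ", paste(bits, collapse = " "))
}

write_lines_with_header <- function(lines, path, seed = NULL, extra = NULL) {
  writeLines(c(provenance_line(seed = seed, extra = extra), lines), path)
  invisible(path)
}

# Read a tab-separated file, skipping '#'-prefixed comment lines.
read_tsv_commented <- function(path, col_names) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          sep = "\t", quote = "", stringsAsFactors = FALSE,
                          col.names = col_names,
                          check.names = FALSE, blank.lines.skip = TRUE)
  tibble::as_tibble(df)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}
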