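#' Heuristic maximum-parsimony tree search
#'
#' Infers most-parsimonious unrooted trees from a binary presence/absence
#' matrix by stepwise random addition followed by hill-climbing over NNI or
#' SPR rearrangements, with restarts. Identical columns are collapsed to
#' weighted patterns before scoring. All distinct topologies found at the
#' best length are returned; runs are deterministic for a fixed seed.
#'
#' @inheritParams tree_length
#' @param n_starts number of random-addition restarts.
#' @param rearrangement `"SPR"` (default, wider neighbourhood) or `"NNI"`.
#' @param seed integer seed driving the random addition orders.
#' @param max_ties cap on the number of tied topologies retained.
#' @return An object of class `truc_mp`: list with `length` (best parsimony
#'   length), `trees` (list of `phylo`, each with a `parsimony_length`
#'   attribute), `n_starts`, `rearrangement`.
#' @seealso [exhaustive_mp()] for the enumeration oracle on up to 8 taxa,
#'   [bootstrap_support()], [lundberg_root()].
#' @export
mp_search <- function(pa, n_starts = 10, rearrangement = c("SPR", "NNI"),
                      seed = 1, max_ties = 64) {
  rearrangement <- match.arg(rearrangement)
  cells <- as_pa_cells(pa)
  n <- nrow(cells)
  if (n < 4) abort("need at least 4 taxa for tree search")
  cw <- compress_columns(cells)
  best_len <- Inf
  found <- list()   # canon -> tr
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      ord <- sample.int(n)
      tr <- stepwise_addition(ord, cw$codes, cw$weights, n)
      res <- hill_climb(tr, cw$codes, cw$weights, rearrangement)
      if (res$length < best_len - 1e-9) {
        best_len <- res$length
        found <- list()
      }
      if (res$length <= best_len + 1e-9) {
        for (cand in res$trees) {
          key <- tr_canon(cand)
          if (is.null(found[[key]]) && length(found) < max_ties) {
            found[[key]] <- cand
          }
        }
      }
    }
  })
  taxa <- rownames(cells)
  trees <- lapply(unname(found), function(tr) {
    phy <- tr_to_phylo(tr, taxa)
    attr(phy, "parsimony_length") <- as.integer(best_len)
    phy
  })
  structure(list(length = as.integer(best_len), trees = trees,
                 n_starts = n_starts, rearrangement = rearrangement),
            class = "truc_mp")
}

#' @export
print.truc_mp <- function(x, ...) {
  cat(sprintf("<truc_mp> best length %d; %d tied topolog%s (%s, %d starts)\n",
              x$length, length(x$trees),
              if (length(x$trees) == 1) "y" else "ies",
              x$rearrangement, x$n_starts))
  invisible(x)
}

compress_columns <- function(cells) {
  pat <- apply(cells, 2, paste, collapse = "")
  u <- !duplicated(pat)
  list(codes = codes_from_cells(cells[, u, drop = FALSE]),
       weights = as.integer(table(factor(pat, levels = pat[u]))))
}

stepwise_addition <- function(ord, codes, weights, ntip_global) {
  tr <- tr_new(ord[1:3], ntip_global)
  for (t in ord[-(1:3)]) {
    best <- Inf; best_tr <- NULL
    for (i in seq_len(nrow(tr$edge))) {
      cand <- tr_attach(tr, i, t)
      len <- tr_fitch(cand, codes, weights)
      if (len < best) {
        best <- len
        best_tr <- cand
      }
    }
    tr <- best_tr
  }
  tr
}

hill_climb <- function(tr, codes, weights, rearrangement) {
  neighbors <- switch(rearrangement,
                      NNI = tr_nni_neighbors,
                      SPR = tr_spr_neighbors)
  cur_len <- tr_fitch(tr, codes, weights)
  ties <- list(tr)
  repeat {
    nb <- neighbors(tr)
    lens <- vapply(nb, tr_fitch, numeric(1), codes = codes, weights = weights)
    if (!length(lens) || min(lens) >= cur_len) {
      # local optimum: keep equally good neighbours as tied candidates
      if (length(lens)) ties <- c(ties, nb[lens == cur_len])
      break
    }
    j <- which.min(lens)
    tr <- nb[[j]]
    cur_len <- lens[j]
    ties <- list(tr)
  }
  list(trees = ties, length = cur_len)
}
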