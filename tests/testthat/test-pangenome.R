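four_genomes <- c("G1", "G2", "G3", "G4")

spec_row <- function(family, genomes, k = 1L, len = 150L, div = 0.2) {
  tibble::tibble(family = family, genomes = genomes, genes_per_genome = k,
                 length = len, divergence = div)
}

test_that("identical and unrelated sequences behave as expected under alignment", {
  withr::with_seed(50, {
    seq200 <- paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                             "M","F","P","S","T","W","Y","V"),
                           200, replace = TRUE), collapse = "")
    genes <- tibble::tibble(genome = c("G1", "G2"), gene = c("x", "y"),
                            seq = seq200)
    hits <- all_vs_all_homology(genes)
    expect_identical(nrow(hits), 2L)
    expect_equal(hits$identity, c(100, 100))
    expect_equal(hits$coverage_q, c(1, 1))
    expect_true(all(hits$evalue < 1e-3))
  })
  # empirical null: random 100-aa pairs never pass at e <= 1e-3
  withr::with_seed(52, {
    n_hits <- 0L
    for (i in 1:100) {
      g <- tibble::tibble(
        genome = c("G1", "G2"), gene = c("a", "b"),
        seq = replicate(2, paste(sample(c("A","R","N","D","C","Q","E","G",
                                          "H","I","L","K","M","F","P","S",
                                          "T","W","Y","V"),
                                        100, replace = TRUE),
                                 collapse = "")))
      n_hits <- n_hits + nrow(all_vs_all_homology(g))
    }
    expect_identical(n_hits, 0L)
  })
})

test_that("a family planted near 40% identity still passes the thresholds", {
  # members diverge independently from the ancestor, so pairwise identity is
  # about (1-p)^2 + p^2/19; p = 0.37 lands near 40%
  cfg <- sim_config(family_spec = spec_row("fam40", "G1;G2;G3", len = 200L,
                                           div = 0.37),
                    seed = 3)
  gen <- sim_genomes(cfg)
  hits <- all_vs_all_homology(gen$genes)
  fams <- build_families(hits, gen$genes)
  expect_identical(unique(fams$span), 3L)
  expect_identical(length(unique(fams$family)), 1L)
})

test_that("planted family spans are recovered exactly at permissive thresholds", {
  spec <- dplyr::bind_rows(
    spec_row("all4", "G1;G2;G3;G4"),
    spec_row("trio", "G1;G2;G3"),
    spec_row("duo", "G2;G4"),
    spec_row(paste0("solo", 1:4), four_genomes, k = 2L)
  )
  gen <- sim_genomes(sim_config(family_spec = spec, seed = 4))
  hits <- all_vs_all_homology(gen$genes)
  fams <- build_families(hits, gen$genes)
  truth_span <- gen$truth |> dplyr::distinct(gene, span)
  merged <- dplyr::left_join(fams, truth_span, by = "gene")
  expect_true(all(merged$span.x == merged$span.y))
  # zero shared families => empty core
  solo_gen <- sim_genomes(sim_config(
    family_spec = spec_row(paste0("u", 1:4), four_genomes, len = 100L),
    seed = 5))
  part <- partition_pangenome(build_families(
    all_vs_all_homology(solo_gen$genes), solo_gen$genes))
  expect_identical(part$global$core_families, 0L)
})

test_that("families are connected components of reciprocal hits only", {
  genes <- tibble::tibble(genome = c("G1", "G2", "G3", "G4"),
                          gene = c("a", "b", "c", "d"),
                          seq = strrep("ACDEFGHIKL", 10))
  hit <- function(q, s) tibble::tibble(
    query = q, subject = s, identity = 90, coverage_q = 1, coverage_s = 1,
    score = 500, evalue = 1e-30, taxonomy = NA_character_)
  # chain a<->b, b<->c merges {a,b,c}; c->d is one-directional: no edge
  hits <- dplyr::bind_rows(hit("a", "b"), hit("b", "a"),
                           hit("b", "c"), hit("c", "b"),
                           hit("c", "d"))
  fams <- build_families(hits, genes)
  expect_identical(fams$family[fams$gene == "a"],
                   fams$family[fams$gene == "c"])
  expect_false(fams$family[fams$gene == "d"] %in%
                 fams$family[fams$gene == "a"])
  expect_identical(sort(unique(fams$span)), c(1L, 3L))
  # no edges at all: every gene its own family
  solo <- build_families(hit("a", "b")[0, ], genes)
  expect_identical(length(unique(solo$family)), 4L)
  expect_error(build_families(hit("a", "zz"), genes), "unknown gene")
})

test_that("toy partition counts match the hand count", {
  fams <- tibble::tibble(
    family = c("a", "a", "a", "a", "b", "c"),
    gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
    genome = c("G1", "G2", "G3", "G4", "G1", "G3"))
  fams <- fams |>
    dplyr::group_by(family) |>
    dplyr::mutate(span = dplyr::n_distinct(genome)) |>
    dplyr::ungroup()
  part <- partition_pangenome(fams)
  expect_identical(part$global$core_families, 1L)
  expect_identical(part$global$pangenome_families, 3L)
  pg <- part$per_genome
  expect_identical(pg$n_unique[pg$genome == "G1"], 1L)
  expect_identical(pg$n_core[pg$genome == "G1"], 1L)
  # conservation: core + span3 + span2 + unique = total
  span2 <- vapply(pg$genome, function(g) {
    sum(fams$genome == g & fams$span == 2)
  }, integer(1))
  expect_true(all(pg$n_core + pg$n_span3 + span2 + pg$n_unique == pg$total))
})

test_that("percentage reporting rounds half away from zero at one decimal", {
  counts <- tibble::tibble(genome = c("x", "y"), total = c(400L, 1000L),
                           n_core = c(1L, 25L), n_span3 = c(2L, 5L),
                           n_shared_any = c(10L, 145L))
  out <- partition_percentages(counts)
  expect_equal(out$pct_core, c(0.3, 2.5))       # 0.25 -> 0.3, not 0.2
  expect_equal(out$pct_span3, c(0.5, 0.5))
  expect_equal(out$pct_shared_any, c(2.5, 14.5))
})

test_that("tabular hits parse and filter like BLAST outfmt 6", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# blast-style comment",
    paste("q1", "s1", "45.2", "120", "60", "3", "1", "120", "10", "129",
          "1e-20", "180", "Bacteria;Proteobacteria;Rickettsiaceae;Rickettsia",
          sep = "\t"),
    paste("q1", "s2", "15.0", "80", "60", "3", "1", "80", "5", "84",
          "0.5", "30", sep = "\t")), tmp)
  hits <- read_hits(tmp, query_lengths = c(q1 = 150))
  expect_identical(nrow(hits), 2L)
  expect_equal(hits$coverage_q[1], 120 / 150)
  expect_identical(hits$taxonomy[1],
                   "Bacteria;Proteobacteria;Rickettsiaceae;Rickettsia")
  kept <- filter_hits(hits)
  expect_identical(kept$subject, "s1")
})
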