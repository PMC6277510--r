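aa_seq <- function(len, seed = 1) {
  withr::with_seed(seed, paste(sample(LETTERS[c(1, 3:9, 11:14, 16:20, 22:23,
                                                25)],
                                      len, replace = TRUE), collapse = ""))
}

test_that("fragmentation follows the 40/20 sliding-window rule", {
  f100 <- fragment_protein(aa_seq(100))
  expect_identical(f100$start, c(0L, 20L, 40L, 60L, 80L))
  expect_identical(f100$end - f100$start, c(40L, 40L, 40L, 40L, 20L))
  f39 <- fragment_protein(aa_seq(39))
  expect_identical(nrow(f39), 1L)
  expect_identical(f39$end, 39L)
  expect_identical(nrow(fragment_protein("")), 0L)
  expect_error(fragment_protein(aa_seq(50), step = 0), "step")
  expect_error(fragment_protein(aa_seq(50), window = 10, step = 20), "step")
})

test_that("every residue is covered for all lengths 20-500 and boundaries depend only on length", {
  for (len in 20:500) {
    fr <- fragment_protein(strrep("A", len))
    covered <- logical(len)
    for (i in seq_len(nrow(fr))) {
      covered[(fr$start[i] + 1):fr$end[i]] <- TRUE
    }
    expect_true(all(covered))
    # count formula: starts at multiples of 20 with >= 20 residues remaining
    expect_identical(nrow(fr),
                     length(which(seq(0, len - 1, by = 20) <= len - 20)))
    expect_true(all(fr$end - fr$start <= 40))
    expect_true(all(fr$end <= len))
  }
})

test_that("best-hit classification honours scores, exclusion ranks and ties", {
  hit <- function(q, s, score, tax, id = 50) tibble::tibble(
    query = q, subject = s, identity = id, score = score, evalue = 1e-20,
    taxonomy = tax)
  qt <- "Viruses;Megavirales;Mimiviridae;Tupanvirus"
  euk <- "Eukaryota;Opisthokonta;Saccharomycetaceae;Saccharomyces"
  bac <- "Bacteria;Proteobacteria;Rickettsiaceae;Rickettsia"
  fam <- "Viruses;Megavirales;Mimiviridae;Mimivirus"

  one <- classify_best_hits(hit("g1", "s1", 100, euk), qt)
  expect_identical(as.character(one$donor), "eukaryota")

  both <- dplyr::bind_rows(hit("g1", "self", 300, fam),
                           hit("g1", "bact", 200, bac))
  excl <- classify_best_hits(both, qt, exclusion_rank = "family")
  expect_identical(as.character(excl$donor), "bacteria")
  none <- classify_best_hits(both, qt, exclusion_rank = "none")
  expect_identical(as.character(none$donor), "virus")

  orfan <- classify_best_hits(hit("g1", "s", 1, euk)[0, ], qt,
                              units = c("g1", "g2"))
  expect_identical(as.character(orfan$donor), c("ORFan", "ORFan"))

  # score tie: higher identity, then lexicographic subject id; flagged
  tied <- dplyr::bind_rows(hit("g1", "zz", 100, euk, id = 60),
                           hit("g1", "aa", 100, bac, id = 60))
  cl <- classify_best_hits(tied, qt)
  expect_identical(cl$best_subject, "aa")
  expect_identical(as.character(cl$donor), "bacteria")
  expect_true(cl$tie)

  expect_warning(
    classify_best_hits(hit("g1", "s1", 10, NA_character_), qt,
                       units = "g1"),
    "taxonomy")
})

test_that("classification is invariant to hit order", {
  sh <- sim_hit_table(sim_config(seed = 6), sprintf("g%03d", 1:50))
  fwd <- classify_best_hits(sh$hits, sh$query_taxonomy, units = sh$truth$gene)
  rev <- classify_best_hits(sh$hits[rev(seq_len(nrow(sh$hits))), ],
                            sh$query_taxonomy, units = sh$truth$gene)
  expect_identical(fwd$donor, rev$donor)
})

test_that("noise-free truth tables are recovered exactly, decoys notwithstanding", {
  genes <- sprintf("g%04d", 1:400)
  cfg <- sim_config(donor_props = c(virus = 0.5, eukaryota = 0.3,
                                    bacteria = 0.2),
                    decoy_self_hits = TRUE, seed = 12)
  sh <- sim_hit_table(cfg, genes)
  cl <- classify_best_hits(sh$hits, sh$query_taxonomy, units = genes)
  expect_identical(as.character(cl$donor), sh$truth$donor)
  agg <- aggregate_rhizome(cl, genome_size = length(genes))
  expect_identical(sum(agg$n), length(genes))
  # all-virus limit
  all_v <- sim_hit_table(sim_config(donor_props = c(virus = 1), seed = 2),
                         genes[1:50])
  agg_v <- aggregate_rhizome(
    classify_best_hits(all_v$hits, all_v$query_taxonomy, units = genes[1:50]))
  expect_equal(agg_v$pct[agg_v$donor == "virus"], 100)
  expect_equal(agg_v$n[agg_v$donor == "ORFan"], 0L)
})

test_that("below-threshold ORFan hits are removed by filtering, not classification", {
  cfg <- sim_config(donor_props = c(virus = 0.5), seed = 3,
                    orfan_mode = "below_threshold")
  sh <- sim_hit_table(cfg, sprintf("g%02d", 1:40))
  passing <- filter_hits(sh$hits)
  cl <- classify_best_hits(passing, sh$query_taxonomy,
                           units = sh$truth$gene)
  expect_identical(as.character(cl$donor), sh$truth$donor)
})

test_that("a planted chimera switches donors within one window of the junction", {
  seq <- aa_seq(400, seed = 9)
  junction <- 190
  ch <- sim_chimeric_hits(seq, junction, donor_n = "eukaryota",
                          donor_c = "virus")
  gr <- fragment_rhizome(seq, ch$hits, ch$query_taxonomy)
  donors <- as.character(gr$fragments$donor)
  switch_at <- which(donors != donors[1])[1]          # first C-donor fragment
  true_switch <- which(ch$truth$donor != ch$truth$donor[1])[1]
  expect_lte(abs(switch_at - true_switch), 1)
  expect_identical(sum(gr$summary$n), nrow(gr$fragments))
  # no hits at all: every fragment is an ORFan
  empty <- fragment_rhizome(seq, ch$hits[0, ], ch$query_taxonomy)
  expect_true(all(as.character(empty$fragments$donor) == "ORFan"))
})

test_that("the Circos tableviewer matrix lays genomes against donor classes", {
  cl <- classify_best_hits(
    tibble::tibble(query = "g1", subject = "s", identity = 50, score = 10,
                   evalue = 0, taxonomy = "Eukaryota;X;Yaceae;Z"),
    "Viruses;A;Bidae;C", units = c("g1", "g2"))
  agg <- aggregate_rhizome(cl)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_circos_table(list(gv = agg), tmp)
  lines <- readLines(tmp)
  expect_match(lines[2], "^labels\tvirus\teukaryota\tbacteria\tarchaea\tORFan$")
  expect_match(lines[3], "^gv\t0\t1\t0\t0\t1$")
})
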