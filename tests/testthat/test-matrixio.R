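test_that("assignment tables deduplicate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "t1\tf1", "t1\tf1", "t2\tf2"), tmp)
  gm <- c(t1 = "archaea", t2 = "bacteria")
  pa <- read_assignments(tmp, gm)
  expect_identical(dim(pa), c(2L, 2L))
  expect_identical(sum(pa$cells), 2L)
  expect_identical(pa$cells["t1", "f1"], 1L)
  expect_identical(pa$cells["t1", "f2"], 0L)

  m <- random_pa(10, 25, seed = 31, p = 0.6)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(m, out, seed = 31)
  back <- read_assignments(out, pa_groups(m))
  expect_identical(back$cells[pa_taxa(m), pa_features(m)], m$cells)

  expect_error(read_assignments(tmp, c(t1 = "archaea")), "t2")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_error(read_assignments(empty, gm), "no assignment rows")
})

test_that("matrix TSV and NEXUS writers round-trip, including ages and quoting", {
  ages <- withr::with_seed(2, runif(25))
  m <- random_pa(8, 25, seed = 32)
  m <- pa_matrix(m$cells, pa_groups(m), setNames(ages, pa_features(m)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pa_tsv(m, tsv)
  back <- read_pa_tsv(tsv)
  expect_identical(back$cells, m$cells)
  expect_identical(pa_groups(back), pa_groups(m))
  expect_equal(back$ages, m$ages, tolerance = 1e-9)

  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus(m, nex)
  back2 <- read_nexus_pa(nex, group_map = pa_groups(m), ages = m$ages)
  expect_identical(back2$cells, m$cells)

  # labels with spaces are single-quoted and survive the round trip
  cells <- matrix(c(1L, 0L, 0L, 1L), 2,
                  dimnames = list(c("taxon one", "t2"), c("f1", "f2")))
  pq <- pa_matrix(cells, c("archaea", "bacteria"))
  nex2 <- withr::local_tempfile(fileext = ".nex")
  write_nexus(pq, nex2)
  expect_true(any(grepl("'taxon one'", readLines(nex2))))
  back3 <- read_nexus_pa(nex2)
  expect_identical(back3$cells, cells)
})

test_that("the NEXUS dialect is readable by ape", {
  m <- random_pa(6, 12, seed = 33)
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus(m, nex)
  via_ape <- ape::read.nexus.data(nex)
  expect_identical(names(via_ape), pa_taxa(m))
  got <- do.call(rbind, lapply(via_ape, as.integer))
  expect_identical(unname(got), unname(m$cells))
})

test_that("universal selection matches the brute-force definition and is idempotent", {
  m <- random_pa(12, 50, seed = 34, p = 0.4)
  u <- select_universal(m)
  brute <- Filter(function(f) {
    all(vapply(TRUC_GROUPS, function(g) {
      any(m$cells[pa_groups(m) == g, f] == 1L)
    }, logical(1)))
  }, pa_features(m))
  expect_identical(pa_features(u), brute)
  expect_identical(pa_taxa(u), pa_taxa(m))
  expect_identical(select_universal(u)$cells, u$cells)

  # hand cases: present once per group kept; absent in all archaea dropped
  rows <- c(a = "11", b = "11", e = "11", v = "10")
  pa <- pa_from_strings(rows)
  pa$cells["a", "f1"] <- 1L
  expect_identical(pa_features(select_universal(pa)), "f1")
  no_arch <- pa_from_strings(c(a = "0", b = "1", e = "1", v = "1"))
  expect_identical(ncol(select_universal(no_arch)$cells), 0L)
  three_groups <- pa_matrix(matrix(1L, 3, 1, dimnames = list(c("a", "b", "e"), "f1")),
                            c("archaea", "bacteria", "eukaryota"))
  expect_error(select_universal(three_groups), "absent")
})

test_that("parsimony-informative filtering keeps exactly the 2-vs-2-capable characters", {
  rows <- c(t1 = "1101", t2 = "1001", t3 = "0011", t4 = "0000")
  pa <- pa_from_strings(rows)
  # f1: 2/2 split kept; f2: autapomorphy dropped; f3: constant-ish 0/4?
  keep <- pa_features(filter_parsimony_informative(pa))
  ones <- colSums(pa$cells)
  expect_identical(keep, pa_features(pa)[ones >= 2 & (4 - ones) >= 2])
  const <- pa_from_strings(c(t1 = "1", t2 = "1", t3 = "1", t4 = "1"))
  expect_identical(ncol(filter_parsimony_informative(const)$cells), 0L)
})

test_that("filters commute on the shared feature set", {
  m <- random_pa(12, 60, seed = 35, p = 0.35)
  ab <- filter_parsimony_informative(select_universal(m))
  ba <- select_universal(filter_parsimony_informative(m))
  expect_identical(ab$cells, ba$cells)
})

test_that("sharing patterns partition the features and match brute force", {
  m <- random_pa(12, 100, seed = 36, p = 0.3)
  m <- pa_matrix(m$cells[, colSums(m$cells) > 0], pa_groups(m))  # occurring features
  sp <- sharing_patterns(m)
  expect_identical(nrow(sp), 15L)
  expect_identical(sum(sp$n), ncol(m$cells))
  # brute force per feature
  codes <- c(archaea = "A", bacteria = "B", eukaryota = "E",
             megavirales = "V")
  brute <- vapply(pa_features(m), function(f) {
    paste(codes[TRUC_GROUPS][vapply(TRUC_GROUPS, function(g) {
      any(m$cells[pa_groups(m) == g, f] == 1L)
    }, logical(1))], collapse = "")
  }, character(1))
  for (p in sp$pattern) {
    expect_identical(sp$n[sp$pattern == p], sum(brute == p))
  }
  # a feature in all four groups lands in the ABEV cell
  allm <- pa_from_strings(c(a = "1", b = "1", e = "1", v = "1"))
  spa <- sharing_patterns(allm)
  expect_identical(spa$n[spa$pattern == "ABEV"], 1L)
  expect_identical(sum(spa$n), 1L)
})
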