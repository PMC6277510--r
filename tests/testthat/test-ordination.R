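test_that("age weighting hits the formula endpoints and hand distances", {
  pa <- pa_from_strings(c(t1 = "11", t2 = "10"),
                        ages = c(0.2, 0.8))
  w <- age_weight(pa)
  expect_equal(w["t1", "f1"], 0.8)       # shared ancient feature
  expect_equal(w["t2", "f2"], 0)         # absent -> 0
  expect_equal(unname(as.matrix(dist(w))["t1", "t2"]), 1 - 0.8)
  ends <- pa_from_strings(c(t1 = "11", t2 = "11"), ages = c(0, 1))
  we <- age_weight(ends)
  expect_equal(unname(we[, "f1"]), c(1, 1))   # nd = 0: full weight
  expect_equal(unname(we[, "f2"]), c(0, 0))   # nd = 1: aged out
  no_ages <- pa_from_strings(c(t1 = "1", t2 = "0"))
  expect_error(age_weight(no_ages), "ages")
})

test_that("classical PCoA embeds a 3-4-5 triangle exactly and validates input", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  res <- classical_pcoa(d, k = 2)
  emb <- as.matrix(res$points[, c("axis_1", "axis_2")])
  rownames(emb) <- res$points$taxon
  expect_equal(as.matrix(dist(emb))[c("p", "q", "r"), c("p", "q", "r")],
               d, tolerance = 1e-10, ignore_attr = TRUE)
  bad <- d; bad[1, 2] <- 99
  expect_error(classical_pcoa(bad), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(classical_pcoa(neg), "negative")
})

test_that("Euclidean input is reconstructed within 1e-8 and eigenvalues are near-PSD", {
  sim <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                        n_characters = 80, seed = 14))
  w <- age_weight(sim$pa)
  d <- dist(w)
  res <- classical_pcoa(d, k = 3, groups = pa_groups(sim$pa))
  rec <- dist(res$all_positive_points)
  denom <- max(as.matrix(d))
  expect_lt(max(abs(as.matrix(rec) - as.matrix(d))) / denom, 1e-8)
  expect_true(all(res$eig >= -1e-9 * max(res$eig)))
  # identical taxa land on coincident points
  cells <- sim$pa$cells
  cells[2, ] <- cells[1, ]
  dup <- pa_matrix(cells, pa_groups(sim$pa), sim$pa$ages)
  rd <- evo_pcoa(dup)
  pts <- as.matrix(rd$points[, c("axis_1", "axis_2", "axis_3")])
  expect_equal(pts[1, ], pts[2, ], tolerance = 1e-8)
})

test_that("the ordination is invariant to taxon order and reduces to raw PCoA at nd = 0", {
  sim <- sim_presence_matrix(sim_config(n_taxa_per_group = 3,
                                        n_characters = 60, seed = 15))
  pa <- sim$pa
  perm <- withr::with_seed(4, sample(nrow(pa$cells)))
  pa_perm <- pa_matrix(pa$cells[perm, ], pa_groups(pa)[perm], pa$ages)
  r1 <- evo_pcoa(pa); r2 <- evo_pcoa(pa_perm)
  p1 <- r1$points[order(r1$points$taxon), ]
  p2 <- r2$points[order(r2$points$taxon), ]
  for (ax in c("axis_1", "axis_2", "axis_3")) {
    expect_true(isTRUE(all.equal(p1[[ax]], p2[[ax]], tolerance = 1e-6)) ||
                  isTRUE(all.equal(p1[[ax]], -p2[[ax]], tolerance = 1e-6)))
  }
  flat <- pa_matrix(pa$cells, pa_groups(pa),
                    setNames(rep(0, ncol(pa$cells)), pa_features(pa)))
  expect_equal(as.matrix(dist(age_weight(flat))),
               as.matrix(dist(pa$cells)), tolerance = 1e-12)
})

test_that("group separation scores behave at the constructed extremes", {
  withr::with_seed(6, {
    centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
    pts <- do.call(rbind, lapply(1:4, function(g) {
      sweep(matrix(rnorm(15, sd = 0.5), 5, 3), 2, centers[g, ], `+`)
    }))
  })
  taxa <- sprintf("t%02d", 1:20)
  groups <- setNames(rep(TRUC_GROUPS, each = 5), taxa)
  res <- structure(list(points = dplyr::bind_cols(
    tibble::tibble(taxon = taxa, group = unname(groups)),
    tibble::as_tibble(`colnames<-`(pts, paste0("axis_", 1:3)))),
    k = 3), class = "truc_pcoa")
  sep <- group_separation(res)
  expect_identical(nrow(sep), 4L)
  expect_true(all(sep$score > 0.5))
  # collapse one group onto another's coordinates: its score drops to <= 0
  pts2 <- pts; pts2[16:20, ] <- pts[1:5, ]
  res2 <- res
  res2$points[paste0("axis_", 1:3)] <- tibble::as_tibble(
    `colnames<-`(pts2, paste0("axis_", 1:3)))
  sep2 <- group_separation(res2)
  expect_lte(sep2$score[sep2$group == "megavirales"], 0)
})
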