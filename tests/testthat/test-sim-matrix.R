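test_that("generators are byte-reproducible for a fixed seed", {
  a <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                      n_characters = 40, seed = 7))
  b <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                      n_characters = 40, seed = 7))
  expect_identical(a$pa$cells, b$pa$cells)
  expect_identical(a$pa$ages, b$pa$ages)
  expect_identical(a$truth, b$truth)
  c <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                      n_characters = 40, seed = 8))
  expect_false(identical(a$pa$cells, c$pa$cells))
})

test_that("the no-change limit gives an all-present matrix with zero tree length", {
  sim <- sim_presence_matrix(sim_config(n_taxa_per_group = 3,
                                        n_characters = 20, gain_rate = 0,
                                        loss_rate = 0, origin = "root",
                                        seed = 1))
  expect_true(all(sim$pa$cells == 1L))
  expect_identical(tree_length(sim$tree, sim$pa), 0L)
})

test_that("single-gain characters fit the truth tree perfectly", {
  sim <- sim_presence_matrix(sim_config(n_taxa_per_group = 5,
                                        n_characters = 120, gain_rate = 0,
                                        loss_rate = 0, age_noise = 0,
                                        seed = 5))
  fit <- character_fit(sim$tree, sim$pa)
  informative <- fit$g > fit$m & fit$m == 1L
  expect_true(all(fit$s == fit$m | fit$s == 0))
  expect_true(all(fit$ci[informative] == 1))
  # Fitch oracle agrees character by character
  for (f in pa_features(sim$pa)[1:10]) {
    expect_identical(fitch_steps(sim$tree,
                                 setNames(sim$pa$cells[, f],
                                          pa_taxa(sim$pa))),
                     sankoff_steps(sim$tree,
                                   setNames(sim$pa$cells[, f],
                                            pa_taxa(sim$pa))))
  }
})

test_that("ages are monotone in gain-node depth without jitter, clipped with it", {
  sim <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                        n_characters = 60, age_noise = 0,
                                        seed = 9))
  expect_true(all(sim$truth$nd == sim$truth$nd_true))
  o <- order(sim$truth$origin_depth)
  expect_false(is.unsorted(sim$truth$nd[o]))
  noisy <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                          n_characters = 60,
                                          age_noise = 0.4, seed = 9))
  expect_true(all(noisy$pa$ages >= 0 & noisy$pa$ages <= 1))
})

test_that("the truth tree carries the four groups as clades and bad configs error", {
  sim <- sim_presence_matrix(sim_config(n_taxa_per_group = 4,
                                        n_characters = 10, seed = 2))
  gm <- groups_monophyletic(sim$tree, pa_groups(sim$pa))
  expect_true(all(gm$monophyletic))
  expect_error(sim_config(gain_rate = 1.5), "probability")
  expect_error(sim_config(n_taxa_per_group = 1), "at least 2")
  expect_error(sim_config(n_characters = 0), "at least 1")
  expect_error(sim_config(donor_props = c(virus = 0.8, bacteria = 0.5)),
               "sum")
})
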