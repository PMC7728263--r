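test_that("genotype likelihood picks the best clone per cell", {
  tr <- mutation_tree(c(0L, 1L)) # profiles: {}, {M1}, {M1, M2}
  gm <- genotype_matrix(matrix(c(1L, 0L), 1), alpha = 0.1, beta = 0.01)
  # best attachment is clone 1 ({M1}): log(1-alpha) + log(1-beta)
  expect_equal(genotype_log_lik(tr, gm), log(0.9) + log(0.99), tolerance = 1e-12)
  # missing entries are skipped
  gm3 <- genotype_matrix(matrix(c(1L, 3L), 1), alpha = 0.1, beta = 0.01)
  expect_equal(genotype_log_lik(tr, gm3), log(0.9), tolerance = 1e-12)
})

test_that("near-noiseless sampling concentrates on the generating tree", {
  truth <- simulate_tumor(m = 4, seed = 13)
  gm <- add_noise(truth, alpha = 0.02, beta = 1e-3, copies = 12, seed = 14)
  # comparisons happen in mutation-label space: the sampler's node j is
  # mutation Mj, while the simulator permutes labels over nodes
  expected <- paste(label_space_parent(truth$tree), collapse = " ")
  # exhaustive oracle: the generating topology maximizes the genotype
  # likelihood over all rooted trees on 4 mutations
  trees <- all_parent_vectors(4)
  lls <- vapply(trees, genotype_log_lik, numeric(1), gm = gm)
  best <- trees[[which.max(lls)]]
  expect_equal(paste(best$parent[-1], collapse = " "), expected)
  # the chain's modal sample matches that maximum-likelihood topology
  samp <- sample_trees(gm, n_samples = 60, burn_in = 300, thin = 5, seed = 15)
  keys <- vapply(samp, function(t) paste(t$parent[-1], collapse = " "),
                 character(1))
  modal <- names(which.max(table(keys)))
  expect_equal(modal, expected)
})

test_that("impossible cells under a noise-free model raise an error", {
  tr <- mutation_tree(c(0L, 1L))
  # profile containing M2 but not M1 exists under no attachment
  gm <- genotype_matrix(matrix(c(0L, 1L), 1), alpha = 0, beta = 0)
  expect_error(genotype_log_lik(tr, gm), "degenerate data")
  expect_error(sample_trees(genotype_matrix(matrix(3L, 1, 1)), 1), "degenerate data")
})

test_that("tree sampling is deterministic under a fixed seed", {
  truth <- simulate_tumor(m = 5, seed = 17)
  gm <- add_noise(truth, alpha = 0.1, beta = 1e-3, copies = 3, seed = 18)
  s1 <- sample_trees(gm, n_samples = 8, burn_in = 40, seed = 19)
  s2 <- sample_trees(gm, n_samples = 8, burn_in = 40, seed = 19)
  expect_identical(lapply(s1, `[[`, "parent"), lapply(s2, `[[`, "parent"))
})

test_that("pooled posteriors reduce to the two-sample formulas", {
  # identical trees: zero spread for every label
  tr <- read_mutation_tree("0 1 1 2 2")
  post <- rate_posterior(list(tr, tr), 0.5, 2, theta0 = 1)
  expect_true(all(post$se == 0))
  expect_true(all(post$n == 2))
  # two topologies: mean and population spread of the two fitted rates
  tr2 <- read_mutation_tree("0 1 2 2 3")
  f1 <- infer_rates(tr, 0.5, 2, theta0 = 1)
  f2 <- infer_rates(tr2, 0.5, 2, theta0 = 1)
  post2 <- rate_posterior(list(tr, tr2), 0.5, 2, theta0 = 1)
  r1 <- f1$theta[2]; r2 <- f2$theta[2] # label M1 is internal in both
  row <- post2[post2$label == "M1", ]
  expect_equal(row$mean, (r1 + r2) / 2, tolerance = 1e-9)
  expect_equal(row$se, abs(r1 - r2) / 2, tolerance = 1e-9)
  expect_s3_class(autoplot(post2), "ggplot")
})

test_that("externally supplied tree directories are accepted", {
  tmp <- withr::local_tempdir()
  writeLines("0 1 1 2 2", file.path(tmp, "a.txt"))
  tr <- read_mutation_tree("0 1 1 2 2")
  write_mutation_tree(tr, file.path(tmp, "b.dot"), dialect = "dot")
  post <- rate_posterior(tmp, 0.5, 2, theta0 = 1)
  expect_true(all(post$n == 2)) # both files parsed to the same tree
  expect_true(all(post$se == 0))
  expect_error(rate_posterior(withr::local_tempdir(), 0.5, 2), "no tree files")
})

test_that("per-label spread shrinks as cells accumulate", {
  # a wide rate box keeps the per-tree rate fits off the band boundary so
  # topology uncertainty is visible in the pooled rates
  truth <- simulate_tumor(m = 5, seed = 23)
  spread <- vapply(c(1L, 4L, 16L), function(copies) {
    gm <- add_noise(truth, alpha = 0.15, beta = 1e-3, copies = copies, seed = 24)
    trees <- sample_trees(gm, n_samples = 15, burn_in = 300, thin = 10, seed = 25)
    post <- rate_posterior(trees, 0.001, 0.05)
    mean(post$se)
  }, numeric(1))
  expect_lt(spread[3], spread[1])
  expect_lte(spread[2], spread[1])
})
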