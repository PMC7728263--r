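test_that("branch log-probabilities match the model densities", {
  expect_equal(edge_log_prob("internal", 1, 1), -1)
  expect_equal(edge_log_prob("leaf", 2, 0), log(2))
  expect_equal(edge_log_prob("internal", 1, 0.5), 2 * log(1) + log(0.5) - 0.5)
  expect_equal(edge_log_prob("internal", 1, 0), -Inf) # degenerate interval
  expect_error(edge_log_prob("internal", -1, 1))
})

test_that("the worked single-edge log-likelihood is reproduced", {
  tr <- mutation_tree(0L)
  expect_equal(tree_log_lik(tr, c(1, 1), c(0, 0.5), 1),
               0.5 + log(0.5) - 2, tolerance = 1e-12)
})

test_that("ordering violations yield -Inf", {
  tr <- mutation_tree(c(0L, 0L))
  sig <- list(c(2L, 1L), integer(0), integer(0))
  expect_warning(
    v <- tree_log_lik(tr, c(1, 1, 1), c(0, 0.2, 0.6), 1, sig),
    "ordering violated"
  )
  expect_identical(v, -Inf)
})

test_that("sum-form equals the branch-product form on random instances", {
  # the closed log-likelihood is algebraically the log of the product of
  # Erlang-2 / exponential branch densities of the binary phylogeny
  set.seed(41)
  for (i in 1:200) {
    tr <- random_tree(sample(3:10, 1))
    n <- n_mutations(tr)
    th <- c(runif(1, 0.5, 2), runif(n, 0.5, 2))
    t <- random_valid_times(tr)
    H <- 1 + runif(1)
    edges <- phylogeny_edges(tr, th, t, H)
    direct <- sum(mapply(edge_log_prob, edges$kind, edges$rate, edges$elapsed))
    expect_equal(tree_log_lik(tr, th, t, H), direct, tolerance = 1e-9)
  }
})

test_that("scaled-coordinate form reproduces the log-likelihood", {
  # substituting u = t/H gives H*sum(theta_i u_i) + sum(log scaled gaps)
  # - H*sum(theta) + n*log(H) + sum((2d+1) log theta)
  set.seed(43)
  for (i in 1:20) {
    tr <- random_tree(sample(3:8, 1))
    n <- n_mutations(tr)
    th <- c(1, runif(n, 0.5, 2))
    H <- 2 + runif(1)
    t <- random_valid_times(tr, horizon = H)
    u <- t / H
    gaps_u <- unlist(clonerate:::sibling_gaps(tr, u, default_orderings(tr)))
    scaled <- H * sum(th * u) + sum(log(gaps_u)) - H * sum(th) +
      n * log(H) + sum((2 * tr$outdegree + 1) * log(th))
    expect_equal(tree_log_lik(tr, th, t, H), scaled, tolerance = 1e-9)
  }
})

test_that("star stationarity solves in closed form for d = 1 and d = 2", {
  # d = 1: mu = 1 + H*theta, t = 1
  s1 <- star_optimal_times(0.7, 3)
  expect_equal(s1$mu, 1 + 3 * 0.7, tolerance = 1e-10)
  expect_equal(s1$times, 1)
  # d = 2, theta = (1, 2), H = 10: mu^2 - 52 mu + 650 = 0, root above 30
  s2 <- star_optimal_times(c(1, 2), 10)
  expect_equal(s2$mu, (52 + sqrt(52^2 - 4 * 650)) / 2, tolerance = 1e-9)
  expect_equal(s2$times, c(1 / (s2$mu - 30), 1), tolerance = 1e-9)
  expect_equal(s2$times[1], 0.909902, tolerance = 1e-6)
})

test_that("star solution satisfies its stationarity system on random stars", {
  set.seed(47)
  for (i in 1:50) {
    d <- sample(1:6, 1)
    th <- runif(d, 0.1, 3)
    H <- runif(1, 1, 50)
    s <- star_optimal_times(th, H)
    S <- rev(cumsum(rev(H * th)))
    expect_equal(sum(1 / (s$mu - S)), 1, tolerance = 1e-9)
    expect_equal(s$times[d], 1, tolerance = 1e-12)
    expect_equal(diff(c(0, s$times)), 1 / (s$mu - S), tolerance = 1e-9)
    expect_gt(s$mu, H * sum(th))
  }
})

test_that("star dual gap mu - H*sum(theta) approaches 1 for large horizons", {
  th <- c(0.4, 1.1, 2.3)
  eps <- vapply(c(1e2, 1e3, 1e4), function(H) {
    star_optimal_times(th, H)$mu - H * sum(th)
  }, numeric(1))
  expect_true(all(diff(abs(eps - 1)) < 0)) # monotone approach
  expect_equal(eps[3], 1, tolerance = 1e-3)
})

test_that("star partial likelihood grows like a*H - b*log(H) + const", {
  # linear coefficient a = sum of child rates; log coefficient b = d - 1
  # (the gap term for the dual constraint contributes log(1) = 0); the
  # residual converges to a constant as the horizon grows
  set.seed(59)
  th <- runif(4, 0.3, 2)
  Hs <- 10^(2:5)
  resid <- vapply(Hs, function(H) {
    star_optimal_times(sort(th), H)$value - (sum(th) * H - 3 * log(H))
  }, numeric(1))
  steps <- abs(diff(resid))
  expect_true(all(diff(steps) < 0)) # shrinking corrections
  expect_lt(steps[3], 1e-3)
})

test_that("star value matches a direct numeric maximization", {
  set.seed(53)
  for (i in 1:10) {
    d <- sample(2:4, 1)
    th <- runif(d, 0.2, 2)
    H <- runif(1, 2, 20)
    s <- star_optimal_times(th, H)
    # independent oracle: optimize over increments with the simplex bound
    obj <- function(z) { # z = log increments, t_d constrained to 1
      inc <- exp(z); inc <- inc / sum(inc)
      t <- cumsum(inc)
      -(H * sum(th * t) + sum(log(inc)))
    }
    o <- optim(rep(0, d), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    expect_equal(s$value, -o$value, tolerance = 1e-6)
  }
})

test_that("ascending rates is the optimal star birth order", {
  expect_equal(optimal_star_ordering(c(0.3, 0.1, 0.2)), c(2L, 3L, 1L))
  expect_equal(optimal_star_ordering(c(1, 1, 1)), c(1L, 2L, 3L)) # stable ties
  expect_equal(optimal_star_ordering(5), 1L)
  # with child ids
  expect_equal(optimal_star_ordering(c(0.3, 0.1, 0.2), children = 4:6),
               c(5L, 6L, 4L))
})

test_that("orderings derived from times sort siblings by birth time", {
  tr <- mutation_tree(c(0L, 0L, 0L))
  t <- c(0, 0.5, 0.2, 0.9)
  expect_equal(orderings_from_times(tr, t)[[1]], c(2L, 1L, 3L))
})
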