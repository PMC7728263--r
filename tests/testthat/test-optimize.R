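test_that("fixed-horizon star solves match the analytic stationary solution", {
  set.seed(61)
  for (i in 1:10) {
    d <- sample(2:5, 1)
    th0 <- runif(1, 0.2, 2)
    th <- runif(d, 0.2, 2)
    H <- runif(1, 2, 20)
    star <- mutation_tree(rep(0L, d))
    fit <- optimize_times(star, c(th0, th), horizon = H)
    kkt <- star_optimal_times(th, H)
    expect_equal(fit$times[-1] / H, kkt$times, tolerance = 1e-6)
  }
})

test_that("free-horizon star solve matches a nested 1-D oracle", {
  th0 <- 0.5; th <- c(1, 2)
  star <- mutation_tree(c(0L, 0L))
  fit <- optimize_times(star, c(th0, th))
  # oracle: profile out the scaled times with the stationary form, then
  # maximize the 1-D profile over H
  prof <- function(H) {
    star_optimal_times(th, H)$value + 2 * log(H) - sum(c(th0, th)) * H
  }
  o <- optimize(prof, c(0.01, 50), maximum = TRUE, tol = 1e-10)
  expect_equal(fit$horizon, o$maximum, tolerance = 1e-5)
  expect_equal(fit$partial, o$objective, tolerance = 1e-8)
})

test_that("two-node chain at unit horizon lands on the golden ratio", {
  # maximize t1 + t2 + log(t1) + log(t2 - t1) with t2 <= 1: t2 = 1 and
  # t1^2 + t1 - 1 = 0
  ch <- mutation_tree(c(0L, 1L))
  fit <- optimize_times(ch, c(1, 1, 1), horizon = 1)
  expect_equal(fit$times[2], (sqrt(5) - 1) / 2, tolerance = 1e-7)
  expect_equal(fit$times[3], 1, tolerance = 1e-9)
})

test_that("root-only trees take the degenerate closed form", {
  tr <- mutation_tree(integer(0))
  fit <- optimize_times(tr, theta = 2)
  expect_equal(fit$horizon, 0)
  expect_equal(fit$loglik, log(2))
  fit5 <- optimize_times(tr, theta = 2, horizon = 5)
  expect_equal(fit5$loglik, log(2) - 10)
})

test_that("infeasible fixed horizons raise the documented error", {
  # lower band needs H - t_1 >= 2/theta_max = 20, impossible at H = 5
  tr <- mutation_tree(c(0L, 1L, 1L))
  expect_error(
    optimize_times(tr, rep(0.1, 4), theta_min = 0.01, theta_max = 0.1,
                   horizon = 5),
    "no feasible timing"
  )
})

test_that("solutions dominate random feasible perturbations", {
  set.seed(67)
  for (i in 1:5) {
    tr <- random_tree(sample(8:20, 1))
    n <- n_mutations(tr)
    th <- c(0.8, runif(n, 0.5, 2))
    # lower-band mode so the feasibility check below matches the solver's set
    fit <- optimize_times(tr, th, theta_min = 0.5, theta_max = 2,
                          bands = "lower")
    best <- -Inf
    d <- tr$outdegree
    internal <- which(d[-1] >= 1)
    for (k in 1:200) {
      t2 <- fit$times + c(0, runif(n, -1, 1) * 0.1)
      H2 <- fit$horizon + runif(1, -1, 1) * 0.1
      if (any(H2 - t2[internal + 1] < d[internal + 1] / 2)) next
      if (any(H2 < t2)) next
      lv <- suppressWarnings(tree_log_lik(tr, th, t2, H2))
      if (is.finite(lv)) best <- max(best, lv)
    }
    expect_lte(best, fit$loglik + 1e-8)
  }
})

test_that("timing bands hold at the solution", {
  set.seed(71)
  tr <- random_tree(15)
  th <- c(0.0075, runif(15, 0.005, 0.01))
  fit <- optimize_times(tr, th, theta_min = 0.005, theta_max = 0.01)
  d <- tr$outdegree
  internal <- which(d[-1] >= 1)
  expo <- fit$horizon - fit$times[internal + 1]
  expect_true(all(expo >= d[internal + 1] / 0.01 - 1e-7)) # lower band
  expect_true(all(fit$times[-1] >= -1e-9))
  expect_true(all(fit$times[-1] <= fit$horizon + 1e-9))
  # reported log-likelihood is consistent with the returned configuration
  expect_equal(fit$loglik,
               tree_log_lik(tr, th, fit$times, fit$horizon),
               tolerance = 1e-9)
})

test_that("upper bands cap exposures where the tree allows it", {
  # chain of three internal nodes, outdegree 1 each: band is [1/tmax, 1/tmin]
  tr <- mutation_tree(c(0L, 1L, 2L, 3L))
  th <- rep(0.1, 5)
  fit <- optimize_times(tr, th, theta_min = 0.05, theta_max = 0.2,
                        bands = "both")
  internal <- 1:3
  expo <- fit$horizon - fit$times[internal + 1]
  expect_true(all(expo <= 1 / 0.05 * 1.05 + 1e-6))
  expect_true(all(expo >= 1 / 0.2 - 1e-7))
})
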