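# Restricted mutability landscapes: the rate changes in at most s vertices of
# the tree ("s-model").  A state is a set X of s internal non-root vertices
# (the change events) together with one free rate per component of T \ X; the
# component containing the root keeps the fixed normal rate.  The profile
# likelihood of a state maximizes over times, horizon and orderings.

#' Component assignment for a change set
#'
#' Every node takes the rate of its nearest ancestor-or-self in `X`
#' (component ids `1..s` in the order of `sort(X)`), or component 0 (the
#' normal rate) when no change event lies on its root path.
#'
#' @param tree a `mutation_tree`
#' @param X integer vector of change vertices (internal, non-root)
#' @return integer vector of component ids indexed by node id + 1
#' @export
rate_components <- function(tree, X) {
  X <- sort(as.integer(X))
  n <- n_mutations(tree)
  comp <- integer(n + 1L)
  for (v in subtree_nodes(tree, 0L)) {
    if (v == 0L) next
    comp[v + 1L] <- if (v %in% X) match(v, X) else comp[tree$parent[v + 1L] + 1L]
  }
  comp
}

smodel_profile <- function(tree, comp, rates, control) {
  theta <- rates[comp + 1L]
  fit <- best_orderings(tree, theta, bands = "none", control = control)
  fit$loglik
}

#' Fit the s-model by Metropolis search
#'
#' Searches jointly over change sets `X` (1-flip neighborhood moves
#' `X' = (X \ u) + v`) and component rates (Gaussian random-walk proposals
#' reflected into `[theta_min, theta_max]`), scoring each state by its
#' profile log-likelihood; the best state visited is returned with its free
#' rates polished by coordinate-wise 1-D maximization.  For `s = 0` there is
#' a single free rate shared by all clones and the fit reduces to a
#' deterministic 1-D maximization.
#'
#' @param tree a `mutation_tree`
#' @param s maximal number of rate-change vertices
#' @param theta_min,theta_max feasible rate box for the free rates
#' @param theta_normal the normal-tissue rate assigned to the root component
#'   when `s >= 1`
#' @param normal_fixed keep the root-component rate pinned at `theta_normal`
#'   (the default); with `FALSE` it is searched over the box like the other
#'   component rates, which makes the `s = 1` model nest the flat `s = 0`
#'   model
#' @param n_iter Metropolis iterations
#' @param step random-walk standard deviation (defaults to a quarter of the
#'   box width)
#' @param seed RNG seed
#' @param control ordering-search control for the inner solves
#' @return an object of class `smodel_fit`: `X`, `rates` (component rates,
#'   entry 1 is the normal/shared rate), `comp` (per-node component ids),
#'   `theta` (per-node rates), `loglik`, `s`
#' @examples
#' \donttest{
#' tr <- read_mutation_tree("0 1 1 2 2", dialect = "parent_vector")
#' fit0 <- fit_s_model(tr, s = 0, theta_min = 0.5, theta_max = 2)
#' }
#' @export
fit_s_model <- function(tree, s, theta_min, theta_max,
                        theta_normal = (theta_min + theta_max) / 2,
                        normal_fixed = TRUE,
                        n_iter = 200L, step = NULL, seed = 0L,
                        control = list()) {
  stopifnot(s >= 0, theta_min > 0, theta_min < theta_max)
  d <- tree$outdegree
  eligible <- which(d[-1L] >= 1L) # internal non-root node ids
  if (s > length(eligible)) stop("infeasible s")
  if (is.null(step)) step <- (theta_max - theta_min) / 4

  if (s == 0L) {
    comp <- integer(n_mutations(tree) + 1L)
    prof <- function(r) smodel_profile(tree, comp, r, control)
    opt <- stats::optimize(prof, c(theta_min, theta_max), maximum = TRUE,
                           tol = 1e-8 * (theta_max - theta_min))
    return(new_smodel_fit(tree, integer(0), opt$maximum, comp,
                          opt$objective, 0L))
  }

  withr_seed(seed, {
    X <- sort(sample(eligible, s))
    rates <- c(theta_normal, stats::runif(s, theta_min, theta_max))
    comp <- rate_components(tree, X)
    cur <- smodel_profile(tree, comp, rates, control)
    best <- list(X = X, rates = rates, comp = comp, loglik = cur)
    for (it in seq_len(n_iter)) {
      if (s < length(eligible) && stats::runif(1) < 0.5) {
        # 1-flip move on the change set
        u <- if (length(X) == 1L) X else sample(X, 1L)
        v <- sample(setdiff(eligible, X), 1L)
        X_new <- sort(c(setdiff(X, u), v))
        comp_new <- rate_components(tree, X_new)
        rates_new <- rates
      } else {
        # rate move on one free component
        j <- if (normal_fixed) 1L + sample.int(s, 1L) else sample.int(s + 1L, 1L)
        r <- rates[j] + stats::rnorm(1, 0, step)
        r <- reflect_into(r, theta_min, theta_max)
        X_new <- X; comp_new <- comp
        rates_new <- rates; rates_new[j] <- r
      }
      prop <- smodel_profile(tree, comp_new, rates_new, control)
      if (is.finite(prop) &&
          stats::runif(1) < exp(min(0, prop - cur))) {
        X <- X_new; comp <- comp_new; rates <- rates_new; cur <- prop
        if (cur > best$loglik) {
          best <- list(X = X, rates = rates, comp = comp, loglik = cur)
        }
      }
    }
    # polish the free rates of the best change set
    free <- if (normal_fixed) 1L + seq_len(s) else seq_len(s + 1L)
    for (sweep in 1:2) {
      for (j in free) {
        prof_j <- function(r) {
          rr <- best$rates; rr[j] <- r
          smodel_profile(tree, best$comp, rr, control)
        }
        opt <- stats::optimize(prof_j, c(theta_min, theta_max), maximum = TRUE,
                               tol = 1e-7 * (theta_max - theta_min))
        if (opt$objective > best$loglik) {
          best$rates[j] <- opt$maximum
          best$loglik <- opt$objective
        }
      }
    }
    new_smodel_fit(tree, best$X, best$rates, best$comp, best$loglik, s)
  })
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

new_smodel_fit <- function(tree, X, rates, comp, loglik, s) {
  structure(
    list(tree = tree, X = as.integer(X), rates = rates, comp = comp,
         theta = rates[comp + 1L], loglik = loglik, s = s),
    class = "smodel_fit"
  )
}

#' @export
print.smodel_fit <- function(x, ...) {
  cat(sprintf("<smodel_fit> s = %d; logLik %.4f; change vertices: %s\n",
              x$s, x$loglik,
              if (length(x$X)) paste(x$X, collapse = ", ") else "none"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.smodel_fit <- function(x, ...) {
  n <- n_mutations(x$tree)
  tibble::tibble(
    node = 0:n,
    label = x$tree$label,
    component = x$comp,
    rate = x$theta,
    change_vertex = (0:n) %in% x$X
  )
}

#' @exportS3Method generics::glance
glance.smodel_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, s = x$s,
                 n_components = length(unique(x$comp)))
}

#' One-rate vs two-rate model comparison for a tree
#'
#' Fits the flat landscape (`s = 0`, one shared rate) and the single
#' change-event landscape (`s = 1`, normal rate plus one changed rate) and
#' summarizes the evidence with [model_compare()] (`k1 = 1`, `k2 = 3`).
#'
#' @inheritParams fit_s_model
#' @param n number of vertices used in the BIC penalty; defaults to the
#'   mutation count of the tree
#' @return a one-row tibble from [model_compare()] plus `L1`, `L2`
#' @export
compare_rate_models <- function(tree, theta_min, theta_max,
                                theta_normal = (theta_min + theta_max) / 2,
                                n = n_mutations(tree),
                                n_iter = 200L, seed = 0L, control = list()) {
  f0 <- fit_s_model(tree, 0L, theta_min, theta_max, theta_normal,
                    n_iter = n_iter, seed = seed, control = control)
  # both rates of the two-rate model are estimated (its parameter count k2=3
  # is two rates plus one change vertex), so the flat model is nested
  f1 <- fit_s_model(tree, 1L, theta_min, theta_max, theta_normal,
                    normal_fixed = FALSE,
                    n_iter = n_iter, seed = seed, control = control)
  out <- model_compare(f0$loglik, f1$loglik, k1 = 1, k2 = 3, n = n)
  out$L1 <- f0$loglik
  out$L2 <- f1$loglik
  out
}
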