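#' Log-probability of a single branch of the timed binary phylogeny
#'
#' The generative model treats mutation acquisition in clone `k` as a Poisson
#' process with rate `theta_k`.  A branch between two internal birth events
#' labeled by clone `k` carries the shape-2 Erlang density
#' `theta^2 * dt * exp(-theta * dt)`; the terminal branch from the last event
#' on a lineage to its sampling carries `theta * exp(-theta * dt)`.
#'
#' @param kind `"internal"` or `"leaf"`
#' @param rate clone mutation rate, > 0
#' @param elapsed elapsed time along the branch, >= 0
#' @return the log-probability; `-Inf` (degenerate interval) for an internal
#'   branch of zero length
#' @examples
#' edge_log_prob("internal", 1, 1) # -1
#' edge_log_prob("leaf", 2, 0)     # log(2)
#' @export
edge_log_prob <- function(kind = c("internal", "leaf"), rate, elapsed) {
  kind <- match.arg(kind)
  stopifnot(rate > 0, elapsed >= 0)
  if (kind == "internal") {
    if (elapsed == 0) return(-Inf) # degenerate interval
    2 * log(rate) + log(elapsed) - rate * elapsed
  } else {
    log(rate) - rate * elapsed
  }
}

#' Sibling orderings in node-index order
#'
#' An ordering family assigns to every node the birth order of its children;
#' it is the discrete component that resolves the mutation tree's polytomies
#' into a binary phylogeny.  This helper returns the default family (children
#' ordered by node id).
#'
#' @param tree a `mutation_tree`
#' @return list indexed by node id + 1; element `i+1` is an integer vector of
#'   the children of node `i` in birth order
#' @export
default_orderings <- function(tree) tree$children

#' Ordering family implied by a set of birth times
#' @param tree a `mutation_tree`
#' @param times numeric vector of birth times indexed by node id + 1
#' @return an ordering family (see [default_orderings()])
#' @export
orderings_from_times <- function(tree, times) {
  lapply(tree$children, function(kids) {
    if (length(kids) < 2L) return(kids)
    kids[order(times[kids + 1L])]
  })
}

validate_orderings <- function(tree, sigma) {
  if (length(sigma) != n_mutations(tree) + 1L) stop("ordering family has wrong length")
  for (i in seq_along(sigma)) {
    if (!setequal(sigma[[i]], tree$children[[i]]) ||
        length(sigma[[i]]) != length(tree$children[[i]])) {
      stop("ordering of node ", i - 1L, " is not a permutation of its children")
    }
  }
  invisible(sigma)
}

# per-node gaps between consecutive birth events along clone i's lineage:
# anchor t_i, then ordered children times
sibling_gaps <- function(tree, times, sigma) {
  lapply(seq_along(sigma), function(i1) {
    kids <- sigma[[i1]]
    if (!length(kids)) return(numeric(0))
    diff(c(times[i1], times[kids + 1L]))
  })
}

#' Log-likelihood of a timed, ordered mutation tree
#'
#' Evaluates the mutability-landscape log-likelihood
#' \deqn{L = \sum_i \theta_i t_i + \sum_i \sum_j \log(t_{\sigma_{i,j}} -
#'   t_{\sigma_{i,j-1}}) - H \sum_i \theta_i + \sum_i (2 d_i + 1)\log\theta_i,}
#' the log of the product of branch probabilities of the binary phylogeny
#' determined by `sigma` (with \eqn{t_{\sigma_{i,0}} = t_i}).
#'
#' @param tree a `mutation_tree`
#' @param theta numeric vector of clone rates indexed by node id + 1
#' @param times numeric vector of birth times indexed by node id + 1
#'   (`times[1]` must be 0)
#' @param horizon sampling time `H`
#' @param sigma ordering family; default: children in node-index order
#' @return the log-likelihood; `-Inf` with a warning if sibling times do not
#'   increase along the ordering
#' @examples
#' tr <- mutation_tree(0L) # single edge 0 -> 1
#' tree_log_lik(tr, theta = c(1, 1), times = c(0, 0.5), horizon = 1)
#' @export
tree_log_lik <- function(tree, theta, times, horizon, sigma = NULL) {
  n <- n_mutations(tree)
  stopifnot(length(theta) == n + 1L, length(times) == n + 1L,
            all(theta > 0), times[1L] == 0)
  if (is.null(sigma)) sigma <- default_orderings(tree)
  gaps <- unlist(sibling_gaps(tree, times, sigma))
  if (length(gaps) && any(gaps <= 0)) {
    warning("ordering violated: sibling times not strictly increasing")
    return(-Inf)
  }
  sum(theta * times) + sum(log(gaps)) - horizon * sum(theta) +
    sum((2 * tree$outdegree + 1) * log(theta))
}

#' Branches of the binary phylogeny
#'
#' Expands a timed, ordered mutation tree into the branch list of its binary
#' phylogeny: for each clone `i`, one internal branch per consecutive pair of
#' birth events on its lineage and one terminal (sampling) branch.
#'
#' @inheritParams tree_log_lik
#' @return a tibble with columns `clone`, `kind`, `rate`, `elapsed`
#' @export
phylogeny_edges <- function(tree, theta, times, horizon, sigma = NULL) {
  if (is.null(sigma)) sigma <- default_orderings(tree)
  n <- n_mutations(tree)
  rows <- purrr::map_dfr(0:n, function(i) {
    kids <- sigma[[i + 1L]]
    ev <- c(times[i + 1L], times[kids + 1L])
    tibble::tibble(
      clone = i,
      kind = c(rep("internal", length(kids)), "leaf"),
      rate = theta[i + 1L],
      elapsed = c(diff(ev), horizon - ev[length(ev)])
    )
  })
  rows
}

# ---------------------------------------------------------------------------
# star-tree closed form

#' Optimal scaled event times on a star tree
#'
#' For a star (one internal node with `d` leaf children) and a fixed child
#' order, the partial likelihood `H * sum(theta_k t_k) + sum(log(t_k -
#' t_{k-1}))` over scaled times `0 < t_1 < ... < t_d <= 1` has a closed-form
#' stationary solution: the dual value `mu` of the constraint `t_d <= 1`
#' solves \eqn{\sum_k 1/(\mu - H \sum_{i \ge k} \theta_i) = 1}, and the
#' increments are \eqn{t_k - t_{k-1} = 1/(\mu - H \sum_{i \ge k} \theta_i)}.
#'
#' @param rates child rates in the chosen sibling order
#' @param horizon sampling time `H` (the scaled times live on \[0, 1\])
#' @return a list with `mu`, `times` (scaled, `times[d] = 1`), and `value`,
#'   the attained partial likelihood `mu - d - sum(log(mu - H cumsum))`
#' @export
star_optimal_times <- function(rates, horizon) {
  stopifnot(all(rates > 0), horizon > 0)
  kkt_star_solve(horizon * rates)
}

# shared KKT solve for the star-like problem max sum(lambda_k t_k) +
# sum(log(t_k - t_{k-1})) s.t. t_d <= 1; lambda = H*theta for true stars
kkt_star_solve <- function(lambda) {
  d <- length(lambda)
  S <- rev(cumsum(rev(lambda))) # S[k] = sum_{i>=k} lambda_i
  Smax <- max(S)
  f <- function(mu) sum(1 / (mu - S)) - 1
  lo <- Smax + 1e-12
  hi <- Smax + d + 1
  mu <- stats::uniroot(f, c(lo, hi), tol = 1e-12 * max(1, abs(Smax)))$root
  for (k in 1:3) { # Newton polish to full precision
    fv <- sum(1 / (mu - S)) - 1
    fp <- -sum(1 / (mu - S)^2)
    step <- fv / fp
    mu_new <- mu - step
    if (mu_new > Smax) mu <- mu_new
  }
  inc <- 1 / (mu - S)
  times <- cumsum(inc)
  list(mu = mu, times = times, value = mu - d - sum(log(mu - S)))
}

#' Likelihood-optimal sibling order on a star
#'
#' The partial likelihood of a star is maximized when children are born in
#' ascending order of their mutation rates; ties keep node-index order.
#'
#' @param rates numeric child rates
#' @param children optional child ids (defaults to positions `1..d`)
#' @return `children` permuted into the optimal order
#' @examples
#' optimal_star_ordering(c(0.3, 0.1, 0.2)) # 2 3 1
#' @export
optimal_star_ordering <- function(rates, children = seq_along(rates)) {
  stopifnot(all(rates > 0), length(children) == length(rates))
  children[order(rates)]
}
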