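# Search over sibling orderings (polytomy resolutions).  The search is the
# bottom-up dynamic program over the tree: children's subtree orderings are
# fixed to their own optima first (their choice is horizon-independent in the
# large-H regime, and empirically stable across horizons), then the node's own
# child permutation is chosen.  Two scoring tiers per node:
#   * exact  — every permutation of the children is scored by a full convex
#     solve on the node's subtree (free subtree horizon); used while
#     d! * subtree_size stays within `exact_budget`;
#   * asymptotic — for wide polytomies the large-horizon expansion collapses
#     each child subtree to a linear-plus-log contribution whose
#     permutation-dependent part is exactly the star problem in the child's
#     own rate, so the optimal order is ascending in the child rate (ties keep
#     node-index order).
# A final full-tree convex solve evaluates the composed family.

#' Best sibling orderings for fixed rates
#'
#' Resolves every polytomy of the mutation tree into a birth order that
#' maximizes the log-likelihood for the given rates, jointly with the optimal
#' event times, via the bottom-up search described above.
#'
#' @inheritParams optimize_times
#' @param control list: `exact_budget` (default 600) bounds `d! * subtree
#'   size` for exhaustive per-node scoring; `degree_cap` (default 9) is the
#'   maximal outdegree accepted without `heuristic = TRUE`; `heuristic`
#'   forces the ascending-rate tier above the cap; `solver` is passed to
#'   [optimize_times()]
#' @param warm optional previous solution `list(theta, sigma)`: nodes whose
#'   subtree rates are unchanged reuse their previous ordering (the per-node
#'   decision depends only on the subtree's rates and shape, so the reuse is
#'   exact)
#' @return a list with `sigma` (ordering family), `times`, `horizon`,
#'   `loglik`, and `tiers` (per-node scoring tier used)
#' @export
best_orderings <- function(tree, theta, theta_min = 0, theta_max = Inf,
                           horizon = NULL, theta0_fixed = TRUE,
                           bands = c("both", "lower", "none"),
                           control = list(), warm = NULL) {
  bands <- match.arg(bands)
  ctl <- utils::modifyList(
    list(exact_budget = 600, degree_cap = 9L, heuristic = FALSE,
         climb_budget = 25L, solver = list()),
    control
  )
  n <- n_mutations(tree)
  sigma <- tree$children
  sz <- subtree_sizes(tree)
  tiers <- rep(NA_character_, n + 1L)

  for (k in postorder_nodes(tree)) {
    kids <- tree$children[[k + 1L]]
    d <- length(kids)
    if (d <= 1L) next
    if (d > ctl$degree_cap && !isTRUE(ctl$heuristic)) {
      stop("polytomy too wide; raise cap or use heuristic flag")
    }
    if (!is.null(warm)) {
      sub_ids <- subtree_nodes(tree, k) + 1L
      if (identical(theta[sub_ids], warm$theta[sub_ids])) {
        sigma[[k + 1L]] <- warm$sigma[[k + 1L]]
        tiers[k + 1L] <- "warm"
        next
      }
    }
    if (factorial(d) * sz[k + 1L] <= ctl$exact_budget) {
      tiers[k + 1L] <- "exact"
      sigma[[k + 1L]] <- exact_node_ordering(
        tree, k, kids, sigma, theta, theta_min, theta_max,
        theta0_fixed, bands, ctl$solver
      )
    } else {
      tiers[k + 1L] <- "heuristic"
      sigma[[k + 1L]] <- heuristic_node_ordering(
        tree, k, kids, sigma, theta, theta_min, theta_max,
        theta0_fixed, bands, ctl
      )
    }
  }

  fit <- optimize_times(tree, theta, sigma, theta_min, theta_max,
                        horizon, theta0_fixed, bands, ctl$solver)
  list(sigma = sigma, times = fit$times, horizon = fit$horizon,
       loglik = fit$loglik, tiers = tiers)
}

# Ordering for polytomies too wide for exhaustive scoring: start from the
# asymptotically motivated order (children whose subtrees need the largest
# exposures first -- they must be born early for their descendants to fit --
# then ascending child rate, the star-tree rule), and improve it by
# adjacent-transposition hill climbing with exact subtree scoring under a
# solve budget.
heuristic_node_ordering <- function(tree, k, kids, sigma, theta,
                                    theta_min, theta_max, theta0_fixed,
                                    bands, ctl) {
  d_out <- tree$outdegree
  smax <- vapply(kids, function(c) {
    sub <- subtree_nodes(tree, c)
    internal <- sub[d_out[sub + 1L] >= 1L]
    if (!length(internal) || !is.finite(theta_max)) return(0)
    max(d_out[internal + 1L]) / theta_max
  }, numeric(1))
  ord <- kids[order(-smax, theta[kids + 1L], kids)]
  budget <- ctl$climb_budget
  if (budget <= 0) return(ord)

  sub <- extract_subtree(tree, k, sigma)
  th_sub <- theta[sub$nodes + 1L]
  root_fixed <- (k == 0L) && theta0_fixed
  score <- function(p) {
    sig <- sub$sigma
    sig[[1L]] <- unname(sub$map[as.character(p)])
    tryCatch(
      optimize_times(sub$tree, th_sub, sig, theta_min, theta_max,
                     horizon = NULL, theta0_fixed = root_fixed,
                     bands = bands, control = ctl$solver)$partial,
      error = function(e) -Inf
    )
  }
  cur_val <- score(ord); budget <- budget - 1L
  if (!is.finite(cur_val)) return(ord)
  improved <- TRUE
  while (improved && budget > 0L) {
    improved <- FALSE
    for (j in seq_len(length(ord) - 1L)) {
      if (budget <= 0L) break
      cand <- ord
      cand[c(j, j + 1L)] <- cand[c(j + 1L, j)]
      val <- score(cand); budget <- budget - 1L
      if (is.finite(val) && val > cur_val + 1e-9) {
        ord <- cand; cur_val <- val; improved <- TRUE
      }
    }
  }
  ord
}

# exhaustive permutation scoring at one node, on its standalone subtree
exact_node_ordering <- function(tree, k, kids, sigma, theta,
                                theta_min, theta_max, theta0_fixed,
                                bands, solver_ctl) {
  sub <- extract_subtree(tree, k, sigma)
  th_sub <- theta[sub$nodes + 1L]
  root_fixed <- (k == 0L) && theta0_fixed
  best <- NULL; best_val <- -Inf
  for (p in all_permutations(kids)) {
    sig <- sub$sigma
    sig[[1L]] <- sub$map[as.character(p)]
    val <- tryCatch(
      optimize_times(sub$tree, th_sub, sig, theta_min, theta_max,
                     horizon = NULL, theta0_fixed = root_fixed,
                     bands = bands, control = solver_ctl)$partial,
      error = function(e) -Inf
    )
    if (is.finite(val) && val > best_val + 1e-9) {
      best_val <- val; best <- p
    }
  }
  if (is.null(best)) kids else best
}

# standalone subtree rooted at k: re-indexed tree, node map, and the working
# ordering family restricted to the subtree
extract_subtree <- function(tree, k, sigma) {
  nodes <- subtree_nodes(tree, k) # preorder, k first
  map <- stats::setNames(seq_along(nodes) - 1L, as.character(nodes))
  m <- length(nodes) - 1L
  parent <- integer(m)
  for (v in nodes[-1L]) {
    parent[map[[as.character(v)]]] <- map[[as.character(tree$parent[v + 1L])]]
  }
  sub_tree <- mutation_tree(parent,
                            label = tree$label[nodes[-1L] + 1L],
                            loss = tree$loss[nodes[-1L] + 1L])
  sub_sigma <- vector("list", m + 1L)
  for (v in nodes) {
    sub_sigma[[map[[as.character(v)]] + 1L]] <-
      unname(map[as.character(sigma[[v + 1L]])])
  }
  list(tree = sub_tree, nodes = nodes, map = map, sigma = sub_sigma)
}

all_permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Exhaustive ordering search (test oracle)
#'
#' Enumerates every ordering family (all products of child permutations) and
#' scores each by a full convex time solve; exact but exponential, intended
#' for validating [best_orderings()] on small trees.
#'
#' @inheritParams best_orderings
#' @param max_families enumeration budget on `prod(d_i!)`
#' @return as [best_orderings()], without `tiers`
#' @export
brute_force_orderings <- function(tree, theta, theta_min = 0, theta_max = Inf,
                                  horizon = NULL, theta0_fixed = TRUE,
                                  bands = c("both", "lower", "none"),
                                  max_families = 1e5, control = list()) {
  bands <- match.arg(bands)
  n <- n_mutations(tree)
  perm_sets <- lapply(tree$children, function(kids) {
    if (length(kids) <= 1L) list(kids) else all_permutations(kids)
  })
  counts <- lengths(perm_sets)
  if (prod(counts) > max_families) stop("too many orderings")

  idx <- rep(1L, n + 1L)
  best <- NULL; best_val <- -Inf
  repeat {
    sigma <- lapply(seq_along(perm_sets), function(i) perm_sets[[i]][[idx[i]]])
    fit <- tryCatch(
      optimize_times(tree, theta, sigma, theta_min, theta_max,
                     horizon, theta0_fixed, bands, control),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$loglik) && fit$loglik > best_val + 1e-9) {
      best_val <- fit$loglik
      best <- c(fit, list(sigma = sigma))
    }
    # advance mixed-radix counter; last node varies fastest so earlier
    # (lower-index) nodes win ties
    pos <- n + 1L
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= counts[pos]) break
      idx[pos] <- 1L
      pos <- pos - 1L
      if (pos < 1L) break
    }
    if (pos < 1L) break
  }
  if (is.null(best)) stop("no feasible timing for any ordering")
  list(sigma = best$sigma, times = best$times, horizon = best$horizon,
       loglik = best$loglik)
}
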