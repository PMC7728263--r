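# EM driver: alternate the M step (orderings + event times for fixed rates)
# with the E step (rate update theta_i = d_i / (H - t_i), clamped to the box).

#' Rate update from event times (E step)
#'
#' The expected mutation rate of an internal clone is its offspring count
#' divided by its exposure time, `theta_i = d_i / (H - t_i)`, clamped into
#' `[theta_min, theta_max]`.  Leaves have no offspring to estimate a rate
#' from, so they keep their previous value; the root keeps its configured
#' rate when `theta0_fixed`.
#'
#' @param tree a `mutation_tree`
#' @param times birth times indexed by node id + 1
#' @param horizon sampling time `H`
#' @param theta_prev previous rate vector (supplies leaf rates)
#' @param theta_min,theta_max feasible rate box
#' @param theta0_fixed keep the root rate at `theta_prev[1]`?
#' @param exact with `exact = TRUE` the update uses the unconstrained
#'   stationary point of the log-likelihood in `theta_i`,
#'   `(2 d_i + 1)/(H - t_i)`, instead of the expected-rate form
#' @return updated rate vector
#' @export
estep_rates <- function(tree, times, horizon, theta_prev,
                        theta_min, theta_max, theta0_fixed = TRUE,
                        exact = FALSE) {
  d <- tree$outdegree
  n <- n_mutations(tree)
  stopifnot(length(theta_prev) == n + 1L, length(times) == n + 1L)
  expo <- horizon - times
  internal <- d >= 1L
  if (any(expo[internal] <= 0)) stop("invalid timing")
  theta <- theta_prev
  num <- if (exact) 2 * d + 1 else d
  theta[internal] <- pmin(pmax(num[internal] / expo[internal], theta_min),
                          theta_max)
  if (theta0_fixed) theta[1L] <- theta_prev[1L]
  theta
}

#' Infer the mutability landscape of a mutation tree
#'
#' Maximum-likelihood estimation of per-clone mutation rates, mutation event
#' times, the sampling time `H`, and the sibling birth orders, by EM:
#' the M step finds orderings and times for the current rates
#' ([best_orderings()]); the E step re-estimates rates from the exposures
#' ([estep_rates()]).  Iteration stops when the attained log-likelihood
#' changes by less than `tol`; because the rate update is a heuristic, the
#' best iterate seen is tracked and returned.
#'
#' @param tree a `mutation_tree`
#' @param theta_min,theta_max feasible rate box for non-root clones
#' @param theta0 root (normal-tissue) rate; defaults to the box midpoint
#' @param theta0_fixed hold the root rate fixed (recommended; the root has no
#'   birth time to date it by)
#' @param init `"midpoint"` starts all rates at `(theta_min + theta_max)/2`;
#'   `"random"` draws them uniformly from the box
#' @param max_iter EM iteration cap
#' @param tol convergence tolerance on the log-likelihood
#' @param estep `"expected"` uses `d_i/(H - t_i)`; `"exact"` uses
#'   `(2 d_i + 1)/(H - t_i)`
#' @param bands timing-band mode passed to [optimize_times()]
#' @param seed RNG seed used when `init = "random"`
#' @param control ordering-search control, see [best_orderings()]
#' @return an object of class `clonerate_fit`: a list with `theta`, `times`,
#'   `horizon`, `sigma`, `loglik`, `iterations`, `converged`, `trace` (per
#'   iteration log-likelihoods), plus the call configuration
#' @examples
#' tr <- read_mutation_tree("0 1 1 2 2", dialect = "parent_vector")
#' fit <- infer_rates(tr, theta_min = 0.5, theta_max = 2, theta0 = 1)
#' tidy(fit)
#' glance(fit)
#' @export
infer_rates <- function(tree, theta_min, theta_max,
                        theta0 = (theta_min + theta_max) / 2,
                        theta0_fixed = TRUE,
                        init = c("midpoint", "random"),
                        max_iter = 100L, tol = 1e-6,
                        estep = c("expected", "exact"),
                        bands = c("both", "lower", "none"),
                        seed = 0L, control = list()) {
  stopifnot(theta_min > 0, theta_min < theta_max)
  init <- match.arg(init)
  estep <- match.arg(estep)
  bands <- match.arg(bands)
  n <- n_mutations(tree)

  theta <- if (init == "midpoint") {
    rep((theta_min + theta_max) / 2, n + 1L)
  } else {
    withr_seed(seed, c(0, stats::runif(n, theta_min, theta_max)))
  }
  theta[1L] <- theta0

  best <- NULL
  trace <- numeric(0)
  loglik_prev <- -Inf
  converged <- FALSE
  iterations <- 0L
  warm <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    m <- tryCatch(
      best_orderings(tree, theta, theta_min, theta_max,
                     horizon = NULL, theta0_fixed = theta0_fixed,
                     bands = bands, control = control, warm = warm),
      error = function(e) {
        if (bands == "both" && grepl("no feasible timing", conditionMessage(e))) {
          # composed family clashes with the upper bands: relax for this pass
          best_orderings(tree, theta, theta_min, theta_max,
                         horizon = NULL, theta0_fixed = theta0_fixed,
                         bands = "lower", control = control)
        } else {
          stop(e)
        }
      }
    )
    warm <- list(theta = theta, sigma = m$sigma)
    trace <- c(trace, m$loglik)
    if (is.null(best) || m$loglik > best$loglik) {
      best <- list(theta = theta, times = m$times, horizon = m$horizon,
                   sigma = m$sigma, loglik = m$loglik)
    }
    if (abs(m$loglik - loglik_prev) < tol) {
      converged <- TRUE
      break
    }
    loglik_prev <- m$loglik
    theta <- estep_rates(tree, m$times, m$horizon, theta,
                         theta_min, theta_max, theta0_fixed,
                         exact = (estep == "exact"))
  }

  structure(
    list(
      tree = tree, theta = best$theta, times = best$times,
      horizon = best$horizon, sigma = best$sigma, loglik = best$loglik,
      iterations = iterations, converged = converged, trace = trace,
      theta_min = theta_min, theta_max = theta_max,
      theta0_fixed = theta0_fixed, init = init, estep = estep, bands = bands
    ),
    class = "clonerate_fit"
  )
}

# evaluate expr with a temporary seed without disturbing the session RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' @export
print.clonerate_fit <- function(x, ...) {
  cat(sprintf(
    "<clonerate_fit> %d mutations; logLik %.4f; H %.4g; %d EM iteration%s%s\n",
    n_mutations(x$tree), x$loglik, x$horizon, x$iterations,
    if (x$iterations == 1L) "" else "s",
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Tidy a mutability-landscape fit
#'
#' @param x a `clonerate_fit`
#' @param ... unused
#' @return a tibble with one row per node: `node`, `label`, `parent`,
#'   `outdegree`, `rate`, `estimated` (leaves and a fixed root are not), and
#'   `time` (birth time; sampling time is in [glance()])
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.clonerate_fit <- function(x, ...) {
  tr <- x$tree
  n <- n_mutations(tr)
  tibble::tibble(
    node = 0:n,
    label = tr$label,
    parent = tr$parent,
    outdegree = as.integer(tr$outdegree),
    rate = x$theta,
    estimated = tr$outdegree >= 1L & !(0:n == 0L & x$theta0_fixed),
    time = x$times
  )
}

#' Glance at a mutability-landscape fit
#'
#' @param x a `clonerate_fit`
#' @param ... unused
#' @return a one-row tibble: `logLik`, `horizon`, `n_mutations`,
#'   `iterations`, `converged`
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.clonerate_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    horizon = x$horizon,
    n_mutations = n_mutations(x$tree),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
logLik.clonerate_fit <- function(object, ...) {
  structure(object$loglik, df = sum(object$tree$outdegree >= 1L), class = "logLik")
}
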