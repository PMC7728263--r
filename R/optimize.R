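# Convex optimization of event times (and the sampling horizon) for a fixed
# ordering family and fixed rates.  The objective
#   sum_i theta_i t_i + sum(log sibling gaps) - H sum_i theta_i
# is concave in (t, H); constraints are linear:
#   * sibling gaps > 0 (also the log terms' domain),
#   * d_i/theta_max <= H - t_i <= d_i/theta_min for rate-estimated internal
#     nodes (keeps the EM rate update inside the feasible box),
#   * 0 <= t_i <= H for leaves.
# The solve is an interior-point Newton method (exact gradient and Hessian)
# along a decreasing log-barrier schedule, started from a strictly feasible
# point found by Bellman-Ford on the difference-constraint system, then
# sharpened by an active-set equality-constrained Newton polish, because
# optima routinely sit on constraint boundaries (H in particular is always
# pinned from below).

#' Maximum-likelihood event times for fixed rates and orderings
#'
#' Maximizes the tree log-likelihood over birth times `t` (and the sampling
#' time `H` unless `horizon` is supplied) for a fixed ordering family and
#' fixed rates, subject to sibling-order constraints and the rate-box timing
#' bands `d_i/theta_max <= H - t_i <= d_i/theta_min` for internal nodes whose
#' rates are estimated.  Leaves are constrained to `0 <= t_i <= H` only; the
#' root band is dropped when `theta0_fixed` (its rate is not re-estimated).
#'
#' @param tree a `mutation_tree`
#' @param theta clone rates indexed by node id + 1
#' @param sigma ordering family (default: node-index order)
#' @param theta_min,theta_max feasible rate box; the defaults `0`/`Inf`
#'   disable the timing bands
#' @param horizon if numeric, the sampling time is held fixed at this value;
#'   if `NULL` it is optimized jointly
#' @param theta0_fixed is the root rate fixed (excluded from the timing band)?
#' @param bands `"both"` (default) enforces the two-sided band, with each
#'   node's upper band relaxed minimally (5% headroom above the largest lower
#'   band among its internal descendants) so that the system stays feasible
#'   on trees where a child's outdegree exceeds `theta_max/theta_min` times
#'   its parent's; `"lower"` keeps only `H - t_i >= d_i/theta_max`; `"none"`
#'   drops the bands
#' @param control list of solver settings (`polish`, barrier schedule)
#' @return a list with `times` (length `n + 1`, `times[1] = 0`), `horizon`,
#'   `loglik` (the full log-likelihood at the solution), `partial` (the
#'   optimized time-dependent part), and `feasible`
#' @export
optimize_times <- function(tree, theta, sigma = NULL,
                           theta_min = 0, theta_max = Inf,
                           horizon = NULL, theta0_fixed = TRUE,
                           bands = c("both", "lower", "none"),
                           control = list()) {
  n <- n_mutations(tree)
  bands <- match.arg(bands)
  stopifnot(length(theta) == n + 1L, all(theta > 0))
  if (is.null(sigma)) sigma <- default_orderings(tree)
  ctl <- utils::modifyList(list(
    mu = 1e-4, outer.iterations = 60L, outer.eps = 1e-8,
    maxit = 300L, reltol = 1e-12, polish = TRUE
  ), control)

  if (n == 0L) { # root-only tree: no free times, H at its lower bound
    H <- if (is.null(horizon)) 0 else horizon
    return(list(times = 0, horizon = H,
                loglik = log(theta[1L]) - theta[1L] * H,
                partial = 0, feasible = TRUE))
  }

  if (bands == "none") { theta_min <- 0; theta_max <- Inf }
  if (bands != "both") theta_min <- 0
  prob <- timing_problem(tree, sigma, theta, theta_min, theta_max,
                         horizon, theta0_fixed)
  start <- feasible_start(prob)
  if (is.null(start)) stop("no feasible timing")

  sol <- solve_timing(prob, start, ctl)
  times <- c(0, sol$x[seq_len(n)])
  H <- if (prob$hfree) sol$x[n + 1L] else horizon
  list(times = times, horizon = H,
       loglik = tree_log_lik(tree, theta, times, H, sigma),
       partial = sol$value, feasible = TRUE)
}

# Build the gap list, constraint system and objective closures.
timing_problem <- function(tree, sigma, theta, theta_min, theta_max,
                           horizon, theta0_fixed) {
  n <- n_mutations(tree)
  hfree <- is.null(horizon)
  nvar <- n + as.integer(hfree)
  hidx <- if (hfree) n + 1L else NA_integer_

  # gap terms (a = later event, b = earlier; node id 0 is the constant 0)
  ga <- integer(0); gb <- integer(0)
  for (i1 in seq_along(sigma)) {
    kids <- sigma[[i1]]
    if (!length(kids)) next
    prev <- c(i1 - 1L, kids[-length(kids)])
    ga <- c(ga, kids)
    gb <- c(gb, prev)
  }

  d <- tree$outdegree
  banded <- which(d[-1L] >= 1L) # internal non-root node ids
  band_lo <- d[banded + 1L] / theta_max
  band_up <- if (theta_min > 0) d[banded + 1L] / theta_min else rep(Inf, length(banded))
  # Feasibility relaxation: every event forced after node i (its descendants
  # and, under the given sibling order, the subtrees of its later siblings)
  # must fit inside i's exposure, so i's upper band is raised with 5%
  # headroom above the largest lower band in that forced-after set; without
  # this the printed two-sided band system is infeasible whenever a child's
  # outdegree is too large relative to its parent's.
  if (theta_min > 0 && length(banded)) {
    lo_by_node <- numeric(length(d))
    lo_by_node[banded + 1L] <- band_lo
    smax <- numeric(length(d)) # max lower band within each subtree
    for (v in postorder_nodes(tree)) {
      kids <- tree$children[[v + 1L]]
      smax[v + 1L] <- max(lo_by_node[v + 1L],
                          if (length(kids)) max(smax[kids + 1L]) else 0)
    }
    need <- numeric(length(d))
    for (i1 in seq_along(sigma)) {
      kids <- sigma[[i1]]
      dk <- length(kids)
      if (!dk) next
      later <- 0 # max lower band among later siblings' subtrees
      for (j in rev(seq_len(dk))) {
        cj <- kids[j]
        below <- tree$children[[cj + 1L]]
        own <- if (length(below)) max(smax[below + 1L]) else 0
        need[cj + 1L] <- max(own, later)
        later <- max(later, smax[cj + 1L])
      }
    }
    idx <- need[banded + 1L] > 0
    band_up[idx] <- pmax(band_up[idx], 1.05 * need[banded + 1L][idx])
  }
  leaves <- which(d[-1L] == 0L)
  root_band <- !theta0_fixed && d[1L] >= 1L

  # linear constraints ui %*% x >= ci over x = (t_1..t_n[, H])
  rows <- list(); cis <- numeric(0)
  add_row <- function(cols, vals, ci) {
    r <- numeric(nvar); r[cols] <- vals
    rows[[length(rows) + 1L]] <<- r
    cis <<- c(cis, ci)
  }
  for (k in seq_along(ga)) { # t_a - t_b >= 0
    if (gb[k] == 0L) add_row(ga[k], 1, 0)
    else add_row(c(ga[k], gb[k]), c(1, -1), 0)
  }
  bound_row <- function(i, lo, up) {
    # lo <= H - t_i (<= up)
    if (hfree) add_row(c(i, hidx), c(-1, 1), lo)
    else add_row(i, -1, lo - horizon)
    if (is.finite(up)) {
      if (hfree) add_row(c(i, hidx), c(1, -1), -up)
      else add_row(i, 1, horizon - up)
    }
  }
  for (k in seq_along(banded)) bound_row(banded[k], band_lo[k], band_up[k])
  for (i in leaves) bound_row(i, 0, Inf)
  if (root_band) {
    lo0 <- d[1L] / theta_max
    up0 <- if (theta_min > 0) d[1L] / theta_min else Inf
    if (is.finite(up0) && length(banded)) {
      up0 <- max(up0, 1.05 * max(band_lo)) # same descendant relaxation
    }
    if (hfree) {
      add_row(hidx, 1, lo0)
      if (is.finite(up0)) add_row(hidx, -1, -up0)
    } # fixed horizon: root band is a constant check
  }
  ui <- do.call(rbind, rows)

  list(n = n, nvar = nvar, hfree = hfree, hidx = hidx, horizon = horizon,
       theta = theta, ga = ga, gb = gb, ui = ui, ci = cis,
       banded = banded, band_lo = band_lo, band_up = band_up,
       leaves = leaves, root_band = root_band,
       lo0 = if (root_band) d[1L] / theta_max else 0,
       up0 = if (root_band && theta_min > 0) d[1L] / theta_min else Inf)
}

# Strictly feasible start via Bellman-Ford on the difference-constraint
# system (all constraints have the form x_a - x_b >= c; the root time is the
# zero reference).  Slack eps makes the point interior.
feasible_start <- function(prob) {
  n <- prob$n
  hfree <- prob$hfree
  nv <- n + 2L # vertices: 1 = t_0, 2..n+1 = t_1..t_n, n+2 = H
  H_V <- n + 2L
  cons <- list() # (a, b, c): x_a - x_b >= c  (vertex indices)
  for (k in seq_along(prob$ga)) {
    cons[[length(cons) + 1L]] <- c(prob$ga[k] + 1L, prob$gb[k] + 1L, 0)
  }
  addb <- function(i, lo, up) {
    cons[[length(cons) + 1L]] <<- c(H_V, i + 1L, lo)
    if (is.finite(up)) cons[[length(cons) + 1L]] <<- c(i + 1L, H_V, -up)
  }
  for (k in seq_along(prob$banded)) addb(prob$banded[k], prob$band_lo[k], prob$band_up[k])
  for (i in prob$leaves) addb(i, 0, Inf)
  if (prob$root_band) addb(0L, prob$lo0, prob$up0)
  if (!hfree) { # pin H to the given constant
    cons[[length(cons) + 1L]] <- c(H_V, 1L, prob$horizon)
    cons[[length(cons) + 1L]] <- c(1L, H_V, -prob$horizon)
  }
  cm <- do.call(rbind, cons)

  widths <- c(prob$band_up - prob$band_lo, if (!hfree) prob$horizon,
              1 / mean(prob$theta))
  widths <- widths[is.finite(widths) & widths > 0]
  eps0 <- min(widths) / (4 * (n + 2))
  for (eps in eps0 * c(1, 0.1, 0.01, 1e-4, 1e-7)) {
    slack <- ifelse(cm[, 3] == prob$horizon & !hfree & cm[, 1] == H_V, 0, eps)
    pin <- !hfree & ((cm[, 1] == H_V & cm[, 2] == 1L) | (cm[, 1] == 1L & cm[, 2] == H_V))
    cvec <- cm[, 3] + ifelse(pin, 0, eps)
    x <- bellman_ford(nv, cm[, 1], cm[, 2], cvec)
    if (is.null(x)) next
    x <- x - x[1L]
    t_start <- x[2:(n + 1L)]
    H_start <- x[H_V]
    start <- if (hfree) c(t_start, H_start) else t_start
    if (all(prob$ui %*% start - prob$ci > 0)) return(start)
  }
  NULL
}

bellman_ford <- function(nv, a, b, cvec) {
  d <- rep(0, nv)
  for (it in seq_len(nv + 1L)) {
    changed <- FALSE
    cand <- d[a] - cvec
    for (k in seq_along(a)) {
      if (cand[k] < d[b[k]] - 1e-15) {
        d[b[k]] <- cand[k]
        changed <- TRUE
      }
      # refresh candidates lazily: recompute this source's later edges
      cand[k] <- d[a[k]] - cvec[k]
    }
    cand <- d[a] - cvec
    if (!changed) return(d)
  }
  NULL # negative cycle: infeasible
}

# objective (to maximize), gradient and Hessian over x = (t_1..t_n[, H])
timing_objective <- function(prob) {
  n <- prob$n; hfree <- prob$hfree
  theta <- prob$theta
  th_sum <- sum(theta)
  ga <- prob$ga; gb <- prob$gb
  tval <- function(x, id) { # t value by node id; id 0 is the root (t = 0)
    v <- numeric(length(id))
    pos <- id > 0L
    v[pos] <- x[id[pos]]
    v
  }
  f <- function(x) {
    gaps <- tval(x, ga) - tval(x, gb)
    if (any(gaps <= 0)) return(NaN)
    t_all <- c(0, x[seq_len(n)])
    H <- if (hfree) x[n + 1L] else prob$horizon
    sum(theta * t_all) + sum(log(gaps)) - th_sum * H
  }
  g <- function(x) {
    gaps <- tval(x, ga) - tval(x, gb)
    gr <- numeric(prob$nvar)
    gr[seq_len(n)] <- theta[-1L]
    for (k in seq_along(ga)) {
      gr[ga[k]] <- gr[ga[k]] + 1 / gaps[k]
      if (gb[k] > 0L) gr[gb[k]] <- gr[gb[k]] - 1 / gaps[k]
    }
    if (hfree) gr[n + 1L] <- -th_sum
    gr
  }
  h <- function(x) {
    gaps <- tval(x, ga) - tval(x, gb)
    H <- matrix(0, prob$nvar, prob$nvar)
    for (k in seq_along(ga)) {
      w <- 1 / gaps[k]^2
      a <- ga[k]; b <- gb[k]
      H[a, a] <- H[a, a] - w
      if (b > 0L) {
        H[b, b] <- H[b, b] - w
        H[a, b] <- H[a, b] + w
        H[b, a] <- H[b, a] + w
      }
    }
    H
  }
  list(f = f, g = g, h = h)
}

solve_timing <- function(prob, start, ctl) {
  # rescale the time unit so variables are O(1)
  s <- max(abs(start), 1)
  prob_s <- prob
  prob_s$theta <- prob$theta * s
  if (!prob$hfree) prob_s$horizon <- prob$horizon / s
  prob_s$ci <- prob$ci / s
  obj_s <- timing_objective(prob_s)
  x0 <- start / s

  x_bar <- barrier_path(x0, obj_s, prob_s, ctl)
  best <- list(x = x_bar, value = obj_s$f(x_bar))

  if (isTRUE(ctl$polish)) {
    pol <- polish_active_set(x_bar, obj_s, prob_s)
    if (!is.null(pol) && is.finite(pol$value) && pol$value >= best$value - 1e-12) {
      best <- pol
    }
  }
  # undo rescaling; the partial-likelihood value gains #gaps * log(s)
  list(x = best$x * s, value = best$value + length(prob$ga) * log(s))
}

# Interior-point solve: Newton steps on -f(x) - mu * sum(log(ui x - ci))
# along a decreasing barrier schedule.  f supplies exact gradient/Hessian;
# the barrier makes the Hessian positive definite in the H direction too.
barrier_path <- function(x0, obj, prob, ctl) {
  ui <- prob$ui; ci <- prob$ci
  x <- x0
  phi <- function(x, mu) {
    fv <- obj$f(x)
    if (!is.finite(fv)) return(Inf)
    g <- as.numeric(ui %*% x - ci)
    if (any(g <= 0)) return(Inf)
    -fv - mu * sum(log(g))
  }
  mu_seq <- 10^seq(0, -9, by = -1.5)
  for (mu in mu_seq) {
    for (it in 1:60) {
      g <- as.numeric(ui %*% x - ci)
      grad <- -obj$g(x) - mu * as.numeric(crossprod(ui, 1 / g))
      Hb <- crossprod(ui * (sqrt(mu) / g))
      Hm <- -obj$h(x) + Hb
      dx <- tryCatch(-solve(Hm, grad), error = function(e) NULL)
      if (is.null(dx)) {
        Hm <- Hm + diag(1e-8 * max(abs(diag(Hm))), nrow(Hm))
        dx <- tryCatch(-solve(Hm, grad), error = function(e) NULL)
        if (is.null(dx)) break
      }
      lamsq <- -sum(grad * dx) # Newton decrement squared
      if (!is.finite(lamsq) || lamsq < 1e-13) break
      a <- 1
      p0 <- phi(x, mu)
      while (phi(x + a * dx, mu) > p0 - 0.25 * a * lamsq && a > 1e-12) a <- a / 2
      if (a <= 1e-12) break
      x <- x + a * dx
      if (a * sqrt(sum(dx^2)) < 1e-14 * (1 + sqrt(sum(x^2)))) break
    }
  }
  x
}

# Equality-constrained Newton refinement on the estimated active set, with
# multiplier-sign checks to drop wrongly activated rows.  Sharpens boundary
# solutions (adaptive barriers stop short of the boundary).
polish_active_set <- function(x, obj, prob) {
  ui <- prob$ui; ci <- prob$ci
  scale <- 1 + max(abs(x))
  active <- which(ui %*% x - ci < 1e-3 * scale)
  # H must be pinned: its gradient component never vanishes
  if (prob$hfree && !any(ui[active, prob$hidx, drop = FALSE] != 0)) {
    hrows <- which(ui[, prob$hidx] != 0)
    if (!length(hrows)) return(NULL)
    slack <- (ui %*% x - ci)[hrows]
    active <- union(active, hrows[which.min(slack)])
  }
  sol <- NULL
  for (round in 1:4) {
    if (!length(active)) return(NULL)
    A <- ui[active, , drop = FALSE]
    qrA <- qr(t(A))
    keep <- qrA$pivot[seq_len(qrA$rank)]
    active <- active[keep]
    A <- ui[active, , drop = FALSE]
    b <- ci[active]
    sol <- newton_on_manifold(x, obj, A, b, prob)
    if (is.null(sol)) return(NULL)
    # KKT multipliers for "ui x >= ci": grad f = -A' lambda, lambda >= 0
    lam <- tryCatch(as.numeric(qr.solve(A %*% t(A), -A %*% sol$grad)),
                    error = function(e) NULL)
    if (is.null(lam)) return(sol)
    bad <- which(lam < -1e-7 * scale)
    if (!length(bad)) return(sol)
    active <- active[-bad]
    x <- sol$x
  }
  sol
}

newton_on_manifold <- function(x, obj, A, b, prob) {
  ui <- prob$ui; ci <- prob$ci
  for (it in 1:40) {
    g <- obj$g(x)
    H <- obj$h(x)
    na <- nrow(A)
    K <- rbind(cbind(H, t(A)), cbind(A, matrix(0, na, na)))
    rhs <- c(-g, b - as.numeric(A %*% x))
    step <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(step)) {
      step <- tryCatch(qr.solve(K, rhs), error = function(e) NULL)
    }
    if (is.null(step) || anyNA(step) || any(!is.finite(step))) return(NULL)
    dx <- step[seq_along(x)]
    if (max(abs(dx)) < 1e-14 * (1 + max(abs(x)))) break
    alpha <- 1
    f0 <- obj$f(x)
    repeat {
      x_new <- x + alpha * dx
      fv <- obj$f(x_new)
      ok <- is.finite(fv) && all(ui %*% x_new - ci >= -1e-10)
      if (ok && (fv >= f0 - 1e-12 || alpha < 1e-6)) break
      alpha <- alpha / 2
      if (alpha < 1e-10) return(NULL)
    }
    x <- x + alpha * dx
    if (alpha * max(abs(dx)) < 1e-13 * (1 + max(abs(x)))) break
  }
  # snap exactly onto the manifold
  x_try <- tryCatch(
    as.numeric(x - t(A) %*% qr.solve(A %*% t(A), as.numeric(A %*% x - b))),
    error = function(e) NULL
  )
  if (!is.null(x_try) && is.finite(obj$f(x_try)) &&
      all(ui %*% x_try - ci >= -1e-9)) {
    x <- x_try
  }
  list(x = x, value = obj$f(x), grad = obj$g(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
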