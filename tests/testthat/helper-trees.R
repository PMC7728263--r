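# Shared fixtures and independent oracles, all built in code.

# random rooted tree on n mutation nodes with bounded outdegree
random_tree <- function(n, max_degree = 4L) {
  repeat {
    parent <- vapply(seq_len(n), function(i) sample(0:(i - 1), 1L), integer(1))
    tr <- mutation_tree(parent)
    if (max(tr$outdegree) <= max_degree) return(tr)
  }
}

# random strictly feasible times for a tree under node-index sibling order
random_valid_times <- function(tree, horizon = 1) {
  n <- n_mutations(tree)
  repeat {
    t <- c(0, sort(runif(n, 0, horizon)))
    ok <- TRUE
    for (i in seq_len(n)) {
      if (t[i + 1L] <= t[tree$parent[i + 1L] + 1L]) { ok <- FALSE; break }
    }
    if (ok) {
      gaps <- unlist(clonerate:::sibling_gaps(tree, t, default_orderings(tree)))
      if (all(gaps > 0)) return(t)
    }
  }
}

# independent golden-section maximizer (oracle for the s = 0 profile fit)
golden_max <- function(f, lo, hi, tol = 1e-7) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    }
  }
  list(x = (a + b) / 2, value = f((a + b) / 2))
}

# parent vector in mutation-label space: entry j is the label index of the
# parent of mutation "Mj" (0 for the root); comparable across trees whose
# nodes carry permuted labels
label_space_parent <- function(tree) {
  n <- n_mutations(tree)
  idx <- as.integer(sub("M", "", tree$label[-1]))
  out <- integer(n)
  for (i in seq_len(n)) {
    p <- tree$parent[i + 1]
    out[idx[i]] <- if (p == 0) 0L else idx[p]
  }
  out
}

# enumerate all rooted trees (parent vectors) on m mutation nodes
all_parent_vectors <- function(m) {
  grids <- rep(list(0:m), m)
  grid <- do.call(expand.grid, grids)
  out <- list()
  for (r in seq_len(nrow(grid))) {
    p <- as.integer(grid[r, ])
    tr <- tryCatch(mutation_tree(p), error = function(e) NULL)
    if (!is.null(tr)) out[[length(out) + 1L]] <- tr
  }
  out
}
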