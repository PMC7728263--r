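#' Construct a mutation tree
#'
#' A mutation tree is a rooted labeled tree whose non-root nodes are mutation
#' events; node 0 is always the unlabeled wild-type root.  A clone's genotype
#' (mutation profile) is the set of mutations on its path to the root.  Trees
#' may violate the infinite-sites assumption: labels can repeat (recurrent
#' mutations) and a node can be flagged as a loss event, which removes a
#' previously gained label from the profile.
#'
#' @param parent integer vector of length `n`; `parent[i]` is the parent node
#'   of mutation node `i` (node ids are 0-based, 0 denotes the root).
#' @param label optional character vector of length `n` with mutation names
#'   for nodes `1..n`; defaults to `"M1".."Mn"`.
#' @param loss optional logical vector of length `n`; `TRUE` marks a mutation
#'   loss event for the node's label.
#' @return an object of class `mutation_tree` with fields `parent`, `label`,
#'   `loss` (each indexed by node id + 1), plus derived `children` and
#'   `outdegree`.
#' @examples
#' tr <- mutation_tree(c(0L, 1L, 1L))
#' tr
#' as_tibble(tr)
#' @export
mutation_tree <- function(parent, label = NULL, loss = NULL) {
  parent <- as.integer(parent)
  n <- length(parent) # n = 0 gives the root-only tree
  if (anyNA(parent) || any(parent < 0L) || any(parent > n)) {
    stop("malformed tree: parent ids must be in 0..n")
  }
  if (is.null(label)) {
    label <- if (n) paste0("M", seq_len(n)) else character(0)
  }
  label <- as.character(label)
  if (length(label) != n) stop("label must have one entry per mutation node")
  if (is.null(loss)) loss <- rep(FALSE, n)
  loss <- as.logical(loss)
  if (length(loss) != n || anyNA(loss)) stop("loss must be logical of length n")

  tr <- structure(
    list(
      parent = c(NA_integer_, parent), # index = node id + 1
      label = c(NA_character_, label),
      loss = c(FALSE, loss)
    ),
    class = "mutation_tree"
  )
  tr$children <- build_children(tr)
  tr$outdegree <- lengths(tr$children)
  validate_mutation_tree(tr)
  tr
}

build_children <- function(tr) {
  n1 <- length(tr$parent)
  ch <- vector("list", n1)
  for (i in seq_len(n1)) ch[[i]] <- integer(0)
  for (i in seq_len(n1 - 1L)) { # nodes 1..n
    p <- tr$parent[i + 1L]
    ch[[p + 1L]] <- c(ch[[p + 1L]], i)
  }
  ch
}

validate_mutation_tree <- function(tr) {
  n <- n_mutations(tr)
  # connectivity/acyclicity: BFS from root must reach all n+1 nodes exactly once
  seen <- rep(FALSE, n + 1L)
  queue <- 0L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- tr$children[[v + 1L]]
    if (any(seen[kids + 1L])) stop("malformed tree: node visited twice")
    seen[kids + 1L] <- TRUE
    queue <- c(queue, kids)
  }
  if (!all(seen)) stop("malformed tree: cycle or disconnected nodes")
  stopifnot(sum(tr$outdegree) == n)
  invisible(tr)
}

#' Number of mutation nodes (excluding the root)
#' @param tree a `mutation_tree`
#' @return integer `n`
#' @export
n_mutations <- function(tree) length(tree$parent) - 1L

#' @export
print.mutation_tree <- function(x, ...) {
  n <- n_mutations(x)
  cat(sprintf(
    "<mutation_tree> %d mutation nodes + root; max outdegree %d%s\n",
    n, max(x$outdegree),
    if (any(x$loss)) sprintf("; %d loss events", sum(x$loss)) else ""
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble tibble
#' @exportS3Method tibble::as_tibble
as_tibble.mutation_tree <- function(x, ...) {
  n <- n_mutations(x)
  tibble::tibble(
    node = 0:n,
    parent = x$parent,
    label = x$label,
    loss = x$loss,
    outdegree = as.integer(x$outdegree)
  )
}

#' Nodes of the subtree rooted at `k` (closed descendant set)
#' @param tree a `mutation_tree`
#' @param k node id
#' @return integer vector of node ids, preorder, starting with `k`
#' @export
subtree_nodes <- function(tree, k) {
  out <- integer(0)
  stack <- as.integer(k)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- tree$children[[v + 1L]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

#' Subtree sizes n_k for every node
#' @param tree a `mutation_tree`
#' @return integer vector indexed by node id + 1
#' @export
subtree_sizes <- function(tree) {
  n <- n_mutations(tree)
  sz <- rep(1L, n + 1L)
  ord <- postorder_nodes(tree)
  for (v in ord) {
    kids <- tree$children[[v + 1L]]
    if (length(kids)) sz[v + 1L] <- 1L + sum(sz[kids + 1L])
  }
  sz
}

# children-before-parents traversal order
postorder_nodes <- function(tree) {
  pre <- subtree_nodes(tree, 0L)
  rev(pre)
}

#' Mutation profiles of all clones
#'
#' The profile of node `i` is obtained by walking the path from the root to
#' `i`, adding each gained label and removing each lost label.  Losing a label
#' that is not currently present is an inconsistent history and raises an
#' error.
#'
#' @param tree a `mutation_tree`
#' @return a named list (names `"0".."n"`) of character vectors
#' @examples
#' tr <- mutation_tree(c(0L, 1L), label = c("A", "B"))
#' mutation_profiles(tr)[["2"]]
#' @export
mutation_profiles <- function(tree) {
  n <- n_mutations(tree)
  prof <- vector("list", n + 1L)
  prof[[1L]] <- character(0)
  for (v in subtree_nodes(tree, 0L)) {
    if (v == 0L) next
    p <- prof[[tree$parent[v + 1L] + 1L]]
    lab <- tree$label[v + 1L]
    if (tree$loss[v + 1L]) {
      if (!lab %in% p) stop("inconsistent loss event: label '", lab,
                            "' lost at node ", v, " but absent on its path")
      p <- setdiff(p, lab)
    } else {
      p <- union(p, lab)
    }
    prof[[v + 1L]] <- p
  }
  names(prof) <- as.character(0:n)
  prof
}

# ---------------------------------------------------------------------------
# text formats

#' Read a mutation tree from text
#'
#' Two dialects are supported for interoperability with single-cell tree
#' callers: `"parent_vector"` is a whitespace/comma separated list
#' `p_1 ... p_n` where `p_i` is the parent node of mutation node `i`
#' (0 denotes the root); `"dot"` is a GraphViz digraph whose edges point from
#' parent to child, with optional `label="..."` node attributes.  If the DOT
#' root itself carries a mutation label, a synthetic wild-type root 0 is
#' inserted above it.
#'
#' @param source a file path or a character string with the tree text
#' @param dialect `"parent_vector"` or `"dot"`
#' @return a `mutation_tree`
#' @examples
#' read_mutation_tree("0 1 1", dialect = "parent_vector")
#' read_mutation_tree("digraph{0->1;0->2;}", dialect = "dot")
#' @export
read_mutation_tree <- function(source, dialect = c("parent_vector", "dot")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unsupported format"))
  txt <- read_source_text(source)
  switch(dialect,
    parent_vector = parse_parent_vector(txt),
    dot = parse_dot_tree(txt)
  )
}

read_source_text <- function(source) {
  if (length(source) == 1L && !grepl("[\n;{]", source) && file.exists(source)) {
    return(paste(readLines(source, warn = FALSE), collapse = "\n"))
  }
  paste(source, collapse = "\n")
}

parse_parent_vector <- function(txt) {
  toks <- strsplit(trimws(txt), "[,[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("malformed tree: empty parent vector")
  p <- suppressWarnings(as.integer(toks))
  if (anyNA(p)) stop("malformed tree: non-integer parent entry")
  mutation_tree(p)
}

parse_dot_tree <- function(txt) {
  if (!grepl("digraph", txt)) stop("unsupported format: not a digraph")
  body <- sub("^.*?\\{", "", txt)
  body <- sub("\\}[^}]*$", "", body)
  stmts <- trimws(strsplit(body, "[;\n]")[[1]])
  stmts <- stmts[nzchar(stmts)]
  edges <- list()
  labels <- character(0)
  get_label <- function(s) {
    m <- regmatches(s, regexec('label\\s*=\\s*"([^"]*)"', s))[[1]]
    if (length(m) == 2L) return(m[2])
    m <- regmatches(s, regexec("label\\s*=\\s*([^,\\]\\s]+)", s))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  for (s in stmts) {
    if (grepl("->", s)) {
      parts <- strsplit(s, "->")[[1]]
      parts <- gsub("\\[.*\\]", "", parts)
      parts <- gsub("\"", "", trimws(parts))
      for (k in seq_len(length(parts) - 1L)) {
        edges[[length(edges) + 1L]] <- c(parts[k], parts[k + 1L])
      }
    } else if (grepl("\\[", s) && grepl("label", s)) {
      nm <- gsub("\"", "", trimws(sub("\\[.*$", "", s)))
      labels[nm] <- get_label(s)
    }
  }
  if (!length(edges)) stop("malformed tree: no edges in digraph")
  em <- do.call(rbind, edges)
  roots <- unique(setdiff(em[, 1], em[, 2]))
  if (length(roots) != 1L) stop("malformed tree: digraph must have one root")
  root <- roots
  # the root is wild type when unlabeled or labeled as such; a mutation label
  # on the DOT root triggers re-rooting under a synthetic node 0
  root_lab <- labels[root]
  wildtype <- is.na(root_lab) || !nzchar(root_lab) ||
    tolower(root_lab) %in% c("wt", "root", "normal", "wildtype", "wild-type")
  ord <- dot_bfs_order(root, em)
  if (wildtype) {
    inner <- ord[-1L]
    # keep numeric node names as ids when they already form 0..n
    if (all(grepl("^[0-9]+$", ord)) && root == "0" &&
        setequal(as.integer(inner), seq_along(inner))) {
      ids <- stats::setNames(as.integer(ord), ord)
    } else {
      ids <- stats::setNames(seq_along(ord) - 1L, ord)
    }
    n <- length(ord) - 1L
  } else {
    ids <- stats::setNames(seq_along(ord), ord) # every DOT node is a mutation
    n <- length(ord)
  }
  parent <- integer(n)
  for (k in seq_len(nrow(em))) {
    parent[ids[[em[k, 2]]]] <- ids[[em[k, 1]]]
  }
  if (!wildtype) parent[ids[[root]]] <- 0L
  muts <- names(ids)[match(seq_len(n), ids)]
  lab <- ifelse(is.na(labels[muts]) | !nzchar(labels[muts]), muts, labels[muts])
  loss <- grepl("_loss$", lab)
  lab <- sub("_loss$", "", lab)
  mutation_tree(parent, label = unname(lab), loss = loss)
}

dot_bfs_order <- function(root, em) {
  ord <- root
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- em[em[, 1] == v, 2]
    if (any(kids %in% ord)) stop("malformed tree: node with multiple parents or cycle")
    ord <- c(ord, kids)
    queue <- c(queue, kids)
  }
  ord
}

#' Write a mutation tree as text
#'
#' @param tree a `mutation_tree`
#' @param path optional output file; if `NULL` the text is returned
#' @param dialect `"parent_vector"` or `"dot"`
#' @param rates optional numeric vector (node id + 1 indexed) of mutation
#'   rates; when given, DOT nodes are filled on a green (low) to orange
#'   (high) ramp.
#' @return the text, invisibly when written to `path`
#' @export
write_mutation_tree <- function(tree, path = NULL,
                                dialect = c("parent_vector", "dot"),
                                rates = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unsupported format"))
  n <- n_mutations(tree)
  txt <- if (dialect == "parent_vector") {
    paste(tree$parent[-1L], collapse = " ")
  } else {
    dot_text(tree, rates)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

dot_text <- function(tree, rates = NULL) {
  n <- n_mutations(tree)
  lines <- "digraph G {"
  fill <- rep(NA_character_, n + 1L)
  if (!is.null(rates)) {
    r <- rates
    rng <- range(r[-1L], na.rm = TRUE)
    z <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else rep(0.5, length(r))
    ramp <- grDevices::colorRamp(c("#2ca02c", "#ff7f0e")) # green -> orange
    ok <- !is.na(z)
    cols <- rep(NA_character_, length(r))
    cols[ok] <- grDevices::rgb(ramp(pmin(pmax(z[ok], 0), 1)), maxColorValue = 255)
    fill <- cols
  }
  for (i in 0:n) {
    lab <- if (i == 0L) "WT" else {
      paste0(tree$label[i + 1L], if (tree$loss[i + 1L]) "_loss" else "")
    }
    attrs <- sprintf("label=\"%s\"", lab)
    if (!is.na(fill[i + 1L])) {
      attrs <- paste0(attrs, sprintf(", style=filled, fillcolor=\"%s\"", fill[i + 1L]))
    }
    lines <- c(lines, sprintf("  %d [%s];", i, attrs))
  }
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("  %d -> %d;", tree$parent[i + 1L], i))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Export the timed binary phylogeny as a Newick string
#'
#' Given sibling orderings and event times, the mutation tree corresponds to a
#' binary phylogeny of clone-birth events: along clone `i`'s lineage each
#' ordered child splits off at its birth time, and the lineage terminates in a
#' leaf sampled at time `H`.  Leaf names are node ids; branch lengths are time
#' differences (leaf branches `H - t`).
#'
#' @param tree a `mutation_tree`
#' @param times numeric vector of birth times indexed by node id + 1 (`times[1] = 0`)
#' @param horizon sampling time `H`
#' @param sigma ordering family: list indexed by node id + 1 of child ids in
#'   birth order (see [best_orderings()])
#' @return a Newick string
#' @export
as_newick <- function(tree, times, horizon, sigma) {
  lineage <- function(i, idx, t_cur) {
    kids <- sigma[[i + 1L]]
    if (idx > length(kids)) {
      return(sprintf("%d:%.10g", i, horizon - t_cur))
    }
    cj <- kids[idx]
    tj <- times[cj + 1L]
    sprintf("(%s,%s):%.10g",
            lineage(cj, 1L, tj),
            lineage(i, idx + 1L, tj),
            tj - t_cur)
  }
  # the trailing length is the root stalk from t = 0 to the first split
  paste0(lineage(0L, 1L, 0), ";")
}

# ---------------------------------------------------------------------------
# genotype matrices

#' Construct a genotype matrix
#'
#' Binary single-cell genotype observations (rows = cells, columns =
#' mutations) with entry 3 denoting missing data, plus the error rates of the
#' standard single-cell model: `alpha` is the false-negative (allelic dropout)
#' rate and `beta` the false-positive rate.
#'
#' @param data integer matrix with entries in {0, 1, 3}
#' @param alpha false-negative rate in \[0, 1\]
#' @param beta false-positive rate in \[0, 1\]
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(data, alpha = 0, beta = 0) {
  data <- as.matrix(data)
  if (!nrow(data)) stop("no cells")
  if (!all(data %in% c(0L, 1L, 3L))) stop("invalid genotype code")
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  structure(list(data = data, alpha = alpha, beta = beta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d cells x %d mutations (alpha=%g, beta=%g)\n",
              nrow(x$data), ncol(x$data), x$alpha, x$beta))
  invisible(x)
}

#' Read / write genotype matrices
#'
#' Plain-text dialect: one row per cell, one space-separated 0/1 column per
#' mutation, `3` marking missing entries.  With `scite = TRUE` the file is in
#' the transposed orientation used by SCITE-family tools (rows = mutations).
#'
#' @param source file path or text
#' @param alpha,beta error rates attached to the returned object
#' @param scite transpose on read/write
#' @return a `genotype_matrix`
#' @export
read_genotype_matrix <- function(source, alpha = 0, beta = 0, scite = FALSE) {
  txt <- read_source_text(source)
  rows <- strsplit(trimws(txt), "\n")[[1]]
  rows <- rows[nzchar(trimws(rows))]
  if (!length(rows)) stop("no cells")
  parsed <- lapply(rows, function(r) {
    toks <- strsplit(trimws(r), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.integer(toks))
    if (anyNA(v) || !all(v %in% c(0L, 1L, 3L))) stop("invalid genotype code")
    v
  })
  if (length(unique(lengths(parsed))) != 1L) stop("ragged genotype matrix")
  m <- do.call(rbind, parsed)
  if (scite) m <- t(m)
  genotype_matrix(m, alpha = alpha, beta = beta)
}

#' @rdname read_genotype_matrix
#' @param gm a `genotype_matrix`
#' @param path optional output file
#' @export
write_genotype_matrix <- function(gm, path = NULL, scite = FALSE) {
  m <- gm$data
  if (scite) m <- t(m)
  txt <- paste(apply(m, 1L, paste, collapse = " "), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
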