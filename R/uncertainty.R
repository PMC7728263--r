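# Rate-uncertainty quantification: run the landscape solver over mutation
# trees sampled from a posterior given the noisy genotype matrix, and pool
# the inferred rates by mutation label.  The built-in sampler is a minimal
# Metropolis chain over tree topologies (prune-and-reattach moves, uniform
# tree prior, standard false-negative/false-positive genotype likelihood with
# the best-matching attachment per cell); externally reconstructed trees can
# be supplied instead.

#' Log-likelihood of a genotype matrix given a mutation tree
#'
#' Standard single-cell error model: a true genotype 1 is observed as 0 with
#' probability `alpha` (dropout) and a true 0 as 1 with probability `beta`;
#' missing entries (code 3) are skipped.  Each cell is attached to its
#' best-matching clone profile.
#'
#' @param tree a `mutation_tree` whose labels are `"M1".."Mm"` matching the
#'   matrix columns
#' @param gm a `genotype_matrix`
#' @return total log-likelihood over cells
#' @export
genotype_log_lik <- function(tree, gm) {
  sum(cell_attachment_scores(tree, gm))
}

cell_attachment_scores <- function(tree, gm) {
  D <- gm$data
  m <- ncol(D)
  prof <- mutation_profiles(tree)
  G <- t(vapply(prof, function(p) as.integer(paste0("M", seq_len(m)) %in% p),
                integer(m))) # clones x mutations
  NEG <- -1e9 # stands for log(0); detected below
  lg <- function(x) ifelse(x > 0, log(x), NEG)
  A1 <- (D == 1L) + 0; A0 <- (D == 0L) + 0 # missing contributes to neither
  S <- A1 %*% t(G) * lg(1 - gm$alpha) +
    A1 %*% t(1 - G) * lg(gm$beta) +
    A0 %*% t(G) * lg(gm$alpha) +
    A0 %*% t(1 - G) * lg(1 - gm$beta)
  best <- apply(S, 1L, max)
  if (any(best < NEG / 2)) {
    stop("degenerate data: a cell is impossible under every clone profile")
  }
  best
}

#' Sample mutation trees from the genotype posterior
#'
#' Metropolis chain over rooted mutation trees on the matrix's mutations:
#' each move detaches a random subtree and reattaches it below a node outside
#' it (a symmetric proposal), accepted by the ratio of genotype likelihoods
#' under a uniform tree prior.  The chain starts from the star tree.
#'
#' @param gm a `genotype_matrix`
#' @param n_samples trees to return (post burn-in, thinned)
#' @param burn_in discarded initial moves
#' @param thin keep every `thin`-th state after burn-in
#' @param seed RNG seed
#' @return a list of `mutation_tree` objects
#' @examples
#' \donttest{
#' truth <- simulate_tumor(m = 6, seed = 1)
#' gm <- add_noise(truth, alpha = 0.05, beta = 1e-3, copies = 5, seed = 2)
#' trees <- sample_trees(gm, n_samples = 10, burn_in = 50, seed = 3)
#' }
#' @export
sample_trees <- function(gm, n_samples = 100L, burn_in = 200L, thin = 10L,
                         seed = 0L) {
  m <- ncol(gm$data)
  if (!nrow(gm$data) || all(gm$data == 3L)) stop("degenerate data")
  withr_seed(seed, {
    parent <- rep(0L, m) # star start
    tree <- mutation_tree(parent)
    cur <- genotype_log_lik(tree, gm)
    out <- vector("list", n_samples)
    got <- 0L
    it <- 0L
    while (got < n_samples) {
      it <- it + 1L
      v <- sample.int(m, 1L)
      sub <- subtree_nodes(tree, v)
      targets <- setdiff(0:m, sub)
      u <- targets[sample.int(length(targets), 1L)]
      parent_new <- parent
      parent_new[v] <- u
      tree_new <- mutation_tree(parent_new, label = tree$label[-1L])
      prop <- genotype_log_lik(tree_new, gm)
      if (stats::runif(1) < exp(min(0, prop - cur))) {
        parent <- parent_new; tree <- tree_new; cur <- prop
      }
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        got <- got + 1L
        out[[got]] <- tree
      }
    }
    out
  })
}

#' Posterior distribution of clone mutation rates over sampled trees
#'
#' Runs the EM landscape solver on every sampled tree and pools the inferred
#' rates by mutation label (node indices are not comparable across
#' topologies; labels are).  Only internal nodes contribute (leaf rates are
#' not estimated).  Trees on which the solver fails are dropped with a
#' warning.
#'
#' @param trees a list of `mutation_tree` objects, or a directory containing
#'   parent-vector (`.txt`) / DOT (`.dot`, `.gv`) tree files
#' @param theta_min,theta_max feasible rate box
#' @param theta0 fixed root rate passed to [infer_rates()]
#' @param control ordering-search control passed to [infer_rates()]
#' @param ... further arguments for [infer_rates()]
#' @return an object of class `rate_posterior`: a tibble with one row per
#'   mutation label: `label`, `n` (trees where the label was internal),
#'   `mean`, `se` (population standard deviation of the sampled rates), and
#'   `rel_se` (`se/mean`)
#' @export
rate_posterior <- function(trees, theta_min, theta_max,
                           theta0 = (theta_min + theta_max) / 2,
                           control = list(), ...) {
  if (is.character(trees)) trees <- read_tree_dir(trees)
  stopifnot(length(trees) >= 1L)
  samples <- purrr::imap(trees, function(tr, i) {
    fit <- tryCatch(
      infer_rates(tr, theta_min, theta_max, theta0 = theta0,
                  control = control, ...),
      error = function(e) {
        warning("solver failed on sampled tree ", i, ": ",
                conditionMessage(e))
        NULL
      }
    )
    if (is.null(fit)) return(NULL)
    internal <- which(tr$outdegree[-1L] >= 1L)
    tibble::tibble(label = tr$label[internal + 1L],
                   rate = fit$theta[internal + 1L])
  })
  pooled <- dplyr::bind_rows(samples[!vapply(samples, is.null, logical(1))])
  if (!nrow(pooled)) stop("no sampled tree could be fitted")
  out <- pooled |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$rate),
      se = sqrt(mean((.data$rate - mean(.data$rate))^2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(rel_se = .data$se / .data$mean)
  class(out) <- c("rate_posterior", class(out))
  out
}

read_tree_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(txt|tsv|dot|gv)$",
                      full.names = TRUE)
  if (!length(files)) stop("no tree files found in ", path)
  lapply(files, function(f) {
    dialect <- if (grepl("\\.(dot|gv)$", f)) "dot" else "parent_vector"
    read_mutation_tree(f, dialect = dialect)
  })
}
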