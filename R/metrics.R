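# Accuracy metrics for recovery studies and model-selection statistics.

#' Mean absolute percentage accuracy
#'
#' `MAPA = 1 - MAPE`, where MAPE is the mean of `|estimate - truth| /
#' |truth|`.  Can be negative for very poor estimates; reported as-is.
#'
#' @param estimate,truth numeric vectors of equal length (truth nonzero)
#' @return a single accuracy value
#' @examples
#' mapa(c(2, 4), c(4, 4)) # 0.75
#' @export
mapa <- function(estimate, truth) {
  if (!length(estimate)) stop("nothing to score")
  stopifnot(length(estimate) == length(truth), all(truth != 0))
  1 - mean(abs(estimate - truth) / abs(truth))
}

#' Sibling-order accuracy
#'
#' For every node with outdegree at least 2, computes the Kendall tau
#' distance (number of discordant child pairs) between the estimated and the
#' true birth order, normalized by the number of pairs `d (d - 1) / 2`;
#' accuracy is one minus the mean normalized distance over qualifying nodes.
#'
#' @param sigma_est,sigma_true ordering families over the same tree
#' @return a single accuracy value in \[0, 1\]
#' @examples
#' order_accuracy(list(integer(0), 1:2), list(integer(0), 1:2))
#' @export
order_accuracy <- function(sigma_est, sigma_true) {
  stopifnot(length(sigma_est) == length(sigma_true))
  dists <- purrr::map_dbl(seq_along(sigma_true), function(i) {
    kids <- sigma_true[[i]]
    d <- length(kids)
    if (d < 2L) return(NA_real_)
    if (!setequal(kids, sigma_est[[i]])) {
      stop("ordering families disagree on the children of node ", i - 1L)
    }
    p <- match(sigma_est[[i]], kids) # positions of estimated order in truth
    disc <- sum(vapply(seq_len(d - 1L), function(a) {
      sum(p[(a + 1L):d] < p[a])
    }, numeric(1)))
    disc / choose(d, 2)
  })
  dists <- dists[!is.na(dists)]
  if (!length(dists)) stop("nothing to score")
  1 - mean(dists)
}

#' Compare a richer rate model against a simpler one
#'
#' Given maximum log-likelihoods `L1` (simpler model, `k1` parameters) and
#' `L2` (richer model, `k2` parameters) on a tree with `n` vertices, computes
#' the Bayes factor `BF = exp(L2 - L1)` and the information-criterion
#' differences
#' `dAIC = 2 (k1 - k2) + 2 (L2 - L1)` and
#' `dBIC = (k1 - k2) log(n) + 2 (L2 - L1)`.
#' Larger positive values favor the richer model.
#'
#' @param L1,L2 maximum log-likelihoods of the two models
#' @param k1,k2 parameter counts (defaults 1 and 3: one global rate vs two
#'   rates plus one change-point)
#' @param n number of tree vertices (sample size for BIC)
#' @return a one-row tibble: `bf`, `log_bf`, `delta_aic`, `delta_bic`,
#'   `k1`, `k2`, `n`
#' @examples
#' model_compare(L1 = 0, L2 = log(5.037e3), n = 20)
#' @export
model_compare <- function(L1, L2, k1 = 1, k2 = 3, n) {
  stopifnot(n >= 1)
  tibble::tibble(
    bf = exp(L2 - L1),
    log_bf = L2 - L1,
    delta_aic = 2 * (k1 - k2) + 2 * (L2 - L1),
    delta_bic = (k1 - k2) * log(n) + 2 * (L2 - L1),
    k1 = k1, k2 = k2, n = n
  )
}
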