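# ggplot2 views of fitted landscapes: the timed binary phylogeny with
# branches colored by clone mutation rate, and posterior rate summaries.

phylo_segments <- function(tree, theta, times, horizon, sigma) {
  n <- n_mutations(tree)
  # leaf order of the binary phylogeny: recursive left-to-right
  ypos <- numeric(n + 1L)
  counter <- new.env()
  assign("y", 0, envir = counter)
  walk <- function(i, idx) {
    kids <- sigma[[i + 1L]]
    if (idx <= length(kids)) {
      walk(kids[idx], 1L)
      walk(i, idx + 1L)
    } else {
      y <- get("y", envir = counter) + 1
      assign("y", y, envir = counter)
      ypos[i + 1L] <<- y
    }
  }
  walk(0L, 1L)
  horiz <- tibble::tibble(
    node = 0:n,
    label = ifelse(0:n == 0L, "WT", tree$label),
    rate = theta,
    x = times, xend = rep(horizon, n + 1L),
    y = ypos[1:(n + 1L)], yend = ypos[1:(n + 1L)]
  )
  vert <- purrr::map_dfr(0:n, function(i) {
    kids <- sigma[[i + 1L]]
    if (!length(kids)) return(NULL)
    tibble::tibble(node = i, rate = theta[i + 1L],
                   x = times[kids + 1L], xend = times[kids + 1L],
                   y = ypos[i + 1L], yend = ypos[kids + 1L])
  })
  list(horiz = horiz, vert = vert)
}

#' Plot a fitted mutability landscape
#'
#' Draws the timed binary phylogeny implied by the fit: one horizontal
#' lineage per clone from its birth time to the sampling time `H`, colored
#' by the inferred mutation rate (green = low, orange = high), with birth
#' events as vertical connectors.
#'
#' @param object a `clonerate_fit`
#' @param ... unused
#' @return a ggplot object
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.clonerate_fit <- function(object, ...) {
  seg <- phylo_segments(object$tree, object$theta, object$times,
                        object$horizon, object$sigma)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg$vert,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend, colour = .data$rate),
      linewidth = 0.4
    ) +
    ggplot2::geom_segment(
      data = seg$horiz,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend, colour = .data$rate),
      linewidth = 0.8
    ) +
    ggplot2::geom_text(
      data = seg$horiz,
      ggplot2::aes(x = .data$xend, y = .data$y, label = .data$label),
      hjust = -0.1, size = 2.8
    ) +
    ggplot2::scale_colour_gradient(low = "#2ca02c", high = "#ff7f0e") +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.08))) +
    ggplot2::labs(x = "time", y = NULL, colour = "rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' @export
plot.clonerate_fit <- function(x, ...) print(autoplot.clonerate_fit(x, ...))

#' Plot a posterior rate summary
#'
#' @param object a `rate_posterior`
#' @param ... unused
#' @return a ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.rate_posterior <- function(object, ...) {
  df <- as.data.frame(object)
  df$label <- stats::reorder(df$label, df$mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$label)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$mean - .data$se, xmax = .data$mean + .data$se)
    ) +
    ggplot2::labs(x = "posterior mutation rate (mean ± se)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.rate_posterior <- function(x, ...) print(autoplot.rate_posterior(x, ...))
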