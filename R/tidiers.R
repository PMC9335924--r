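#' Tidy a fitted decomposition into a long score table
#'
#' @param x A `tdaign_fit` or `cp_fit`.
#' @param ... Unused.
#' @return A tibble with columns `mirna`, `disease`, `type`, `score`,
#'   sorted by descending score.
#' @method tidy tdaign_fit
#' @export
tidy.tdaign_fit <- function(x, ...) tidy_scores(x)

#' @rdname tidy.tdaign_fit
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, ...) {
  s <- x$scores
  if (is.null(dimnames(s)) || any(vapply(dimnames(s), is.null, logical(1)))) {
    dimnames(s) <- lapply(dim(s), function(n) as.character(seq_len(n)))
  }
  tidy_scores(s)
}

#' One-row summary of a fitted decomposition
#'
#' @param x A `tdaign_fit` or `cp_fit`.
#' @param ... Unused.
#' @method glance tdaign_fit
#' @export
glance.tdaign_fit <- function(x, ...) {
  tibble::tibble(
    rank = x$config$rank,
    rank_prime = x$config$rank_prime,
    episodes = x$config$episodes,
    episodes_converged = sum(x$converged),
    sweeps = nrow(x$trace),
    objective = x$trace$objective[nrow(x$trace)],
    n_weighted = x$trace$n_weighted[nrow(x$trace)]
  )
}

#' @rdname glance.tdaign_fit
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  tibble::tibble(
    rank = x$rank,
    iterations = nrow(x$trace),
    objective = x$trace$objective[nrow(x$trace)],
    fit = tail_fit(x),
    converged = x$converged
  )
}

#' Plot the optimization trace of a fit
#'
#' Objective value per inner sweep, panelled by episode for the weighted
#' model (each episode restarts after a weight-tensor refresh).
#'
#' @param object A `tdaign_fit` or `cp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tdaign_fit
#' @export
autoplot.tdaign_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$sweep, y = .data$objective,
                               colour = factor(.data$episode))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "inner sweep", y = "objective",
                  colour = "episode") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tdaign_fit
#' @method autoplot cp_fit
#' @export
autoplot.cp_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ALS sweep", y = "squared residual") +
    ggplot2::theme_minimal()
}

#' Heatmap of predicted type scores for selected pairs
#'
#' @param scores A `tdaign_fit`, `cp_fit` or labeled score array.
#' @param pairs Optional data frame (`mirna`, `disease`) restricting the
#'   plot; default all pairs.
#' @return A ggplot tiling miRNA-disease pairs against types.
#' @export
plot_type_scores <- function(scores, pairs = NULL) {
  df <- tidy_scores(scores)
  if (!is.null(pairs)) {
    df <- dplyr::semi_join(df, tibble::as_tibble(pairs),
                           by = c("mirna", "disease"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type,
                                   y = paste(.data$mirna, .data$disease, sep = " / "),
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "association type", y = "miRNA / disease pair",
                  fill = "score") +
    ggplot2::theme_minimal()
}
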