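#' Configuration for the weighted tensor-decomposition model
#'
#' Collects every hyperparameter of the regularized objective and its ADMM
#' solver.  Defaults are the values selected by 5-fold cross-validated grid
#' search in the original study of the method.
#'
#' @param alpha Per-view weights \eqn{\alpha_i} for the miRNA similarity
#'   views (recycled to the number of views at fit time).  Default
#'   \eqn{2^{-2} = 0.25}.
#' @param beta Per-view weights \eqn{\beta_j} for the disease similarity
#'   views.  Default 0.25.
#' @param lambda Ridge penalty on the factor matrices.  Default 0.001.
#' @param rank CP rank \eqn{r} of the association tensor.  Default 8.
#' @param rank_prime Embedding rank \eqn{r'} of the similarity
#'   factorizations; must be smaller than both entity counts.  Default 20.
#' @param weight Weight \eqn{w \ge 1} given to poorly reconstructed positive
#'   triplets.  Default 1.5.
#' @param k Loss threshold in (0, 1): a positive triplet whose squared
#'   residual exceeds \eqn{(1-k)^2} is up-weighted.  Default 0.3.
#' @param episodes Number of weight-refresh rounds; each episode runs the
#'   inner alternating/ADMM loop to its stopping condition and then updates
#'   the weight tensor.  Default 4.
#' @param mu,gamma,eta,epsilon ADMM penalty parameters for the four variable
#'   splits `C = A`, `F = A`, `E = B`, `G = B`.  Default 1.
#' @param inner_tol Relative objective-change tolerance of the inner loop.
#'   Default 1e-5.
#' @param inner_max_iter Maximum inner sweeps per episode.  Default 200.
#' @param use_weighting If `FALSE` the weight tensor stays all-ones (the
#'   unweighted TDAIGN ablation).
#' @param use_l21 If `FALSE` the L2,1 penalty on the projection matrices is
#'   dropped.
#' @param use_laplacian If `FALSE` the graph-Laplacian penalty is dropped.
#'   `use_l21 = FALSE` together with `use_laplacian = FALSE` is the TDAI
#'   ablation.
#' @param seed Integer seed for the uniform(0,1) initialization.
#'
#' @return A list of class `tdaign_config`.
#' @export
tdaign_config <- function(alpha = 0.25, beta = 0.25, lambda = 0.001,
                          rank = 8, rank_prime = 20,
                          weight = 1.5, k = 0.3, episodes = 4,
                          mu = 1, gamma = 1, eta = 1, epsilon = 1,
                          inner_tol = 1e-5, inner_max_iter = 200,
                          use_weighting = TRUE, use_l21 = TRUE,
                          use_laplacian = TRUE, seed = NULL) {
  cfg <- list(
    alpha = as.numeric(alpha), beta = as.numeric(beta), lambda = lambda,
    rank = as.integer(rank), rank_prime = as.integer(rank_prime),
    weight = weight, k = k, episodes = as.integer(episodes),
    mu = mu, gamma = gamma, eta = eta, epsilon = epsilon,
    inner_tol = inner_tol, inner_max_iter = as.integer(inner_max_iter),
    use_weighting = isTRUE(use_weighting), use_l21 = isTRUE(use_l21),
    use_laplacian = isTRUE(use_laplacian), seed = seed
  )
  if (any(cfg$alpha < 0) || any(cfg$beta < 0)) {
    abort("`alpha` and `beta` must be nonnegative.", class = "tdaign_input_error")
  }
  if (cfg$lambda < 0) abort("`lambda` must be >= 0.", class = "tdaign_input_error")
  if (cfg$weight < 1) abort("`weight` must be >= 1.", class = "tdaign_input_error")
  if (cfg$k <= 0 || cfg$k >= 1) abort("`k` must lie in (0, 1).", class = "tdaign_input_error")
  if (cfg$rank < 1 || cfg$rank_prime < 1 || cfg$episodes < 1) {
    abort("`rank`, `rank_prime` and `episodes` must be >= 1.", class = "tdaign_input_error")
  }
  for (p in c("mu", "gamma", "eta", "epsilon")) {
    if (cfg[[p]] <= 0) abort(sprintf("`%s` must be positive.", p), class = "tdaign_input_error")
  }
  structure(cfg, class = "tdaign_config")
}

#' @export
print.tdaign_config <- function(x, ...) {
  cat(sprintf(
    paste0("<tdaign_config> r = %d, r' = %d, alpha = %s, beta = %s, lambda = %g,\n",
           "  w = %g, k = %g, episodes = %d, weighting %s, L2,1 %s, Laplacian %s\n"),
    x$rank, x$rank_prime,
    paste(x$alpha, collapse = "/"), paste(x$beta, collapse = "/"), x$lambda,
    x$weight, x$k, x$episodes,
    if (x$use_weighting) "on" else "off",
    if (x$use_l21) "on" else "off",
    if (x$use_laplacian) "on" else "off"
  ))
  invisible(x)
}
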