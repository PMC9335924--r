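#' Generate a synthetic multi-type association dataset
#'
#' Seeded generator of fixtures with the statistical structure the model
#' assumes: nonnegative uniform(0,1) ground-truth CP factors of a chosen
#' rank are drawn, their reconstruction is thresholded at the global
#' quantile matching the target density to give a planted low-rank binary
#' tensor, and similarity views consistent with the planted factors are
#' built as cosine-normalized factor Gram matrices (unit diagonal, PSD)
#' plus optional symmetric noise clipped back to `[0, 1]`.  Random RNA
#' sequences and a random disease tree are also emitted so the sequence-
#' and DAG-based similarity paths can be exercised end to end.
#'
#' @param dims Tensor dimensions `c(n_mirna, n_disease, n_type)`.
#' @param true_rank Rank of the planted factors (default 4).
#' @param density Target fraction of positive entries in (0, 1), default
#'   0.10.
#' @param noise Standard deviation of the symmetric Gaussian perturbation
#'   added to the similarity views (default 0 = views exactly consistent
#'   with the planted factors).
#' @param n_mirna_views,n_disease_views Number of similarity views per side
#'   (default 2, emulating multi-view input).
#' @param seq_length Length of the random RNA sequences (default 22 nt, a
#'   typical mature miRNA length).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A list: `tensor` (association tensor), `mirna_sims`,
#'   `disease_sims` (lists of similarity matrices), `truth` (the planted
#'   factor list M, D, T), `sequences` (named RNA strings), `dag` (a
#'   [disease_dag()] over the disease labels) and `spec` (the arguments).
#' @export
simulate_mda <- function(dims = c(40, 20, 4), true_rank = 4, density = 0.10,
                         noise = 0, n_mirna_views = 2, n_disease_views = 2,
                         seq_length = 22, seed = NULL) {
  stopifnot(length(dims) == 3)
  if (density <= 0 || density >= 1) {
    abort("`density` must lie in (0, 1).", class = "tdaign_spec_error")
  }
  if (true_rank > min(dims)) {
    abort("`true_rank` must not exceed the smallest dimension.",
          class = "tdaign_spec_error")
  }
  if (noise < 0) abort("`noise` must be >= 0.", class = "tdaign_spec_error")
  if (!is.null(seed)) set.seed(seed)
  mirnas <- sprintf("mir-%03d", seq_len(dims[1]))
  diseases <- sprintf("disease-%03d", seq_len(dims[2]))
  types <- sprintf("type-%d", seq_len(dims[3]))
  truth <- list(
    M = init_uniform(mirnas, true_rank),
    D = init_uniform(diseases, true_rank),
    T = init_uniform(types, true_rank)
  )
  xhat <- cp_reconstruct(truth)
  n_pos <- max(1L, round(density * length(xhat)))
  thr <- sort(as.numeric(xhat), decreasing = TRUE)[n_pos]
  x <- (xhat >= thr) * 1
  dimnames(x) <- list(mirnas, diseases, types)
  class(x) <- c("association_tensor", class(x))
  sim_view <- function(fac, labs) {
    g <- tcrossprod(fac)
    s <- g / sqrt(diag(g) %o% diag(g))
    if (noise > 0) {
      e <- matrix(stats::rnorm(nrow(s)^2, sd = noise), nrow(s))
      s <- s + (e + t(e)) / 2
      s <- pmin(pmax(s, 0), 1)
    }
    diag(s) <- 1
    s <- (s + t(s)) / 2
    dimnames(s) <- list(labs, labs)
    s
  }
  mirna_sims <- replicate(n_mirna_views, sim_view(truth$M, mirnas),
                          simplify = FALSE)
  disease_sims <- replicate(n_disease_views, sim_view(truth$D, diseases),
                            simplify = FALSE)
  sequences <- vapply(mirnas, function(id) {
    paste(sample(c("A", "C", "G", "U"), seq_length, replace = TRUE),
          collapse = "")
  }, character(1))
  # random tree: each disease after the first attaches to an earlier one
  parent <- if (dims[2] > 1) {
    vapply(seq(2, dims[2]), function(i) sample(seq_len(i - 1), 1), integer(1))
  } else integer(0)
  dag <- disease_dag(
    tibble::tibble(child = diseases[seq_along(parent) + 1],
                   parent = diseases[parent]),
    nodes = diseases
  )
  list(tensor = x, mirna_sims = mirna_sims, disease_sims = disease_sims,
       truth = truth, sequences = sequences, dag = dag,
       spec = list(dims = dims, true_rank = true_rank, density = density,
                   noise = noise, n_mirna_views = n_mirna_views,
                   n_disease_views = n_disease_views,
                   seq_length = seq_length, seed = seed))
}
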