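#' Initialize the optimizer state
#'
#' Builds the full variable set of the weighted, similarity-regularized
#' decomposition: CP factors `M`, `D`, `T`; per-view latent factors `A_i`
#' (miRNA side) and `B_j` (disease side) with their ADMM split copies
#' `C_i = A_i`, `F_i = A_i`, `E_j = B_j`, `G_j = B_j`; projection matrices
#' `Q_i`, `P_j`; zero Lagrange multipliers `Y_i`, `H_i`, `Z_j`, `J_j`; and
#' the all-ones weight tensor `W`.  Factors and latents are seeded
#' uniform(0,1) draws attached to entity labels, so the whole fit is
#' equivariant under consistent relabeling of an axis.
#'
#' @param x Association tensor from [build_tensor()].
#' @param mirna_sims,disease_sims Lists of symmetric similarity matrices
#'   (one per view) whose dimnames match the tensor's miRNA/disease labels;
#'   matrices are realigned by label when ordered differently.
#' @param config A [tdaign_config()].
#' @return A list of class `tdaign_state`.
#' @export
tdaign_init_state <- function(x, mirna_sims = list(), disease_sims = list(),
                              config = tdaign_config()) {
  stopifnot(length(dim(x)) == 3)
  dims <- dim(x)
  labs <- dimnames(x) %||% lapply(dims, function(n) as.character(seq_len(n)))
  mirna_sims <- align_sims(mirna_sims, labs[[1]], "miRNA")
  disease_sims <- align_sims(disease_sims, labs[[2]], "disease")
  alphas <- recycle_weights(config$alpha, length(mirna_sims), "alpha")
  betas <- recycle_weights(config$beta, length(disease_sims), "beta")
  if (config$rank > min(dims[1], dims[2])) {
    warn("`rank` exceeds min(#miRNAs, #diseases); the CP model is over-parameterized.")
  }
  if ((length(mirna_sims) && config$rank_prime >= dims[1]) ||
      (length(disease_sims) && config$rank_prime >= dims[2])) {
    abort("`rank_prime` must be smaller than both entity counts.",
          class = "tdaign_input_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- config$rank; rp <- config$rank_prime
  M <- init_uniform(labs[[1]], r)
  D <- init_uniform(labs[[2]], r)
  T_ <- init_uniform(labs[[3]], r)
  make_view <- function(s, a, entity_labs, pen_split, pen_lap) {
    A <- init_uniform(entity_labs, rp)
    Q <- matrix(runif(rp * r), rp, r)
    dimnames(s) <- NULL
    L <- if (config$use_laplacian) graph_laplacian(s) else
      matrix(0, nrow(s), ncol(s))
    # (2 a L + pen_lap I) is fixed over the fit; factor it once
    lap_chol <- chol(2 * a * L + pen_lap * diag(nrow(L)))
    list(S = s, L = L, lap_chol = lap_chol, a = a,
         A = A, C = A, F = A, Q = Q,
         Y = matrix(0, nrow(A), rp), H = matrix(0, nrow(A), rp))
  }
  mviews <- purrr::map2(mirna_sims, alphas, make_view,
                        entity_labs = labs[[1]],
                        pen_split = config$mu, pen_lap = config$gamma)
  dviews <- purrr::map2(disease_sims, betas, make_view,
                        entity_labs = labs[[2]],
                        pen_split = config$eta, pen_lap = config$epsilon)
  structure(
    list(M = M, D = D, T = T_, mviews = mviews, dviews = dviews,
         W = array(1, dim = dims), dims = dims, labels = labs),
    class = "tdaign_state"
  )
}

align_sims <- function(sims, labels, what) {
  if (is.matrix(sims)) sims <- list(sims)
  lapply(sims, function(s) {
    s <- as.matrix(s)
    check_square_symmetric(s, arg = sprintf("%s similarity", what))
    if (!is.null(rownames(s))) {
      # realign by label; a matrix covering extra entities is subset down
      if (!all(labels %in% rownames(s))) {
        abort(sprintf("%s similarity labels do not cover the tensor axis.", what),
              class = "tdaign_identifier_error")
      }
      s <- s[labels, labels]
    } else if (nrow(s) != length(labels)) {
      abort(sprintf("A %s similarity matrix has %d rows but the tensor has %d %ss.",
                    what, nrow(s), length(labels), what),
            class = "tdaign_identifier_error")
    }
    s
  })
}

recycle_weights <- function(w, n_views, what) {
  if (n_views == 0) return(numeric(0))
  if (length(w) == 1) w <- rep(w, n_views)
  if (length(w) != n_views) {
    abort(sprintf("`%s` must have length 1 or one value per view.", what),
          class = "tdaign_input_error")
  }
  w
}

# Row-wise weighted ridge least squares shared by the three factor updates.
# Solves, for each row i,
#   row_i [ Z' Diag(Wm[i, ]) Z + ridge I ] = [(Wm * Xm) Z + aux]_i
# where Z is the Khatri-Rao product of the two fixed factors.  Rows whose
# weights are all 1 share the base Gram matrix; weighted rows add a low-rank
# correction over their up-weighted entries only.
solve_weighted_rows <- function(xm, wm, z, aux, ridge) {
  num <- (wm * xm) %*% z
  if (!is.null(aux)) num <- num + aux
  g0 <- crossprod(z) + ridge * diag(ncol(z))
  hot <- which(rowSums(wm != 1) > 0)
  out <- t(solve_sym(g0, t(num)))
  for (i in hot) {
    e <- which(wm[i, ] != 1)
    gi <- g0 + crossprod(z[e, , drop = FALSE] * sqrt(wm[i, e] - 1))
    out[i, ] <- solve_sym(gi, num[i, ])
  }
  out
}

#' Block updates of the alternating ADMM solver
#'
#' Each function performs one exact block update of the augmented-Lagrangian
#' objective with every other variable held fixed, and returns the updated
#' state.  `update_factor_m()`/`_d()`/`_t()` solve the row-wise weighted
#' ridge systems for the CP factors; `update_latents()` updates the
#' similarity embeddings `A_i`, `B_j` and their split copies `C_i`, `F_i`,
#' `E_j`, `G_j`; `update_projections()` updates the L2,1-penalized
#' projections `Q_i`, `P_j` (using the previous iterate's row norms, floored
#' at 1e-8, for the reweighting diagonal); `update_multipliers()` performs
#' the dual ascent step; `update_weight_tensor()` recomputes the weight
#' tensor after an episode: a positive entry keeps weight 1 when its squared
#' residual is at most \eqn{(1-k)^2} and gets weight `w` otherwise (all
#' non-positive entries keep weight 1).
#'
#' @param state A `tdaign_state` (see [tdaign_init_state()]).
#' @param x The association tensor.
#' @param config A [tdaign_config()].
#' @return The updated state.
#' @name tdaign-updates
NULL

#' @rdname tdaign-updates
#' @export
update_factor_m <- function(state, x, config) {
  z <- khatri_rao(state$D, state$T)
  aux <- view_aux(state$mviews, nrow(state$M), config$rank)
  asum <- sum(vapply(state$mviews, `[[`, numeric(1), "a"))
  state$M <- solve_weighted_rows(unfold(x, 1), unfold(state$W, 1), z, aux,
                                 asum + config$lambda)
  state
}

#' @rdname tdaign-updates
#' @export
update_factor_d <- function(state, x, config) {
  z <- khatri_rao(state$M, state$T)
  aux <- view_aux(state$dviews, nrow(state$D), config$rank)
  bsum <- sum(vapply(state$dviews, `[[`, numeric(1), "a"))
  state$D <- solve_weighted_rows(unfold(x, 2), unfold(state$W, 2), z, aux,
                                 bsum + config$lambda)
  state
}

#' @rdname tdaign-updates
#' @export
update_factor_t <- function(state, x, config) {
  z <- khatri_rao(state$M, state$D)
  state$T <- solve_weighted_rows(unfold(x, 3), unfold(state$W, 3), z, NULL,
                                 config$lambda)
  state
}

view_aux <- function(views, n, r) {
  if (length(views) == 0) return(NULL)
  out <- matrix(0, n, r)
  for (v in views) out <- out + v$a * (v$A %*% v$Q)
  out
}

#' @rdname tdaign-updates
#' @export
update_latents <- function(state, config) {
  state$mviews <- lapply(state$mviews, update_latent_view,
                         factor = state$M, mu = config$mu, ga = config$gamma)
  state$dviews <- lapply(state$dviews, update_latent_view,
                         factor = state$D, mu = config$eta, ga = config$epsilon)
  state
}

# One view's A / C / F updates (identical algebra on both sides; `factor`
# is M for miRNA views and D for disease views).
update_latent_view <- function(v, factor, mu, ga) {
  a <- v$a
  rp <- ncol(v$A)
  gram_a <- 2 * a * crossprod(v$C) + 2 * a * tcrossprod(v$Q) + (mu + ga) * diag(rp)
  rhs_a <- 2 * a * (v$S %*% v$C) + 2 * a * (factor %*% t(v$Q)) +
    mu * v$C + v$Y + v$H + ga * v$F
  v$A <- t(solve_sym(gram_a, t(rhs_a)))
  gram_c <- 2 * a * crossprod(v$A) + mu * diag(rp)
  rhs_c <- 2 * a * (v$S %*% v$A) + mu * v$A - v$Y
  v$C <- t(solve_sym(gram_c, t(rhs_c)))
  v$F <- backsolve(v$lap_chol, forwardsolve(t(v$lap_chol), ga * v$A - v$H))
  v
}

#' @rdname tdaign-updates
#' @export
update_projections <- function(state, config) {
  upd <- function(v, factor) {
    gram <- crossprod(v$A)
    if (config$use_l21) {
      lam <- 1 / pmax(row_norms(v$Q), 1e-8)
      gram <- gram + diag(lam / 2, ncol(v$A))
    }
    v$Q <- solve_sym(gram, crossprod(v$A, factor))
    v
  }
  state$mviews <- lapply(state$mviews, upd, factor = state$M)
  state$dviews <- lapply(state$dviews, upd, factor = state$D)
  state
}

#' @rdname tdaign-updates
#' @export
update_multipliers <- function(state, config) {
  state$mviews <- lapply(state$mviews, function(v) {
    v$Y <- v$Y + config$mu * (v$C - v$A)
    v$H <- v$H + config$gamma * (v$F - v$A)
    v
  })
  state$dviews <- lapply(state$dviews, function(v) {
    v$Y <- v$Y + config$eta * (v$C - v$A)
    v$H <- v$H + config$epsilon * (v$F - v$A)
    v
  })
  state
}

#' @rdname tdaign-updates
#' @export
update_weight_tensor <- function(state, x, config) {
  xhat <- cp_reconstruct(state)
  resid2 <- (unclass(x) - xhat)^2
  w <- array(1, dim = dim(resid2))
  w[unclass(x) == 1 & resid2 > (1 - config$k)^2] <- config$weight
  state$W <- w
  state
}

# Primal objective (the augmented-Lagrangian value minus multiplier and
# weight-penalty terms): weighted squared residual + per-view similarity
# fit, projection fit, L2,1 and Laplacian penalties + factor ridge.
tdaign_objective <- function(state, x, config) {
  xhat <- cp_reconstruct(state)
  obj <- sum(state$W * (unclass(x) - xhat)^2) +
    config$lambda * (sum(state$M^2) + sum(state$D^2) + sum(state$T^2))
  view_term <- function(v, factor) {
    t <- sum((v$S - tcrossprod(v$C, v$A))^2) +
      sum((v$A %*% v$Q - factor)^2)
    if (config$use_l21) t <- t + norm_l21(v$Q)
    if (config$use_laplacian) t <- t + sum(v$F * (v$L %*% v$F))
    v$a * t
  }
  for (v in state$mviews) obj <- obj + view_term(v, state$M)
  for (v in state$dviews) obj <- obj + view_term(v, state$D)
  obj
}

#' Fit the weighted similarity-regularized tensor decomposition
#'
#' Completes a sparse binary miRNA x disease x type association tensor by a
#' CP decomposition regularized with multi-view similarity factorizations,
#' graph-Laplacian and L2,1 penalties, solved by alternating block updates
#' with ADMM.  Training proceeds in episodes: the inner loop runs to its
#' stopping condition (relative objective change below `inner_tol` or
#' `inner_max_iter` sweeps), then the weight tensor is refreshed so that
#' poorly reconstructed positive triplets are up-weighted in the next
#' episode.  Toggles in the config give the ablated models: turning
#' weighting off is the unweighted variant; additionally dropping the L2,1
#' and Laplacian penalties is the plain auxiliary-information variant.
#'
#' @inheritParams tdaign_init_state
#' @return An object of class `tdaign_fit` with elements `scores` (the
#'   reconstructed real-valued tensor, same dims/labels as `x`), `state`,
#'   `trace` (tibble: `episode`, `sweep`, `objective`, `n_weighted`),
#'   `config` and `converged`.  Use [tidy()] for a long score table,
#'   [glance()] for a one-row summary and [predict_topk()] to rank types.
#' @examples
#' sim <- simulate_mda(dims = c(12, 8, 3), true_rank = 2, seed = 1)
#' cfg <- tdaign_config(rank = 3, rank_prime = 4, episodes = 2,
#'                      inner_max_iter = 30, seed = 1)
#' fit <- tdaign(sim$tensor, sim$mirna_sims, sim$disease_sims, cfg)
#' head(tidy(fit))
#' @export
tdaign <- function(x, mirna_sims = list(), disease_sims = list(),
                   config = tdaign_config()) {
  state <- tdaign_init_state(x, mirna_sims, disease_sims, config)
  trace <- list()
  converged <- logical(config$episodes)
  for (ep in seq_len(config$episodes)) {
    prev <- Inf
    objs <- numeric(0)
    for (sw in seq_len(config$inner_max_iter)) {
      state <- update_factor_m(state, x, config)
      state <- update_factor_d(state, x, config)
      state <- update_factor_t(state, x, config)
      state <- update_latents(state, config)
      state <- update_projections(state, config)
      state <- update_multipliers(state, config)
      obj <- tdaign_objective(state, x, config)
      if (!is.finite(obj)) {
        abort(sprintf(
          "Objective diverged at episode %d sweep %d; consider larger ADMM penalties (mu/gamma/eta/epsilon).",
          ep, sw), class = "tdaign_divergence_error")
      }
      objs <- c(objs, obj)
      if (is.finite(prev) &&
          abs(prev - obj) <= config$inner_tol * max(abs(prev), .Machine$double.eps)) {
        converged[ep] <- TRUE
        break
      }
      prev <- obj
    }
    if (config$use_weighting) state <- update_weight_tensor(state, x, config)
    trace[[ep]] <- tibble::tibble(
      episode = ep, sweep = seq_along(objs), objective = objs,
      n_weighted = sum(state$W != 1)
    )
  }
  scores <- cp_reconstruct(state)
  dimnames(scores) <- state$labels
  structure(
    list(scores = scores, state = state,
         trace = dplyr::bind_rows(trace), config = config,
         converged = converged, labels = state$labels),
    class = "tdaign_fit"
  )
}

#' @export
print.tdaign_fit <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf(
    "<tdaign_fit> %d x %d x %d scores; %d episodes (%d converged), final objective %.6g\n",
    d[1], d[2], d[3], x$config$episodes, sum(x$converged),
    x$trace$objective[nrow(x$trace)]))
  invisible(x)
}

#' Rank association types for miRNA-disease pairs
#'
#' For each requested pair, orders the association types by decreasing
#' predicted score (ties broken by type-axis order) and keeps the top `k`.
#'
#' @param scores A `tdaign_fit`, `cp_fit` or 3-way score array with
#'   dimnames.
#' @param pairs Data frame with columns `mirna` and `disease`.
#' @param k How many types to keep per pair (default: all).
#' @return A tibble with columns `mirna`, `disease`, `rank`, `type`,
#'   `score`.
#' @export
predict_topk <- function(scores, pairs, k = NULL) {
  s <- score_array(scores)
  labs <- dimnames(s)
  if (is.null(labs)) {
    abort("`scores` must carry axis labels.", class = "tdaign_identifier_error")
  }
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("mirna", "disease") %in% names(pairs)))
  i <- match(as.character(pairs$mirna), labs[[1]])
  j <- match(as.character(pairs$disease), labs[[2]])
  if (anyNA(i) || anyNA(j)) {
    abort("Unknown miRNA or disease in `pairs`.", class = "tdaign_identifier_error")
  }
  k <- k %||% length(labs[[3]])
  k <- min(k, length(labs[[3]]))
  purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
    v <- s[i[p], j[p], ]
    ord <- order(-v)[seq_len(k)]
    tibble::tibble(mirna = labs[[1]][i[p]], disease = labs[[2]][j[p]],
                   rank = seq_len(k), type = labs[[3]][ord],
                   score = unname(v[ord]))
  })
}

score_array <- function(scores) {
  if (inherits(scores, "tdaign_fit")) return(scores$scores)
  if (inherits(scores, "cp_fit")) return(scores$scores)
  stopifnot(length(dim(scores)) == 3)
  scores
}
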