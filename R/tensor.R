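#' Build a binary miRNA x disease x type association tensor
#'
#' Converts a table of miRNA--disease--type triplets into a dense binary
#' third-order array \eqn{X \in \{0,1\}^{|m| \times |n| \times |t|}} with
#' \eqn{x_{ijt} = 1} exactly when the triplet was observed.  Duplicate
#' triplets collapse to a single 1.
#'
#' @param triplets A data frame with character columns `mirna`, `disease`,
#'   `type` (one observed association per row).  Extra columns are ignored.
#' @param mirnas,diseases,types Optional character vectors fixing the axis
#'   labels (and their order).  When supplied, every triplet entity must be
#'   present among them; when `NULL`, labels are taken from the triplets in
#'   first-seen order.
#'
#' @return A 3-way `array` of 0/1 with `dimnames` = (miRNA, disease, type)
#'   and class `"association_tensor"`.
#' @examples
#' tri <- tibble::tibble(mirna = c("m1", "m2"), disease = "d1", type = "t1")
#' x <- build_tensor(tri)
#' tensor_density(x)
#' @export
build_tensor <- function(triplets, mirnas = NULL, diseases = NULL, types = NULL) {
  triplets <- as_triplet_tibble(triplets)
  axis_or_seen <- function(fixed, seen, what) {
    if (is.null(fixed)) return(unique(seen))
    fixed <- as.character(fixed)
    if (anyDuplicated(fixed)) {
      abort(sprintf("Duplicate %s labels.", what), class = "tdaign_identifier_error")
    }
    missing <- setdiff(seen, fixed)
    if (length(missing)) {
      abort(sprintf("Unknown %s label(s): %s", what,
                    paste(head(missing, 5), collapse = ", ")),
            class = "tdaign_identifier_error")
    }
    fixed
  }
  mirnas   <- axis_or_seen(mirnas,   triplets$mirna,   "miRNA")
  diseases <- axis_or_seen(diseases, triplets$disease, "disease")
  types    <- axis_or_seen(types,    triplets$type,    "type")
  x <- array(0, dim = c(length(mirnas), length(diseases), length(types)),
             dimnames = list(mirnas, diseases, types))
  if (nrow(triplets)) {
    idx <- cbind(match(triplets$mirna, mirnas),
                 match(triplets$disease, diseases),
                 match(triplets$type, types))
    x[idx] <- 1
  }
  class(x) <- c("association_tensor", class(x))
  x
}

as_triplet_tibble <- function(triplets) {
  triplets <- tibble::as_tibble(triplets)
  need <- c("mirna", "disease", "type")
  if (!all(need %in% names(triplets))) {
    if (ncol(triplets) < 3) {
      abort("`triplets` needs columns mirna, disease, type.",
            class = "tdaign_input_error")
    }
    names(triplets)[1:3] <- need
  }
  dplyr::mutate(triplets[need], dplyr::across(dplyr::everything(),
                                              ~ trimws(as.character(.x))))
}

#' @export
print.association_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<association_tensor> %d miRNAs x %d diseases x %d types, %d positives (density %.2f%%)\n",
              d[1], d[2], d[3], sum(x != 0), tensor_density(x)))
  invisible(x)
}

#' Tensor density
#'
#' Percentage of nonzero entries, the sparsity statistic reported for
#' association datasets.
#'
#' @param x A 3-way array (or any array).
#' @return `100 * sum(x != 0) / length(x)`.
#' @export
tensor_density <- function(x) {
  if (length(x) == 0) {
    abort("Cannot compute the density of an empty tensor.",
          class = "tdaign_input_error")
  }
  100 * sum(x != 0) / length(x)
}

#' Mode-n matricization of a 3-way tensor
#'
#' Rearranges a third-order tensor into a matrix whose columns are the mode-n
#' fibers.  Columns are ordered over the two remaining indices in their
#' original axis order with the last index varying fastest, the convention
#' under which `unfold(x, 1) == M %*% t(khatri_rao(D, T))` for
#' `x = cp_reconstruct(list(M, D, T))` (and cyclically for modes 2 and 3).
#'
#' @param x A 3-way array.
#' @param mode Which axis becomes the rows: 1, 2 or 3.
#' @return A matrix of shape `dim(x)[mode]` by `prod(dim(x)[-mode])`.
#' @seealso [fold()], [khatri_rao()]
#' @export
unfold <- function(x, mode) {
  stopifnot(length(dim(x)) == 3)
  if (!mode %in% 1:3) {
    abort("`mode` must be 1, 2 or 3.", class = "tdaign_input_error")
  }
  perm <- switch(mode, `1` = c(1, 3, 2), `2` = c(2, 3, 1), `3` = c(3, 2, 1))
  y <- aperm(unclass(x), perm)
  dim(y) <- c(dim(x)[mode], prod(dim(x)[-mode]))
  y
}

#' Fold a matricization back into a 3-way tensor
#'
#' Inverse of [unfold()]: `fold(unfold(x, mode), mode, dim(x))` returns `x`.
#'
#' @param m Matrix produced by [unfold()].
#' @param mode The mode that was unfolded.
#' @param dims The `dim()` of the original tensor.
#' @export
fold <- function(m, mode, dims) {
  stopifnot(length(dims) == 3)
  if (!mode %in% 1:3) {
    abort("`mode` must be 1, 2 or 3.", class = "tdaign_input_error")
  }
  perm <- switch(mode, `1` = c(1, 3, 2), `2` = c(2, 3, 1), `3` = c(3, 2, 1))
  y <- array(m, dim = dims[perm])
  aperm(y, order(perm))
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' For matrices with equal column counts, column `s` of the result is
#' `kronecker(a[, s], b[, s])`, i.e. the row index of `b` varies fastest:
#' row `(i - 1) * nrow(b) + j` equals `a[i, s] * b[j, s]`.
#'
#' @param a,b Matrices with the same number of columns.
#' @return A `(nrow(a) * nrow(b))` by `ncol(a)` matrix.
#' @export
khatri_rao <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) {
    abort("Khatri-Rao factors must have the same number of columns.",
          class = "tdaign_shape_error")
  }
  a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE] *
    b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE]
}

#' Reconstruct a tensor from CP factors
#'
#' Computes \eqn{[[M, D, T]]}: entry \eqn{(i,j,k)} is
#' \eqn{\sum_s M_{is} D_{js} T_{ks}}.
#'
#' @param factors A list (or `cp_fit`) with components `M`, `D`, `T` --
#'   factor matrices sharing the same number of columns (the rank).
#' @return A dense 3-way array.
#' @export
cp_reconstruct <- function(factors) {
  f <- as_factor_set(factors)
  x <- f$M %*% t(khatri_rao(f$D, f$T))
  out <- fold(x, 1, c(nrow(f$M), nrow(f$D), nrow(f$T)))
  dn <- list(rownames(f$M), rownames(f$D), rownames(f$T))
  if (!all(vapply(dn, is.null, logical(1)))) dimnames(out) <- dn
  out
}

as_factor_set <- function(factors) {
  if (inherits(factors, "cp_fit")) factors <- factors$factors
  if (!all(c("M", "D", "T") %in% names(factors))) {
    abort("`factors` must contain matrices M, D and T.",
          class = "tdaign_input_error")
  }
  f <- lapply(factors[c("M", "D", "T")], as.matrix)
  rk <- vapply(f, ncol, integer(1))
  if (length(unique(rk)) != 1) {
    abort("Factor matrices must share a common rank.",
          class = "tdaign_shape_error")
  }
  if (!all(vapply(f, function(m) all(is.finite(m)), logical(1)))) {
    abort("Factor matrices must be finite.", class = "tdaign_input_error")
  }
  f
}

#' CP decomposition by alternating least squares
#'
#' Fits the plain CANDECOMP/PARAFAC model
#' \eqn{\min_{M,D,T} \|X - [[M, D, T]]\|_F^2} by alternating exact
#' least-squares updates of the three factor matrices.  This is the
#' unregularized baseline model; see [tdaign()] for the full weighted,
#' similarity-regularized decomposition.
#'
#' @param x A 3-way array (typically from [build_tensor()]).
#' @param rank Number of rank-1 components \eqn{r}.
#' @param max_iter Maximum ALS sweeps (default 500).
#' @param tol Stop when the relative change of the squared-residual objective
#'   falls below `tol` (default 1e-6).
#' @param seed Integer seed for the uniform(0,1) factor initialization;
#'   fixing it makes the fit deterministic.
#'
#' @return An object of class `cp_fit`: list with `factors` (M, D, T),
#'   `scores` (the reconstruction), `trace` (a tibble with per-iteration
#'   `objective` and `fit` = 1 - relative residual norm), `rank`, and
#'   `converged`.
#' @examples
#' x <- cp_reconstruct(list(M = matrix(1:2), D = matrix(1:3, 3), T = matrix(1:2, 2)))
#' f <- cp_als(x, rank = 1, seed = 1)
#' glance(f)
#' @export
cp_als <- function(x, rank, max_iter = 500, tol = 1e-6, seed = NULL) {
  stopifnot(length(dim(x)) == 3)
  if (rank < 1) abort("`rank` must be >= 1.", class = "tdaign_input_error")
  dims <- dim(x)
  if (rank > max(dims[1] * dims[2], dims[1] * dims[3], dims[2] * dims[3])) {
    warn("Requested rank exceeds the largest unfolding dimension; the model is over-parameterized.")
  }
  labs <- dimnames(x) %||% list(NULL, NULL, NULL)
  if (!is.null(seed)) set.seed(seed)
  M <- init_uniform(labs[[1]] %||% as.character(seq_len(dims[1])), rank)
  D <- init_uniform(labs[[2]] %||% as.character(seq_len(dims[2])), rank)
  T_ <- init_uniform(labs[[3]] %||% as.character(seq_len(dims[3])), rank)
  x1 <- unfold(x, 1); x2 <- unfold(x, 2); x3 <- unfold(x, 3)
  xnorm2 <- sum(x^2)
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- t(solve_sym(crossprod(D) * crossprod(T_), t(x1 %*% khatri_rao(D, T_))))
    D <- t(solve_sym(crossprod(M) * crossprod(T_), t(x2 %*% khatri_rao(M, T_))))
    T_ <- t(solve_sym(crossprod(M) * crossprod(D), t(x3 %*% khatri_rao(M, D))))
    z <- khatri_rao(M, D)
    res2 <- xnorm2 - 2 * sum(x3 * (T_ %*% t(z))) + sum(crossprod(T_) * crossprod(z))
    res2 <- max(res2, 0)
    obj <- c(obj, res2)
    if (is.finite(prev) && abs(prev - res2) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- res2
  }
  factors <- list(M = M, D = D, T = T_)
  scores <- cp_reconstruct(factors)
  dimnames(scores) <- dimnames(x)
  structure(
    list(
      factors = factors,
      scores = scores,
      trace = tibble::tibble(
        iteration = seq_along(obj),
        objective = obj,
        fit = 1 - sqrt(obj) / max(sqrt(xnorm2), .Machine$double.eps)
      ),
      rank = rank,
      converged = converged,
      dims = dims
    ),
    class = "cp_fit"
  )
}

#' @export
print.cp_fit <- function(x, ...) {
  cat(sprintf("<cp_fit> rank %d, %d ALS sweeps, fit %.4f%s\n",
              x$rank, nrow(x$trace), tail_fit(x),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

tail_fit <- function(fit) fit$trace$fit[nrow(fit$trace)]
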