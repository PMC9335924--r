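# Independent oracles used to pin expected values; deliberately brute-force
# and separate from the package's implementation paths.

# Needleman-Wunsch global alignment score, linear gap penalty, full DP table.
nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- gap * (0:n)
  d[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      d[i + 1, j + 1] <- max(d[i, j] + s, d[i, j + 1] + gap, d[i + 1, j] + gap)
    }
  }
  d[n + 1, m + 1]
}

# Entry-by-entry CP reconstruction.
brute_reconstruct <- function(M, D, T_) {
  out <- array(0, c(nrow(M), nrow(D), nrow(T_)))
  for (i in seq_len(nrow(M))) for (j in seq_len(nrow(D))) for (k in seq_len(nrow(T_))) {
    out[i, j, k] <- sum(M[i, ] * D[j, ] * T_[k, ])
  }
  out
}

# Mode-n matricization by explicit index arithmetic: columns run over the
# remaining axes in original order with the last one varying fastest.
brute_unfold <- function(x, mode) {
  d <- dim(x)
  rest <- setdiff(1:3, mode)
  out <- matrix(0, d[mode], prod(d[rest]))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    col <- (idx[rest[1]] - 1) * d[rest[2]] + idx[rest[2]]
    out[idx[mode], col] <- x[i, j, k]
  }
  out
}

# Frequency-scheme disease similarity recomputed from scratch with a chosen
# log base (the package uses the natural log; the ratio is base-invariant).
brute_dss2 <- function(edges, nodes, base = exp(1)) {
  parents_of <- split(edges$parent, edges$child)
  closure <- function(d) {
    seen <- character(0); queue <- d
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, parents_of[[v]])
    }
    seen
  }
  closures <- lapply(setNames(nodes, nodes), closure)
  n_dags <- vapply(nodes, function(a) {
    sum(vapply(closures, function(cl) a %in% cl, logical(1)))
  }, numeric(1))
  d2 <- -log(n_dags / length(nodes), base = base)
  s <- diag(1, length(nodes)); dimnames(s) <- list(nodes, nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i == j) next
    shared <- intersect(closures[[i]], closures[[j]])
    den <- sum(d2[closures[[i]]]) + sum(d2[closures[[j]]])
    s[i, j] <- if (den > 0) (sum(d2[shared]) * 2) / den else 0
  }
  s
}

# Trapezoidal ROC integration over all score thresholds.
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

chain_dag <- function(n) {
  # d1 <- d2 <- ... <- dn (d1 is the root)
  ids <- paste0("d", seq_len(n))
  disease_dag(tibble::tibble(child = ids[-1], parent = ids[-n]))
}

rand_factors <- function(dims, r) {
  list(M = matrix(runif(dims[1] * r), dims[1]),
       D = matrix(runif(dims[2] * r), dims[2]),
       T = matrix(runif(dims[3] * r), dims[3]))
}

# A small labeled random binary tensor plus a bare state for update tests.
tiny_instance <- function(dims = c(5, 4, 3), r = 2, seed = 42) {
  set.seed(seed)
  x <- array(rbinom(prod(dims), 1, 0.3), dim = dims,
             dimnames = list(paste0("m", seq_len(dims[1])),
                             paste0("d", seq_len(dims[2])),
                             paste0("t", seq_len(dims[3]))))
  sm <- cov2cor(crossprod(matrix(runif(dims[1] * dims[1]), dims[1])))
  sd_ <- cov2cor(crossprod(matrix(runif(dims[2] * dims[2]), dims[2])))
  dimnames(sm) <- list(rownames(x), rownames(x))
  dimnames(sd_) <- list(colnames(x), colnames(x))
  list(x = x, sm = abs(sm), sd = abs(sd_))
}
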