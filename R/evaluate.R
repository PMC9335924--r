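#' Split miRNA-disease pairs into cross-validation folds
#'
#' Pairs with at least one positive association type are shuffled by the
#' seed and partitioned into `n_folds` disjoint subsets whose sizes differ
#' by at most one.  During evaluation all types of a test pair are masked to
#' zero in the training tensor (the split is over pairs, not triplets).
#'
#' @param x Association tensor.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return A tibble of class `cv_plan` with columns `mirna`, `disease`,
#'   `fold`, and attributes `n_folds` and `seed`.
#' @export
cv_split_pairs <- function(x, n_folds = 5, seed = NULL) {
  stopifnot(length(dim(x)) == 3)
  pos <- which(apply(unclass(x) != 0, c(1, 2), any), arr.ind = TRUE)
  if (nrow(pos) < n_folds) {
    abort("Fewer positive miRNA-disease pairs than folds.",
          class = "tdaign_input_error")
  }
  labs <- dimnames(x)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(nrow(pos))
  fold <- integer(nrow(pos))
  fold[ord] <- rep_len(seq_len(n_folds), nrow(pos))
  plan <- tibble::tibble(
    mirna = labs[[1]][pos[, 1]],
    disease = labs[[2]][pos[, 2]],
    fold = fold
  )
  structure(plan, n_folds = n_folds, seed = seed,
            class = c("cv_plan", class(plan)))
}

#' Mask all types of the given pairs in a training tensor
#'
#' @param x Association tensor.
#' @param pairs Data frame with columns `mirna`, `disease`.
#' @return A copy of `x` with every type of each pair set to 0.
#' @export
mask_pairs <- function(x, pairs) {
  labs <- dimnames(x)
  i <- match(as.character(pairs$mirna), labs[[1]])
  j <- match(as.character(pairs$disease), labs[[2]])
  if (anyNA(i) || anyNA(j)) {
    abort("Unknown miRNA or disease in `pairs`.", class = "tdaign_identifier_error")
  }
  out <- x
  for (p in seq_along(i)) out[i[p], j[p], ] <- 0
  out
}

#' Top-1 type metrics for the pair-wise protocol
#'
#' For each test pair the highest-scoring type is the prediction.  Top-1
#' precision is the fraction of test pairs whose predicted type is a true
#' type; Top-1 recall divides the number of correct predictions by the
#' total number of true triplets over the test pairs (so pairs with several
#' true types cap recall below precision); Top-1 F1 is their harmonic mean.
#'
#' @param scores Score tensor (`tdaign_fit`, `cp_fit` or array).
#' @param truth The full binary association tensor.
#' @param test_pairs Data frame with columns `mirna`, `disease`; every pair
#'   must have at least one true type.
#' @return A one-row tibble: `top1_precision`, `top1_recall`, `top1_f1`,
#'   `n_pairs`, `n_triplets`.
#' @export
eval_cv_type <- function(scores, truth, test_pairs) {
  s <- score_array(scores)
  labs <- dimnames(truth)
  i <- match(as.character(test_pairs$mirna), labs[[1]])
  j <- match(as.character(test_pairs$disease), labs[[2]])
  if (anyNA(i) || anyNA(j)) {
    abort("Unknown miRNA or disease in `test_pairs`.",
          class = "tdaign_identifier_error")
  }
  n_true <- 0L
  n_hit <- 0L
  for (p in seq_along(i)) {
    true_types <- which(truth[i[p], j[p], ] != 0)
    if (length(true_types) == 0) {
      abort("A test pair has no true association type.",
            class = "tdaign_protocol_error")
    }
    top1 <- order(-s[i[p], j[p], ])[1]
    n_true <- n_true + length(true_types)
    n_hit <- n_hit + (top1 %in% true_types)
  }
  precision <- n_hit / length(i)
  recall <- n_hit / n_true
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(top1_precision = precision, top1_recall = recall,
                 top1_f1 = f1, n_pairs = length(i), n_triplets = n_true)
}

#' Ranking metrics for the triplet protocol
#'
#' Positives are the true triplets of the test pairs; an equal number of
#' negatives is sampled uniformly without replacement (seeded) from the
#' all-zero triplets of the full tensor.  AUC (rank statistic with mean-rank
#' tie handling), AUPR (step-wise precision-recall integration) and MSE
#' (mean of `(1 - score)^2` over the positive triplets only, measuring how
#' well positive samples are recovered) are reported.
#'
#' @inheritParams eval_cv_type
#' @param neg_seed Seed for the negative draw.
#' @return A one-row tibble: `auc`, `aupr`, `mse`, `n_pos`, `n_neg`.
#' @export
eval_cv_triplet <- function(scores, truth, test_pairs, neg_seed = NULL) {
  s <- score_array(scores)
  labs <- dimnames(truth)
  i <- match(as.character(test_pairs$mirna), labs[[1]])
  j <- match(as.character(test_pairs$disease), labs[[2]])
  if (anyNA(i) || anyNA(j)) {
    abort("Unknown miRNA or disease in `test_pairs`.",
          class = "tdaign_identifier_error")
  }
  pos_idx <- do.call(rbind, lapply(seq_along(i), function(p) {
    tt <- which(truth[i[p], j[p], ] != 0)
    cbind(i[p], j[p], tt)
  }))
  zeros <- which(unclass(truth) == 0)
  if (length(zeros) < nrow(pos_idx)) {
    abort("Not enough unobserved triplets to sample negatives from.",
          class = "tdaign_input_error")
  }
  if (!is.null(neg_seed)) set.seed(neg_seed)
  neg <- sample(zeros, nrow(pos_idx))
  pos_scores <- s[pos_idx]
  neg_scores <- s[neg]
  tibble::tibble(
    auc = auc_rank(c(pos_scores, neg_scores),
                   rep(c(1L, 0L), c(length(pos_scores), length(neg_scores)))),
    aupr = aupr_step(c(pos_scores, neg_scores),
                     rep(c(1L, 0L), c(length(pos_scores), length(neg_scores)))),
    mse = mean((1 - pos_scores)^2),
    n_pos = length(pos_scores), n_neg = length(neg_scores)
  )
}

#' Area under the ROC curve via the rank statistic
#'
#' Wilcoxon-Mann-Whitney form with mean-rank handling of ties; identical to
#' trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    abort("AUC needs both positive and negative labels.",
          class = "tdaign_input_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: thresholds sweep the distinct scores in
#' decreasing order and each recall increment contributes that threshold's
#' precision (the average-precision form, with tied scores grouped).
#'
#' @inheritParams auc_rank
#' @export
aupr_step <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  np <- sum(labels == 1)
  if (np == 0) {
    abort("AUPR needs at least one positive label.", class = "tdaign_input_error")
  }
  ord <- order(-scores)
  scores <- scores[ord]; labels <- labels[ord]
  grp <- cumsum(!duplicated(scores))
  tp_g <- tapply(labels, grp, sum)
  n_g <- tapply(rep(1, length(labels)), grp, sum)
  tp <- cumsum(tp_g)
  n <- cumsum(n_g)
  prec <- tp / n
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Relative performance gain in percent
#'
#' `100 * (a - b) / b`, rounded to two decimals for reporting.
#'
#' @param a,b Metric values (e.g. a model and a baseline); `b` must be
#'   positive.
#' @export
relative_gain <- function(a, b) {
  if (any(b <= 0)) {
    abort("Baseline metric must be positive.", class = "tdaign_input_error")
  }
  round(100 * (a - b) / b, 2)
}

#' Run a full cross-validated evaluation
#'
#' Drives the 5-fold protocols end to end: split pairs, mask each test
#' fold's pairs out of the training tensor, fit the model on the masked
#' tensor, and score the held-out fold under the pair-wise (`"type"`),
#' triplet-ranking (`"triplet"`) or both protocols.
#'
#' @param x Association tensor.
#' @param mirna_sims,disease_sims Similarity views passed to [tdaign()].
#' @param config A [tdaign_config()].
#' @param protocol `"type"`, `"triplet"` or `"both"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling the split and the per-fold negative draws.
#' @param gip_views If `TRUE` (default), a Gaussian interaction profile
#'   kernel view ([gip_kernel()]) computed from each fold's *training*
#'   tensor (so no test information leaks) is appended to both view lists,
#'   mirroring the construction of the similarity inputs from known
#'   associations.
#' @return A tibble of per-fold metrics plus a final `fold = "mean"` row
#'   averaging the folds.
#' @export
run_cv <- function(x, mirna_sims = list(), disease_sims = list(),
                   config = tdaign_config(), protocol = c("both", "type", "triplet"),
                   n_folds = 5, seed = NULL, gip_views = TRUE) {
  protocol <- match.arg(protocol)
  if (is.matrix(mirna_sims)) mirna_sims <- list(mirna_sims)
  if (is.matrix(disease_sims)) disease_sims <- list(disease_sims)
  plan <- cv_split_pairs(x, n_folds = n_folds, seed = seed)
  rows <- purrr::map_dfr(seq_len(n_folds), function(f) {
    test_pairs <- dplyr::filter(plan, .data$fold == f)
    train <- mask_pairs(x, test_pairs)
    msims <- mirna_sims
    dsims <- disease_sims
    if (isTRUE(gip_views)) {
      msims <- c(msims, list(gip_kernel(association_profiles(train, 1))))
      dsims <- c(dsims, list(gip_kernel(association_profiles(train, 2))))
    }
    fit <- tdaign(train, msims, dsims, config)
    out <- tibble::tibble(fold = as.character(f))
    if (protocol %in% c("type", "both")) {
      out <- dplyr::bind_cols(out, eval_cv_type(fit, x, test_pairs))
    }
    if (protocol %in% c("triplet", "both")) {
      out <- dplyr::bind_cols(
        out,
        eval_cv_triplet(fit, x, test_pairs,
                        neg_seed = if (is.null(seed)) NULL else seed + f)
      )
    }
    out
  })
  means <- dplyr::summarise(rows, dplyr::across(dplyr::where(is.numeric), mean))
  dplyr::bind_rows(rows, dplyr::bind_cols(tibble::tibble(fold = "mean"), means))
}

#' Sweep model configurations by cross-validation
#'
#' Minimal grid-search helper mirroring the hyperparameter-selection
#' protocol of the method: each candidate configuration is scored by
#' [run_cv()] and the per-config mean metrics are returned for comparison.
#'
#' @param x,mirna_sims,disease_sims,protocol,n_folds,seed Passed to
#'   [run_cv()].
#' @param grid A data frame whose columns name [tdaign_config()] arguments;
#'   one row per candidate.
#' @param base_config Config supplying the non-swept arguments.
#' @return The grid with the mean CV metrics bound as extra columns.
#' @export
sweep_configs <- function(x, mirna_sims = list(), disease_sims = list(),
                          grid, base_config = tdaign_config(),
                          protocol = "triplet", n_folds = 5, seed = NULL) {
  grid <- tibble::as_tibble(grid)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- unclass(base_config)
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    cfg <- do.call(tdaign_config, cfg[names(cfg) %in% names(formals(tdaign_config))])
    out <- run_cv(x, mirna_sims, disease_sims, cfg, protocol = protocol,
                  n_folds = n_folds, seed = seed)
    out[out$fold == "mean", setdiff(names(out), "fold")]
  })
  dplyr::bind_cols(grid, res)
}
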