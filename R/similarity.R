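#' Disease DAG
#'
#' A MeSH-style hierarchy of diseases given as child -> parent edges.  Each
#' disease `d` has a DAG consisting of the node set `T(d)` -- the disease
#' itself plus all of its ancestors -- over which semantic contributions are
#' accumulated.
#'
#' @param edges Data frame with character columns `child`, `parent` (one
#'   edge per row), or a two-column data frame taken in that order.
#' @param nodes Optional character vector of all disease identifiers; must
#'   contain every edge endpoint.  Needed to represent isolated diseases.
#' @param delta Semantic contribution decay factor \eqn{\Delta \in (0, 1]};
#'   each step from a disease to a parent multiplies the contribution by
#'   `delta`.  Default 0.5.
#'
#' @return An object of class `disease_dag` wrapping the validated edge
#'   list, node set, decay factor and an [igraph::graph] (edges directed
#'   child -> parent).
#' @export
disease_dag <- function(edges, nodes = NULL, delta = 0.5) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges))) {
    if (ncol(edges) < 2) {
      abort("`edges` needs columns child and parent.", class = "tdaign_input_error")
    }
    names(edges)[1:2] <- c("child", "parent")
  }
  edges <- dplyr::mutate(edges[c("child", "parent")],
                         dplyr::across(dplyr::everything(),
                                       ~ trimws(as.character(.x))))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1) {
    abort("`delta` must be a single value in (0, 1].", class = "tdaign_input_error")
  }
  nodes <- unique(c(as.character(nodes %||% character(0)),
                    edges$child, edges$parent))
  if (length(nodes) == 0) {
    abort("The disease DAG is empty.", class = "tdaign_structure_error")
  }
  extra <- setdiff(unique(c(edges$child, edges$parent)), nodes)
  if (length(extra)) {
    abort("Edge endpoints missing from `nodes`.", class = "tdaign_identifier_error")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    abort("The disease hierarchy contains a cycle.", class = "tdaign_structure_error")
  }
  structure(list(edges = edges, nodes = nodes, delta = delta, graph = g),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %d diseases, %d edges, delta = %g\n",
              length(x$nodes), nrow(x$edges), x$delta))
  invisible(x)
}

as_disease_dag <- function(dag, delta = 0.5) {
  if (inherits(dag, "disease_dag")) dag else disease_dag(dag, delta = delta)
}

# T(d): the disease itself plus all ancestors reachable along child->parent
# edges.
ancestor_closure <- function(dag, target) {
  v <- igraph::subcomponent(dag$graph, target, mode = "out")
  names(v)
}

#' Semantic contribution of ancestors to a disease
#'
#' Computes, for every disease in the ancestor closure `T(target)`, its
#' semantic contribution to `target` under one of two schemes.  Scheme 1 is
#' the decay recursion: the target contributes 1 and each ancestor
#' contributes `delta` times the largest contribution among its children
#' inside `T(target)` (equivalently \eqn{\Delta^{depth}} along the shortest
#' upward path).  Scheme 2 is frequency-based:
#' \eqn{-\log(\textrm{number of disease DAGs containing } a / \textrm{number of diseases})},
#' so rare (specific) diseases contribute more.  The natural logarithm is
#' used; the derived similarity ([disease_semantic_similarity()]) is
#' invariant to the base.
#'
#' @param dag A [disease_dag()] (or an edge data frame).
#' @param target Disease identifier.
#' @param method 1 (decay) or 2 (DAG-frequency).
#' @return A named numeric vector over `T(target)`.
#' @export
semantic_contribution <- function(dag, target, method = 1) {
  dag <- as_disease_dag(dag)
  target <- as.character(target)
  if (!target %in% dag$nodes) {
    abort(sprintf("Unknown disease id '%s'.", target),
          class = "tdaign_identifier_error")
  }
  if (!method %in% c(1, 2)) {
    abort("`method` must be 1 or 2.", class = "tdaign_input_error")
  }
  anc <- ancestor_closure(dag, target)
  if (method == 1) {
    d <- igraph::distances(dag$graph, v = target, to = anc, mode = "out")
    contrib <- dag$delta^as.numeric(d[1, ])
    names(contrib) <- anc
  } else {
    counts <- dag_membership_counts(dag)
    contrib <- -log(counts[anc] / length(dag$nodes))
  }
  contrib[order(match(names(contrib), dag$nodes))]
}

# For each disease a, the number of diseases d whose closure T(d) contains a
# (i.e. the number of per-disease DAGs that include a): a itself plus all of
# its descendants along parent->child direction.
dag_membership_counts <- function(dag) {
  vapply(dag$nodes, function(v) {
    length(igraph::subcomponent(dag$graph, v, mode = "in"))
  }, numeric(1))
}

#' Disease semantic similarity from a MeSH-style hierarchy
#'
#' For each pair of diseases the similarity is the summed contributions of
#' their shared ancestors, normalized by the two semantic values
#' \eqn{SV(d) = \sum_{a \in T(d)} D(d, a)}:
#' \deqn{DSS_x(d_i, d_j) = \frac{\sum_{a \in T(d_i) \cap T(d_j)}
#'   (D_x(d_i, a) + D_x(d_j, a))}{SV_x(d_i) + SV_x(d_j)}}
#' computed under both contribution schemes of [semantic_contribution()] and
#' averaged: \eqn{DSS = (DSS_1 + DSS_2) / 2}.
#'
#' @inheritParams semantic_contribution
#' @param delta Decay factor used when `dag` is given as an edge list.
#' @param scheme `"average"` (default) for \eqn{(DSS_1 + DSS_2)/2},
#'   `"decay"` for \eqn{DSS_1} alone, `"frequency"` for \eqn{DSS_2} alone.
#' @return A symmetric similarity matrix in `[0, 1]` over `dag$nodes` with
#'   unit diagonal.
#' @export
disease_semantic_similarity <- function(dag, delta = 0.5,
                                        scheme = c("average", "decay", "frequency")) {
  scheme <- match.arg(scheme)
  dag <- as_disease_dag(dag, delta = delta)
  n <- length(dag$nodes)
  c1 <- lapply(dag$nodes, function(d) semantic_contribution(dag, d, 1))
  c2 <- lapply(dag$nodes, function(d) semantic_contribution(dag, d, 2))
  names(c1) <- names(c2) <- dag$nodes
  one <- function(contrib) {
    sv <- vapply(contrib, sum, numeric(1))
    s <- diag(1, n)
    dimnames(s) <- list(dag$nodes, dag$nodes)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
        num <- sum(contrib[[i]][shared]) + sum(contrib[[j]][shared])
        den <- sv[i] + sv[j]
        s[i, j] <- s[j, i] <- if (den > 0) num / den else 0
      }
    }
    s
  }
  s <- switch(scheme,
              average = (one(c1) + one(c2)) / 2,
              decay = one(c1),
              frequency = one(c2))
  diag(s) <- 1
  s
}

#' miRNA functional similarity from shared disease associations
#'
#' Best-match average of disease semantic similarities between the disease
#' sets of two miRNAs: with \eqn{D(m)} the set of diseases associated with
#' `m` in at least one association type,
#' \deqn{MFS(m_i, m_j) = \frac{\sum_{d \in D(m_i)} \max_{d' \in D(m_j)} DSS(d, d')
#'   + \sum_{d \in D(m_j)} \max_{d' \in D(m_i)} DSS(d, d')}{|D(m_i)| + |D(m_j)|}.}
#' A miRNA with no associated disease gets zero similarity to every other
#' miRNA (unit self-similarity): with no evidence there is no basis for
#' functional similarity.
#'
#' @param dss Disease semantic similarity matrix with disease labels as
#'   dimnames (see [disease_semantic_similarity()]).
#' @param triplets Triplet data frame (`mirna`, `disease`, `type`) or an
#'   `association_tensor`; types are collapsed.
#' @param mirnas Optional miRNA label order for the output.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
mirna_functional_similarity <- function(dss, triplets, mirnas = NULL) {
  check_square_symmetric(dss, arg = "dss")
  dlabs <- rownames(dss)
  if (is.null(dlabs)) {
    abort("`dss` must carry disease labels as dimnames.",
          class = "tdaign_identifier_error")
  }
  if (is.array(triplets) && length(dim(triplets)) == 3) {
    triplets <- tensor_to_triplets(triplets)
  }
  triplets <- as_triplet_tibble(triplets)
  missing <- setdiff(unique(triplets$disease), dlabs)
  if (length(missing)) {
    abort(sprintf("Disease(s) missing from `dss`: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "tdaign_identifier_error")
  }
  mirnas <- mirnas %||% unique(triplets$mirna)
  dsets <- lapply(setNames(mirnas, mirnas), function(m) {
    unique(triplets$disease[triplets$mirna == m])
  })
  # colmax[[m]][d] = max_{d' in D(m)} DSS(d, d'), for every disease d
  colmax <- lapply(dsets, function(ds) {
    if (length(ds) == 0) return(NULL)
    apply(dss[, ds, drop = FALSE], 1, max)
  })
  nm <- length(mirnas)
  s <- diag(1, nm)
  dimnames(s) <- list(mirnas, mirnas)
  for (i in seq_len(nm - 1)) {
    for (j in seq(i + 1, nm)) {
      di <- dsets[[i]]; dj <- dsets[[j]]
      if (length(di) == 0 || length(dj) == 0) next
      s[i, j] <- s[j, i] <-
        (sum(colmax[[j]][di]) + sum(colmax[[i]][dj])) / (length(di) + length(dj))
    }
  }
  s
}

#' List the positive triplets of an association tensor
#'
#' @param x An `association_tensor`.
#' @return A tibble (`mirna`, `disease`, `type`), one row per positive entry.
#' @export
tensor_to_triplets <- function(x) {
  idx <- which(x != 0, arr.ind = TRUE)
  labs <- dimnames(x)
  tibble::tibble(
    mirna = labs[[1]][idx[, 1]],
    disease = labs[[2]][idx[, 2]],
    type = labs[[3]][idx[, 3]]
  )
}

#' miRNA sequence similarity by global alignment
#'
#' All-pairs Needleman--Wunsch global alignment scores (computed with
#' [Biostrings::pairwiseAlignment()]; match +1, mismatch -1, linear gap -2
#' by default, all configurable), min--max normalized over the full score
#' matrix:
#' \deqn{MSS(m_i, m_j) = \frac{Score(m_i, m_j) - Score_{min}}{Score_{max} - Score_{min}}.}
#'
#' @param sequences Named character vector of RNA/DNA sequences (names are
#'   miRNA ids); `U` and `T` are treated as equivalent.
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @param gap Linear per-base gap penalty (default -2, i.e. each gapped base
#'   costs 2).
#' @return Symmetric similarity matrix with entries in `[0, 1]`.  If all
#'   alignment scores are identical the normalization is undefined; an
#'   identity matrix is returned with a warning.
#' @export
mirna_sequence_similarity <- function(sequences, match = 1, mismatch = -1,
                                      gap = -2) {
  if (length(sequences) < 2) {
    abort("Need at least two sequences.", class = "tdaign_input_error")
  }
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  seqs <- toupper(trimws(as.character(sequences)))
  if (any(nchar(seqs) == 0)) {
    abort("Empty sequence(s) supplied.", class = "tdaign_input_error")
  }
  if (any(grepl("[^ACGUT]", seqs))) {
    abort("Sequences must be over the alphabet A, C, G, U/T.",
          class = "tdaign_input_error")
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (gap > 0) gap <- -gap
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  set <- Biostrings::DNAStringSet(seqs)
  n <- length(set)
  score <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      set[seq_len(j)], set[[j]],
      substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = -gap,
      type = "global", scoreOnly = TRUE
    )
    score[seq_len(j), j] <- sc
    score[j, seq_len(j)] <- sc
  }
  rng <- range(score)
  if (diff(rng) == 0) {
    warn("All alignment scores identical; min-max normalization undefined, returning the identity matrix.")
    return(diag(1, n) + 0 * score)
  }
  (score - rng[1]) / diff(rng)
}

#' Association profiles of a tensor axis
#'
#' Binary interaction profiles `IP`: for each entity on one axis, the 0/1
#' vector over the partner axis marking partners with at least one observed
#' association of any type.
#'
#' @param x An `association_tensor`.
#' @param margin 1 for miRNA profiles over diseases, 2 for disease profiles
#'   over miRNAs.
#' @return A binary matrix, one profile per row.
#' @export
association_profiles <- function(x, margin = 1) {
  stopifnot(length(dim(x)) == 3, margin %in% 1:2)
  p <- apply(unclass(x) != 0, c(margin, 3 - margin), any) * 1
  p
}

#' Gaussian interaction profile kernel similarity
#'
#' Radial-basis similarity between binary association profiles with the
#' bandwidth normalized by the mean squared profile norm:
#' \deqn{\gamma = \gamma' \Big/ \frac{1}{n}\sum_i \|IP_i\|^2, \qquad
#'   K(i, j) = \exp(-\gamma \|IP_i - IP_j\|^2).}
#'
#' @param profiles Binary matrix of profiles, one entity per row (see
#'   [association_profiles()]).
#' @param gamma_prime Bandwidth numerator \eqn{\gamma' > 0} (default 1).
#' @return Symmetric kernel matrix with unit diagonal.  When every profile
#'   is all-zero the bandwidth is undefined; \eqn{\gamma = 1} is used with a
#'   warning.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (!is.numeric(gamma_prime) || gamma_prime <= 0) {
    abort("`gamma_prime` must be positive.", class = "tdaign_input_error")
  }
  mean_norm2 <- mean(rowSums(profiles^2))
  if (mean_norm2 == 0) {
    warn("All profiles are zero; kernel bandwidth undefined, using gamma = 1.")
    gamma <- 1
  } else {
    gamma <- gamma_prime / mean_norm2
  }
  d2 <- as.matrix(stats::dist(profiles))^2
  k <- exp(-gamma * d2)
  diag(k) <- 1
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  k
}

#' Graph Laplacian of a similarity matrix
#'
#' `L = D - S` with degree matrix `D_ii = sum_j S_ij`.  Used as the local
#' geometry penalty `Tr(A' L A)` that keeps embeddings of similar entities
#' close.
#'
#' @param s Symmetric nonnegative similarity matrix.
#' @param tol Symmetry tolerance.
#' @return A symmetric positive semidefinite matrix with zero row sums,
#'   carrying the attribute `source` (the dimnames of `s`).
#' @export
graph_laplacian <- function(s, tol = 1e-8) {
  s <- as.matrix(s)
  check_square_symmetric(s, tol = tol, arg = "s")
  if (any(s < -tol)) {
    abort("Similarity entries must be nonnegative.", class = "tdaign_input_error")
  }
  l <- diag(rowSums(s), nrow(s)) - s
  dimnames(l) <- dimnames(s)
  l
}
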