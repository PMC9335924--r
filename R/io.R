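#' Read miRNA-disease-type triplets from TSV
#'
#' Expects tab-separated columns `mirna`, `disease`, `type`; a header row is
#' auto-detected and skipped, `#` comment lines are ignored, fields are
#' trimmed, duplicates are dropped, and first-seen order is preserved (it
#' defines the default axis label order of [build_tensor()]).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `mirna`, `disease`, `type`.
#' @export
read_triplets <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 3) {
    abort(sprintf("Malformed triplet file '%s': expected 3 tab-separated columns.",
                  path), class = "tdaign_parse_error")
  }
  df <- df[1:3]
  names(df) <- c("mirna", "disease", "type")
  if (nrow(df) && all(grepl("^(mi?rna|disease|type)s?$", tolower(unlist(df[1, ]))))) {
    df <- df[-1, ]
  }
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    abort(sprintf("Malformed triplet row(s) at line(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "tdaign_parse_error")
  }
  dplyr::distinct(dplyr::mutate(df, dplyr::across(dplyr::everything(), trimws)))
}

#' Read a disease DAG edge list from TSV
#'
#' Two tab-separated columns `child`, `parent`, one edge per line; `#`
#' comments allowed.
#'
#' @param path Path to the TSV file.
#' @param nodes,delta Passed to [disease_dag()].
#' @return A [disease_dag()].
#' @export
read_dag <- function(path, nodes = NULL, delta = 0.5) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) {
    abort(sprintf("Malformed DAG file '%s': expected 2 tab-separated columns.", path),
          class = "tdaign_parse_error")
  }
  df <- df[1:2]
  names(df) <- c("child", "parent")
  if (nrow(df) && all(grepl("^(child|parent)$", tolower(unlist(df[1, ]))))) {
    df <- df[-1, ]
  }
  disease_dag(df, nodes = nodes, delta = delta)
}

#' Read miRNA sequences from FASTA
#'
#' Record ids must match the miRNA ids used in triplet files; `T` bases are
#' normalized to `U`.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort("Duplicate FASTA record ids.", class = "tdaign_identifier_error")
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  setNames(seqs, ids)
}

#' Write miRNA sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta_rna <- function(sequences, path) {
  writeLines(paste0(">", names(sequences), "\n", as.character(sequences)), path)
  invisible(path)
}

#' Read / write a labeled similarity matrix as CSV
#'
#' The format is a full square matrix with a header row of labels and a
#' first column of labels.  A write -> read round trip reproduces values
#' and label order exactly.
#'
#' @param path CSV path.
#' @return `read_similarity()` returns a labeled symmetric matrix.
#' @export
read_similarity <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[-1])
  if (nrow(m) != ncol(m) || !identical(unname(labels), colnames(df)[-1])) {
    abort(sprintf("'%s' is not a square labeled similarity matrix.", path),
          class = "tdaign_shape_error")
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' @rdname read_similarity
#' @param s Labeled square matrix.
#' @export
write_similarity <- function(s, path) {
  s <- as.matrix(s)
  labels <- rownames(s) %||% as.character(seq_len(nrow(s)))
  df <- tibble::as_tibble(s, .name_repair = "minimal")
  names(df) <- labels
  readr::write_csv(dplyr::bind_cols(tibble::tibble(id = labels), df), path)
  invisible(path)
}

#' Write predicted scores as long-format TSV
#'
#' Columns `mirna`, `disease`, `type`, `score`, sorted by descending score.
#'
#' @param scores A `tdaign_fit`, `cp_fit` or labeled 3-way array.
#' @param path Output TSV path.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(tidy_scores(scores), path)
  invisible(path)
}

tidy_scores <- function(scores) {
  s <- score_array(scores)
  labs <- dimnames(s)
  if (is.null(labs)) {
    abort("`scores` must carry axis labels.", class = "tdaign_identifier_error")
  }
  idx <- arrayInd(seq_along(s), dim(s))
  dplyr::arrange(
    tibble::tibble(
      mirna = labs[[1]][idx[, 1]],
      disease = labs[[2]][idx[, 2]],
      type = labs[[3]][idx[, 3]],
      score = as.numeric(s)
    ),
    dplyr::desc(.data$score)
  )
}

#' Serialize / load an association tensor
#'
#' Coordinate-list TSV (`i`, `j`, `k`, `value`) of the nonzero entries plus
#' a JSON sidecar (`<path>.json`) holding the axis labels and dimensions.
#'
#' @param x Association tensor.
#' @param path TSV path; the sidecar is written next to it.
#' @export
write_tensor <- function(x, path) {
  idx <- which(unclass(x) != 0, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                                  value = x[idx]), path)
  jsonlite::write_json(
    list(dims = dim(x), mirnas = dimnames(x)[[1]],
         diseases = dimnames(x)[[2]], types = dimnames(x)[[3]]),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_tsv(path, col_types = "iiid", progress = FALSE)
  x <- array(0, dim = meta$dims,
             dimnames = list(meta$mirnas, meta$diseases, meta$types))
  if (nrow(df)) x[cbind(df$i, df$j, df$k)] <- df$value
  class(x) <- c("association_tensor", class(x))
  x
}

#' Read a model configuration from JSON or YAML
#'
#' Field names mirror the arguments of [tdaign_config()] exactly.
#'
#' @param path A `.json`, `.yml` or `.yaml` file.
#' @return A [tdaign_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package.",
            class = "tdaign_input_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(tdaign_config)))
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s", paste(unknown, collapse = ", ")),
          class = "tdaign_input_error")
  }
  do.call(tdaign_config, vals)
}
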