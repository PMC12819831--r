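# Objective Q-sorting: score institutions against statements and force each
# score profile into a fixed quasi-normal grid.

#' Define a forced-distribution Q grid
#'
#' The grid assigns a fixed number of statements to each of 11 agreement
#' levels from -5 ("least important") through 0 to +5 ("most important").
#' Values must be strictly increasing and symmetric about zero, and counts
#' symmetric (the count at -v equals the count at +v), so every Q-sort column
#' has the same mean (zero) and standard deviation by construction.
#'
#' @param column_values Integer levels, default `-5:5`.
#' @param column_counts Statements per level; the default `c(2, 3, 5, 6, 7,
#'   8, 7, 6, 5, 3, 2)` is the quasi-normal allocation for a 54-statement set.
#' @return A list of class `q_grid` with `column_values`, `column_counts`,
#'   `n_statements`.
#' @export
q_grid <- function(column_values = -5:5,
                   column_counts = c(2, 3, 5, 6, 7, 8, 7, 6, 5, 3, 2)) {
  column_values <- as.integer(column_values)
  column_counts <- as.integer(column_counts)
  if (length(column_values) != length(column_counts)) {
    stop_qorient("Values and counts must align.", "qorient_grid_error")
  }
  if (any(diff(column_values) <= 0)) {
    stop_qorient("Grid values must be strictly increasing.", "qorient_grid_error")
  }
  if (!identical(column_values, -rev(column_values))) {
    stop_qorient("Grid values must be symmetric about 0.", "qorient_grid_error")
  }
  if (!identical(column_counts, rev(column_counts))) {
    stop_qorient("Grid counts must be symmetric.", "qorient_grid_error")
  }
  if (any(column_counts < 1)) {
    stop_qorient("Grid counts must be positive.", "qorient_grid_error")
  }
  structure(
    list(column_values = column_values, column_counts = column_counts,
         n_statements = sum(column_counts)),
    class = "q_grid"
  )
}

#' Read / write a grid specification as YAML
#'
#' @param path YAML file with keys `column_values`, `column_counts`.
#' @export
read_q_grid <- function(path) {
  raw <- yaml::read_yaml(path)
  q_grid(unlist(raw$column_values), unlist(raw$column_counts))
}

#' @rdname read_q_grid
#' @param grid A `q_grid`.
#' @export
write_q_grid <- function(grid, path) {
  yaml::write_yaml(list(column_values = grid$column_values,
                        column_counts = grid$column_counts), path)
  invisible(path)
}

#' Aggregate record embeddings to one vector per institution
#'
#' Each institution's vector is the L2-normalized mean of its record vectors,
#' so duplicated records leave the direction unchanged.
#'
#' @param corpus An [audit_corpus()].
#' @param record_embedding Matrix of record embeddings aligned to the corpus
#'   rows.
#' @return A matrix, one L2-normalized row per institution (rownames are
#'   institution ids, in first-appearance order).
#' @export
aggregate_institutions <- function(corpus, record_embedding) {
  stopifnot(nrow(record_embedding) == nrow(corpus))
  ids <- unique(corpus$institution_id)
  out <- t(vapply(ids, function(id) {
    rows <- which(corpus$institution_id == id)
    if (length(rows) == 0) {
      stop_qorient(paste0("Institution `", id, "` has zero records."),
                   "qorient_schema_error")
    }
    colMeans(record_embedding[rows, , drop = FALSE])
  }, numeric(ncol(record_embedding))))
  norms <- sqrt(rowSums(out^2))
  if (any(norms < 1e-12)) {
    stop_qorient("Aggregated institution vector is all-zero.",
                 "qorient_embedding_error")
  }
  out / norms
}

#' Score institutions against statements
#'
#' Plain cosine similarity between institution vectors and statement
#' embeddings: the objective analogue of a participant's agreement levels.
#'
#' @param inst_vectors Institutions x dim matrix (rownames = institution ids).
#' @param statement_embedding Statements x dim matrix (rownames = statement
#'   ids).
#' @return An institutions x statements cosine matrix with dimnames.
#' @export
score_statements <- function(inst_vectors, statement_embedding) {
  cosine_matrix(inst_vectors, statement_embedding)
}

#' Force a score profile into the Q grid
#'
#' Statements are sorted by descending score; the top `column_counts[+5]`
#' receive +5, the next block +4, and so on down to -5. Only the ordering of
#' the scores matters: any strictly increasing transform of the scores yields
#' the identical Q-sort. Ties are broken deterministically by ascending
#' statement index within the tied block.
#'
#' @param scores Numeric vector, one score per statement; length must equal
#'   the grid's statement count.
#' @param grid A [q_grid()].
#' @param tie_policy Only `"index"` (deterministic ascending-index) is
#'   currently provided.
#' @return An integer vector of grid values, aligned to `scores`.
#' @export
force_distribution <- function(scores, grid, tie_policy = "index") {
  tie_policy <- match.arg(tie_policy)
  if (length(scores) != grid$n_statements) {
    stop_qorient(
      paste0("Got ", length(scores), " scores for a ", grid$n_statements,
             "-statement grid."),
      "qorient_grid_error"
    )
  }
  ord <- order(-scores, seq_along(scores))
  values_by_rank <- rep(rev(grid$column_values), rev(grid$column_counts))
  out <- integer(length(scores))
  out[ord] <- values_by_rank
  out
}

#' Build the Q-sort matrix
#'
#' Applies [force_distribution()] to every institution's score row. Every
#' column of the result contains exactly the configured number of each grid
#' value, so all columns share an identical mean and standard deviation.
#'
#' @param scores Institutions x statements similarity matrix (from
#'   [score_statements()]).
#' @param grid A [q_grid()].
#' @return A statements x institutions integer matrix of class
#'   `qsort_matrix`, with the grid attached as attribute `grid`.
#' @export
build_qsort_matrix <- function(scores, grid = q_grid()) {
  scores <- as.matrix(scores)
  out <- apply(scores, 1, force_distribution, grid = grid)
  # apply() returns statements x institutions (columns = institutions)
  dimnames(out) <- list(colnames(scores), rownames(scores))
  structure(out, grid = grid, class = c("qsort_matrix", class(out)))
}

#' Read / write a Q-sort matrix as CSV
#'
#' Layout consumed by standard Q-analysis tools: rows are statements, columns
#' are institution ids, first column `statement_id`.
#'
#' @param qsorts A `qsort_matrix`.
#' @param path Output path.
#' @export
write_qsorts <- function(qsorts, path) {
  df <- tibble::tibble(statement_id = rownames(qsorts) %||%
                         sprintf("S%02d", seq_len(nrow(qsorts))))
  df <- dplyr::bind_cols(df, tibble::as_tibble(unclass(qsorts)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_qsorts
#' @param grid The grid the sorts were built under (revalidated on read).
#' @export
read_qsorts <- function(path, grid = q_grid()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    statement_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df$statement_id
  for (j in seq_len(ncol(mat))) {
    counts <- table(factor(mat[, j], levels = grid$column_values))
    if (!all(as.integer(counts) == grid$column_counts)) {
      stop_qorient(paste0("Column `", colnames(mat)[j],
                          "` violates the grid counts."), "qorient_grid_error")
    }
  }
  structure(mat, grid = grid, class = c("qsort_matrix", class(mat)))
}

#' Build Q-sorts for a corpus against a statement set in one call
#'
#' Embeds the statement texts and the record texts in a single joint batch
#' (so TF-IDF document statistics are shared and frozen once), aggregates
#' records per institution, scores, and forces the grid.
#'
#' @param corpus An [audit_corpus()].
#' @param statements A `statement_set` tibble (needs columns `statement_id`,
#'   `text`).
#' @param grid A [q_grid()]; its statement count must equal
#'   `nrow(statements)`.
#' @inheritParams embed_texts
#' @return A `qsort_matrix` (statements x institutions) with the similarity
#'   scores attached as attribute `scores`.
#' @export
build_qsorts <- function(corpus, statements, grid = q_grid(),
                         backend = "hash_tfidf", ...) {
  if (nrow(statements) != grid$n_statements) {
    stop_qorient(
      paste0("Grid expects ", grid$n_statements, " statements, got ",
             nrow(statements), "."),
      "qorient_grid_error"
    )
  }
  texts <- c(statements$text, corpus$text)
  E <- embed_texts(texts, backend = backend,
                   ids = c(statements$statement_id,
                           paste0("rec_", seq_len(nrow(corpus)))), ...)
  stmt_E <- E[seq_len(nrow(statements)), , drop = FALSE]
  rec_E <- E[-seq_len(nrow(statements)), , drop = FALSE]
  inst <- aggregate_institutions(corpus, rec_E)
  scores <- score_statements(inst, stmt_E)
  out <- build_qsort_matrix(scores, grid)
  attr(out, "scores") <- scores
  out
}
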