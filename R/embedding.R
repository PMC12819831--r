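# Text-to-vector backends and similarity utilities.
#
# The default backend hashes lowercase tokens into a fixed number of buckets,
# weights counts by TF-IDF computed over the embedding batch, and
# L2-normalizes each row. It is fully deterministic and needs no model
# download; an external sentence-embedding backend can be registered through
# the same registry for production use.

.backend_registry <- new.env(parent = emptyenv())

#' Register an embedding backend
#'
#' A backend is a function `function(texts, ...)` returning a numeric matrix
#' with one row per text. Rows are L2-normalized by [embed_texts()] after the
#' backend returns; an all-zero row is an error.
#'
#' @param name Backend name used in `embed_texts(backend = )`.
#' @param fun The backend function.
#' @export
register_embedding_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .backend_registry)
  invisible(name)
}

embedding_backend <- function(name) {
  if (!exists(name, envir = .backend_registry, inherits = FALSE)) {
    stop_qorient(paste0("Unknown embedding backend: `", name, "`."),
                 "qorient_config_error")
  }
  get(name, envir = .backend_registry, inherits = FALSE)
}

# Lowercase, strip punctuation, split on whitespace; CJK characters are
# tokenized individually (they carry no whitespace separators).
tokenize <- function(text) {
  x <- tolower(text)
  x <- gsub("([\\p{Han}\\p{Hiragana}\\p{Katakana}])", " \\1 ", x, perl = TRUE)
  x <- gsub("[^\\p{L}\\p{N}\\s]", " ", x, perl = TRUE)
  strsplit(trimws(x), "\\s+", perl = TRUE)
}

# Multiplicative string hash over UTF-8 bytes, reduced modulo 2^31 so all
# intermediates stay exact in doubles; the initial state is the documented
# hash seed. Stable across platforms and R sessions.
hash_token <- function(tokens, dim, hash_seed = 3491) {
  vapply(tokens, function(tok) {
    h <- hash_seed
    for (b in utf8ToInt(tok)) {
      h <- (h * 131 + b) %% 2147483647
    }
    (h %% dim) + 1
  }, numeric(1), USE.NAMES = FALSE)
}

# Default backend: hashed token counts with TF-IDF weighting over the batch.
# idf = 1 + log(N / df) keeps weights strictly positive, so a token present
# in every document still contributes.
hash_tfidf_backend <- function(texts, dim = 4096, hash_seed = 3491) {
  toks <- tokenize(texts)
  vocab <- unique(unlist(toks))
  if (length(vocab) == 0) {
    stop_qorient("No tokens in batch.", "qorient_embedding_error")
  }
  bucket_of <- setNames(hash_token(vocab, dim, hash_seed), vocab)
  n <- length(texts)
  mat <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    if (length(toks[[i]]) == 0) next
    counts <- table(bucket_of[toks[[i]]])
    mat[i, as.integer(names(counts))] <- as.numeric(counts)
  }
  df <- colSums(mat > 0)
  idf <- ifelse(df > 0, 1 + log(n / pmax(df, 1)), 0)
  sweep(mat, 2, idf, "*")
}

register_embedding_backend("hash_tfidf", hash_tfidf_backend)

#' Embed a batch of texts
#'
#' Runs the named backend over the batch and L2-normalizes every row. The
#' default `"hash_tfidf"` backend is deterministic given an identical batch:
#' document frequencies are computed over the batch itself, so statement
#' scoring embeds statements and documents in one joint batch, frozen once
#' per run.
#'
#' @param texts Character vector of non-empty texts.
#' @param backend Registered backend name.
#' @param ids Optional unit identifiers (rownames of the result).
#' @param ... Passed to the backend (for `"hash_tfidf"`: `dim`, default 4096,
#'   and `hash_seed`, default 3491).
#' @return A numeric matrix, one L2-normalized row per text, with attributes
#'   `backend` and rownames `ids`.
#' @examples
#' E <- embed_texts(c("wide corridor", "wide corridor", "green garden"))
#' cosine_matrix(E, E)
#' @export
embed_texts <- function(texts, backend = "hash_tfidf", ids = NULL, ...) {
  if (length(texts) == 0) {
    stop_qorient("`texts` must be non-empty.", "qorient_embedding_error")
  }
  empty <- which(!nzchar(normalize_ws(as.character(texts))))
  if (length(empty) > 0) {
    stop_qorient(
      paste0("Empty text after normalization at index(es): ",
             paste(empty, collapse = ", "), "."),
      "qorient_embedding_error"
    )
  }
  fun <- embedding_backend(backend)
  mat <- fun(as.character(texts), ...)
  stopifnot(is.matrix(mat), nrow(mat) == length(texts))
  norms <- sqrt(rowSums(mat^2))
  zero <- which(norms < 1e-12)
  if (length(zero) > 0) {
    stop_qorient(
      paste0("All-zero embedding row at index(es): ",
             paste(zero, collapse = ", "), "."),
      "qorient_embedding_error"
    )
  }
  mat <- mat / norms
  rownames(mat) <- ids %||% rownames(mat)
  attr(mat, "backend") <- backend
  mat
}

#' Cosine similarity between two embedding matrices
#'
#' @param A,B Numeric matrices with the same number of columns; rows are
#'   re-normalized defensively so entries are true cosines in `[-1, 1]`.
#' @return A `nrow(A) x nrow(B)` matrix of cosines.
#' @export
cosine_matrix <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop_qorient(
      paste0("Dimension mismatch: ", ncol(A), " vs ", ncol(B), "."),
      "qorient_dim_error"
    )
  }
  A <- A / sqrt(rowSums(A^2))
  B <- B / sqrt(rowSums(B^2))
  out <- tcrossprod(A, B)
  pmin(pmax(out, -1), 1)
}

# L2-normalize rows of a matrix.
l2_normalize <- function(mat) {
  mat / sqrt(rowSums(mat^2))
}

#' Export an embedding matrix as TSV
#'
#' One row per unit: the unit id followed by the vector components.
#'
#' @param E Embedding matrix with rownames.
#' @param path Output path.
#' @export
write_embedding_tsv <- function(E, path) {
  df <- data.frame(unit_id = rownames(E) %||% seq_len(nrow(E)), unclass(E),
                   check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
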