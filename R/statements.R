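# From audit corpus to Q-statement set: segment, embed, reduce, choose K,
# cluster, extract centroid-nearest discriminative statements.

#' Segment corpus records into sentences
#'
#' Splits each record's text on terminal punctuation (`. ! ? ;` and the CJK
#' equivalents), trims fragments, drops empties, and removes exact duplicate
#' sentences within a record. Provenance (institution and record ids) is kept.
#' A record yielding zero sentences is dropped with a warning.
#'
#' @param corpus An [audit_corpus()].
#' @return A tibble with columns `sentence`, `institution_id`, `record_id`.
#' @export
segment_sentences <- function(corpus) {
  pieces <- strsplit(corpus$text, "[.!?;。！？；]+")
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    s <- normalize_ws(pieces[[i]])
    s <- s[nzchar(s)]
    s <- s[!duplicated(s)]
    if (length(s) == 0) {
      rlang::warn(paste0("Record `", corpus$record_id[i],
                         "` yielded no sentences; dropped."))
      return(NULL)
    }
    tibble::tibble(
      sentence = s,
      institution_id = corpus$institution_id[i],
      record_id = corpus$record_id[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' Build an embedded sentence pool
#'
#' Segments the corpus and embeds every sentence in one batch.
#'
#' @inheritParams segment_sentences
#' @inheritParams embed_texts
#' @return A list of class `sentence_pool` with elements `sentences` (the
#'   [segment_sentences()] tibble) and `embedding` (aligned matrix).
#' @export
sentence_pool <- function(corpus, backend = "hash_tfidf", ...) {
  sentences <- segment_sentences(corpus)
  embedding <- embed_texts(sentences$sentence, backend = backend,
                           ids = paste0("s", seq_len(nrow(sentences))), ...)
  structure(list(sentences = sentences, embedding = embedding),
            class = "sentence_pool")
}

#' Reduce embedding dimensionality by PCA
#'
#' Mean-centers the rows, then retains the smallest number of leading
#' principal components whose cumulative explained variance reaches
#' `variance_target`. With `variance_target = 1` the projection is a pure
#' rotation onto the data's row space, so pairwise distances are preserved.
#'
#' @param E Numeric matrix (rows = units).
#' @param variance_target Fraction in `(0, 1]` of variance to retain.
#' @return A list of class `q_reduction`: `x` (reduced scores), `explained`
#'   (per-component variance fractions for all positive components),
#'   `cumulative` (their cumsum), `n_components`.
#' @export
reduce_dimensions <- function(E, variance_target = 0.9) {
  E <- as.matrix(E)
  if (nrow(E) < 2) {
    stop_qorient("Need at least 2 rows for PCA.", "qorient_dim_error")
  }
  if (!(variance_target > 0 && variance_target <= 1)) {
    stop_qorient("`variance_target` must lie in (0, 1].", "qorient_config_error")
  }
  X <- sweep(E, 2, colMeans(E))
  # All-constant columns are exactly zero after centering and carry no
  # variance; dropping them leaves the covariance eigenstructure untouched
  # and keeps the SVD small for high-dimensional hashed embeddings.
  live <- which(colSums(abs(X)) > 0)
  if (length(live) == 0) {
    stop_qorient("Input has rank 0 (all rows identical).", "qorient_rank_error")
  }
  sv <- svd(X[, live, drop = FALSE])
  var_comp <- sv$d^2
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  var_comp <- var_comp[pos]
  frac <- var_comp / sum(var_comp)
  cum <- cumsum(frac)
  k <- which(cum >= variance_target - 1e-12)[1]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(E)
  structure(
    list(x = scores, explained = frac, cumulative = cum, n_components = k),
    class = "q_reduction"
  )
}

# k-means++ seeding followed by Lloyd iterations. `nstart` independent
# restarts; the run with the lowest within-cluster sum of squares wins.
# Deterministic under the caller-provided seed.
kmeans_pp <- function(X, k, seed, nstart = 10, max_iter = 300, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) {
    stop_qorient("K exceeds the number of points.", "qorient_config_error")
  }
  sq_dist_to <- function(centers) {
    # n x k matrix of squared Euclidean distances
    outer(rowSums(X^2), rep(1, nrow(centers))) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * X %*% t(centers)
  }
  with_seed(seed, {
    best <- NULL
    for (restart in seq_len(nstart)) {
      centers <- X[sample.int(n, 1), , drop = FALSE]
      while (nrow(centers) < k) {
        d2 <- pmax(apply(sq_dist_to(centers), 1, min), 0)
        if (sum(d2) <= 0) {
          idx <- sample.int(n, 1)
        } else {
          idx <- sample.int(n, 1, prob = d2)
        }
        centers <- rbind(centers, X[idx, , drop = FALSE])
      }
      labels <- max.col(-sq_dist_to(centers), ties.method = "first")
      prev_inertia <- Inf
      for (iter in seq_len(max_iter)) {
        for (j in seq_len(k)) {
          members <- labels == j
          if (!any(members)) {
            # re-seed an empty cluster at the point farthest from its center
            far <- which.max(apply(sq_dist_to(centers), 1, min))
            centers[j, ] <- X[far, ]
          } else {
            centers[j, ] <- colMeans(X[members, , drop = FALSE])
          }
        }
        d2 <- sq_dist_to(centers)
        labels <- max.col(-d2, ties.method = "first")
        inertia <- sum(pmax(d2[cbind(seq_len(n), labels)], 0))
        if (prev_inertia - inertia < tol) break
        prev_inertia <- inertia
      }
      if (is.null(best) || inertia < best$inertia) {
        best <- list(labels = labels, centers = centers, inertia = inertia)
      }
    }
    best
  })
}

# Davies-Bouldin index: mean over clusters of the worst ratio of summed
# within-cluster scatters to centroid separation. Lower is better.
davies_bouldin <- function(X, labels, centers) {
  k <- nrow(centers)
  scatter <- vapply(seq_len(k), function(j) {
    members <- labels == j
    mean(sqrt(rowSums((X[members, , drop = FALSE] -
                         matrix(centers[j, ], sum(members), ncol(X),
                                byrow = TRUE))^2)))
  }, numeric(1))
  sep <- as.matrix(stats::dist(centers))
  ratios <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scatter[i] + scatter[j]) / sep[i, j]
    }, numeric(1)))
  }, numeric(1))
  mean(ratios)
}

#' Select the number of clusters by joint silhouette / Davies-Bouldin ranking
#'
#' For every K on the grid, runs K-means (k-means++ seeding, `nstart`
#' restarts, fixed seed) and records the within-cluster sum of squares
#' (elbow curve), the mean silhouette width, and the Davies-Bouldin index.
#' The chosen K minimizes the sum of the silhouette rank (descending: larger
#' is better) and the DBI rank (ascending: smaller is better); ties go to the
#' smaller K. The elbow curve is reported for inspection but does not drive
#' the final choice.
#'
#' @param X Numeric matrix of (reduced) embeddings.
#' @param k_grid Strictly increasing integer grid, minimum at least 2 and
#'   maximum below `nrow(X)`.
#' @param seed Integer seed for the K-means restarts.
#' @param nstart Restarts per K.
#' @return A list of class `k_selection`: `metrics` (tibble `k`, `inertia`,
#'   `silhouette`, `dbi`, `rank_silhouette`, `rank_dbi`, `rank_sum`),
#'   `chosen_k`.
#' @export
select_k <- function(X, k_grid = 2:10, seed = 1, nstart = 10) {
  X <- as.matrix(X)
  k_grid <- as.integer(k_grid)
  if (any(diff(k_grid) <= 0) || min(k_grid) < 2 || max(k_grid) > nrow(X) - 1) {
    stop_qorient("`k_grid` must be strictly increasing within [2, nrow(X) - 1].",
                 "qorient_config_error")
  }
  dmat <- stats::dist(X)
  rows <- purrr::map(k_grid, function(k) {
    fit <- kmeans_pp(X, k, seed = seed + k, nstart = nstart)
    if (length(unique(fit$labels)) < k) {
      return(tibble::tibble(k = k, inertia = fit$inertia,
                            silhouette = NA_real_, dbi = NA_real_))
    }
    sil <- cluster::silhouette(fit$labels, dmat)
    tibble::tibble(
      k = k,
      inertia = fit$inertia,
      silhouette = mean(sil[, "sil_width"]),
      dbi = davies_bouldin(X, fit$labels, fit$centers)
    )
  })
  metrics <- dplyr::bind_rows(rows)
  valid <- !is.na(metrics$silhouette)
  if (!any(valid)) {
    stop_qorient("No K on the grid produced a valid clustering.",
                 "qorient_cluster_error")
  }
  rk_sil <- rk_dbi <- rep(NA_real_, nrow(metrics))
  rk_sil[valid] <- rank(-metrics$silhouette[valid], ties.method = "min")
  rk_dbi[valid] <- rank(metrics$dbi[valid], ties.method = "min")
  metrics$rank_silhouette <- rk_sil
  metrics$rank_dbi <- rk_dbi
  metrics$rank_sum <- rk_sil + rk_dbi
  chosen <- metrics$k[valid][which.min(metrics$rank_sum[valid])]
  structure(list(metrics = metrics, chosen_k = chosen), class = "k_selection")
}

#' Cluster embeddings with K-means
#'
#' K-means with k-means++ initialization, `nstart` restarts (best inertia
#' kept), convergence tolerance 1e-6, and at most 300 Lloyd iterations;
#' deterministic under `seed`.
#'
#' @inheritParams select_k
#' @param k Number of clusters, `2 <= k <= nrow(X)` (K equal to the number of
#'   points puts each point in its own cluster).
#' @return A list of class `cluster_assignment`: `labels` (1-based cluster id
#'   per row), `centroids` (`k x ncol(X)`), `k`, `inertia`.
#' @export
cluster_sentences <- function(X, k, seed = 1, nstart = 10) {
  X <- as.matrix(X)
  if (k > nrow(X)) {
    stop_qorient("K exceeds the number of points.", "qorient_config_error")
  }
  fit <- kmeans_pp(X, k, seed = seed, nstart = nstart)
  structure(
    list(labels = fit$labels, centroids = fit$centers, k = as.integer(k),
         inertia = fit$inertia),
    class = "cluster_assignment"
  )
}

#' Extract centroid-nearest discriminative statements
#'
#' Within each cluster, sentences are ranked by ascending Euclidean distance
#' to their own centroid (in the clustering space). A sentence's
#' discriminative margin is the distance to the nearest *other* centroid
#' minus the distance to its own; sentences with margin `<= 0` (no closer to
#' their own theme than to a neighboring one) are skipped. The top
#' `per_cluster` survivors are taken, dropping near-duplicates along the way:
#' when two candidates' embedding cosine exceeds `dedup_threshold` the one
#' closer to the centroid is kept and the ranking is refilled.
#'
#' @param assignment A `cluster_assignment` over the pool's sentences.
#' @param pool The `sentence_pool` that was clustered.
#' @param X The matrix the clustering ran on (the reduced embedding); used
#'   for centroid distances.
#' @param per_cluster Statements to keep per cluster (default 3).
#' @param dedup_threshold Cosine above which two statements count as
#'   duplicates (default 0.95).
#' @return A tibble of class `statement_set`: `statement_id`, `category`
#'   (cluster id), `text`, `centroid_distance`, `margin`, ordered by category
#'   then rank; texts are unique.
#' @export
extract_statements <- function(assignment, pool, X, per_cluster = 3,
                               dedup_threshold = 0.95) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  X <- as.matrix(X)
  centers <- assignment$centroids
  k <- assignment$k
  d_all <- vapply(seq_len(k), function(j) {
    sqrt(rowSums((X - matrix(centers[j, ], nrow(X), ncol(X), byrow = TRUE))^2))
  }, numeric(nrow(X)))
  taken_texts <- character(0)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    members <- which(assignment$labels == j)
    own <- d_all[members, j]
    other <- if (k == 1) rep(Inf, length(members)) else {
      apply(d_all[members, -j, drop = FALSE], 1, min)
    }
    margin <- other - own
    ord <- members[order(own, members)]
    margin_of <- setNames(margin[order(own, members)], ord)
    chosen <- integer(0)
    for (idx in ord) {
      if (length(chosen) >= per_cluster) break
      if (margin_of[[as.character(idx)]] <= 0) next
      txt <- pool$sentences$sentence[idx]
      if (txt %in% taken_texts) next
      if (length(chosen) > 0) {
        cs <- cosine_matrix(pool$embedding[idx, , drop = FALSE],
                            pool$embedding[chosen, , drop = FALSE])
        if (any(cs > dedup_threshold)) next
      }
      chosen <- c(chosen, idx)
      taken_texts <- c(taken_texts, txt)
    }
    if (length(chosen) < per_cluster) {
      stop_qorient(
        paste0("Cluster ", j, " exhausted: only ", length(chosen),
               " admissible statements (need ", per_cluster, ")."),
        "qorient_cluster_error"
      )
    }
    out[[j]] <- tibble::tibble(
      category = j,
      text = pool$sentences$sentence[chosen],
      centroid_distance = unname(d_all[chosen, j]),
      margin = unname(margin_of[as.character(chosen)])
    )
  }
  res <- dplyr::bind_rows(out)
  res <- tibble::tibble(statement_id = sprintf("S%02d", seq_len(nrow(res))), res)
  class(res) <- c("statement_set", class(res))
  res
}

#' Write / read a statement set as CSV
#'
#' @param statements A `statement_set` tibble.
#' @param path Output path.
#' @export
write_statements <- function(statements, path) {
  readr::write_csv(tibble::as_tibble(unclass(statements))[
    , c("category", "statement_id", "text", "centroid_distance", "margin")],
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_statements
#' @export
read_statements <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    category = readr::col_integer(),
    statement_id = readr::col_character(),
    text = readr::col_character(),
    centroid_distance = readr::col_double(),
    margin = readr::col_double()
  ), progress = FALSE)
  df <- df[, c("statement_id", "category", "text", "centroid_distance", "margin")]
  class(df) <- c("statement_set", class(df))
  df
}

#' Build a Q-statement set from a corpus in one call
#'
#' Convenience wrapper: pool, reduce, (optionally) select K, cluster, extract.
#'
#' @inheritParams sentence_pool
#' @param k Number of clusters; if `NULL`, chosen by [select_k()] over
#'   `k_grid`.
#' @param k_grid Grid for K selection when `k` is `NULL`.
#' @param variance_target PCA retained-variance fraction.
#' @param per_cluster Statements per cluster.
#' @param dedup_threshold Near-duplicate cosine threshold.
#' @param seed Integer seed.
#' @return A list of class `statement_build`: `statements` (the
#'   [extract_statements()] tibble), `k_selection` (or `NULL`), `assignment`,
#'   `reduction`, `pool`.
#' @export
build_statements <- function(corpus, k = NULL, k_grid = 2:10,
                             variance_target = 0.9, per_cluster = 3,
                             dedup_threshold = 0.95, seed = 1,
                             backend = "hash_tfidf", ...) {
  pool <- sentence_pool(corpus, backend = backend, ...)
  red <- reduce_dimensions(pool$embedding, variance_target)
  ksel <- NULL
  if (is.null(k)) {
    ksel <- select_k(red$x, k_grid = k_grid, seed = seed)
    k <- ksel$chosen_k
  }
  assignment <- cluster_sentences(red$x, k, seed = seed)
  statements <- extract_statements(assignment, pool, red$x,
                                   per_cluster = per_cluster,
                                   dedup_threshold = dedup_threshold)
  structure(
    list(statements = statements, k_selection = ksel, assignment = assignment,
         reduction = red, pool = pool),
    class = "statement_build"
  )
}
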