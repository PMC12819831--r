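# Shared fixtures and independent oracles, all built in code at test time.

tiny_corpus <- function() {
  audit_corpus(tibble::tibble(
    institution_id = c("A", "A", "B", "B"),
    record_id = c("a1", "a2", "b1", "b2"),
    text = c(
      "The corridor has continuous handrails. Lighting is uniform.",
      "Bedrooms hold a nursing bed and a bedside cabinet.",
      "The garden holds thriving camphor trees and lush groundcover.",
      "A shaded pergola corridor links resting pavilions."
    )
  ))
}

# Three well-separated isotropic Gaussian blobs in 2-D.
gaussian_blobs <- function(n_per = 20, centers = rbind(c(0, 0), c(1, 0), c(0, 1)),
                           sigma = 0.05, seed = 42) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
      cbind(stats::rnorm(n_per, centers[j, 1], sigma),
            stats::rnorm(n_per, centers[j, 2], sigma))
    }))
    list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# Brute-force mean silhouette: the O(n^2) textbook formula, independent of
# cluster::silhouette.
silhouette_oracle <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(D[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force varimax maximum for a 2-factor loading matrix: exhaustive grid
# over the planar rotation angle (criterion has period pi/2), vectorized over
# the grid.
varimax_planar_oracle <- function(L, normalize = TRUE, step = 1e-4) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    L <- L / h
  }
  theta <- seq(0, pi / 2, by = step)
  n <- nrow(L)
  B1 <- outer(L[, 1], cos(theta)) + outer(L[, 2], sin(theta))
  B2 <- -outer(L[, 1], sin(theta)) + outer(L[, 2], cos(theta))
  crit <- (colSums(B1^4) / n - (colSums(B1^2) / n)^2) +
    (colSums(B2^4) / n - (colSums(B2^2) / n)^2)
  max(crit)
}

# Varimax criterion on raw (optionally Kaiser-normalized) loadings; mirrors
# the package's definition for comparing iterates with the oracle.
varimax_crit <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    L <- L / h
  }
  n <- nrow(L)
  sq <- L^2
  sum(colSums(sq^2) / n - (colSums(sq) / n)^2)
}

# A forced-grid Q-sort matrix built directly from random scores.
random_qsorts <- function(n_inst = 12, grid = q_grid(), seed = 99) {
  withr::with_seed(seed, {
    scores <- matrix(stats::rnorm(n_inst * grid$n_statements), n_inst)
    rownames(scores) <- sprintf("i%02d", seq_len(n_inst))
    colnames(scores) <- sprintf("S%02d", seq_len(grid$n_statements))
    build_qsort_matrix(scores, grid)
  })
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_setequal(as.character(a), as.character(b))
}
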