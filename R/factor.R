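# Inverted (by-person) factor analysis of Q-sorts: correlation, principal
# component extraction, Kaiser-Guttman screening, varimax and manual
# rotation, defining-sort flagging, factor scores and arrays, composite
# reliability, and distinguishing/consensus statement statistics.

#' By-person correlation matrix of Q-sorts
#'
#' Pearson correlation between institutions' Q-sort columns (raw grid
#' integers; the forced distribution makes columns comparable by
#' construction). High pairwise correlation indicates overlapping
#' orientations.
#'
#' @param qsorts A statements x institutions `qsort_matrix` (or plain integer
#'   matrix).
#' @return An institutions x institutions correlation matrix.
#' @export
q_correlate <- function(qsorts) {
  qsorts <- unclass(qsorts)
  if (ncol(qsorts) < 2) {
    stop_qorient("Need at least 2 institutions.", "qorient_dim_error")
  }
  sds <- apply(qsorts, 2, sd)
  stopifnot(all(sds > 0)) # guaranteed by the grid invariant
  R <- cor(qsorts)
  (R + t(R)) / 2
}

#' Loading significance threshold
#'
#' The conventional standard-error bound for a Q-sort loading:
#' `z_crit / sqrt(n_statements)`. With the default `z_crit = 2.58` this is
#' the P < 0.01 criterion.
#'
#' @param n_statements Number of statements in the Q set.
#' @param z_crit Critical normal deviate (2.58 for P < 0.01, 1.96 for
#'   P < 0.05).
#' @return The loading threshold.
#' @examples
#' significance_threshold(54) # ~0.351
#' @export
significance_threshold <- function(n_statements, z_crit = 2.58) {
  stopifnot(is_count(n_statements))
  z_crit / sqrt(n_statements)
}

# Sign convention: flip each loading column so its largest-magnitude entry is
# positive. Eigenvector sign is arbitrary; reports must be stable.
fix_signs <- function(loadings) {
  for (j in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) loadings[, j] <- -loadings[, j]
  }
  loadings
}

#' Extract factors from a correlation matrix by principal components
#'
#' Eigendecomposition of the by-person correlation matrix; loading column
#' `f` is `eigenvector_f * sqrt(eigenvalue_f)`. Explained variance per factor
#' is `100 * eigenvalue / n` (n institutions); the full eigenvalue spectrum
#' is kept for scree plots and trace checks.
#'
#' @param R Correlation matrix.
#' @param max_factors Number of leading factors whose loadings are retained.
#' @param n_statements Number of statements behind each Q-sort (used for the
#'   significance threshold).
#' @param z_crit Critical deviate for the threshold (default 2.58).
#' @return An object of class `q_factor_solution`: `loadings`
#'   (institutions x max_factors, sign-fixed), `eigenvalues` (retained),
#'   `all_eigenvalues`, `explained_pct`, `cumulative_pct`, `rotation_log`,
#'   `n_statements`, `threshold`, `n_institutions`.
#' @export
q_extract <- function(R, max_factors = 8, n_statements, z_crit = 2.58) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) {
    stop_qorient("Correlation matrix must be symmetric.", "qorient_dim_error")
  }
  n <- ncol(R)
  if (max_factors < 1 || max_factors > n) {
    stop_qorient("`max_factors` out of range.", "qorient_config_error")
  }
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- eig$values
  m <- max_factors
  loadings <- eig$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(m)], 0)), m)
  rownames(loadings) <- colnames(R)
  colnames(loadings) <- paste0("F", seq_len(m))
  loadings <- fix_signs(loadings)
  explained <- 100 * vals[seq_len(m)] / n
  structure(
    list(
      loadings = loadings,
      eigenvalues = vals[seq_len(m)],
      all_eigenvalues = vals,
      explained_pct = explained,
      cumulative_pct = cumsum(explained),
      rotation_log = list(),
      n_statements = if (missing(n_statements)) NA_integer_ else as.integer(n_statements),
      threshold = if (missing(n_statements)) NA_real_ else significance_threshold(n_statements, z_crit),
      n_institutions = n
    ),
    class = "q_factor_solution"
  )
}

#' Kaiser-Guttman screen for the admissible factor count
#'
#' Counts the leading factors that satisfy both admission criteria: an
#' eigenvalue strictly greater than 1.0, and at least two Q-sorts that load
#' significantly on the factor *and* carry the strict majority of their
#' communality there (the defining-sort notion of standard Q-analysis
#' software). When the number of sorts far exceeds the number of statements
#' the by-person correlation matrix is rank-deficient and residual
#' eigenvalues are inflated well above 1, so the bare eigenvalue rule admits
#' everything; requiring two would-be defining sorts is what actually stops
#' the count at the scree inflection, mirroring how the eigenvalue rule,
#' the two-sort rule and the scree plot are applied jointly in practice.
#'
#' @param solution A `q_factor_solution`.
#' @param threshold Loading threshold; defaults to the solution's.
#' @return The number of admissible leading factors.
#' @export
kaiser_guttman_screen <- function(solution, threshold = NULL) {
  threshold <- threshold %||% solution$threshold
  if (is.na(threshold)) {
    stop_qorient("No significance threshold available; pass `n_statements` to `q_extract()`.",
                 "qorient_config_error")
  }
  L <- solution$loadings
  h2 <- rowSums(L^2)
  count <- 0L
  for (f in seq_along(solution$eigenvalues)) {
    defining <- abs(L[, f]) > threshold & L[, f]^2 > h2 / 2
    ok <- solution$eigenvalues[f] > 1.0 && sum(defining) >= 2
    if (!ok) break
    count <- count + 1L
  }
  count
}

#' Retain the leading factors of a solution
#'
#' @param solution A `q_factor_solution`.
#' @param n_factors Number of leading factors to keep.
#' @return The trimmed `q_factor_solution`.
#' @export
retain_factors <- function(solution, n_factors) {
  stopifnot(is_count(n_factors), n_factors <= ncol(solution$loadings))
  solution$loadings <- solution$loadings[, seq_len(n_factors), drop = FALSE]
  solution$eigenvalues <- solution$eigenvalues[seq_len(n_factors)]
  solution$explained_pct <- solution$explained_pct[seq_len(n_factors)]
  solution$cumulative_pct <- solution$cumulative_pct[seq_len(n_factors)]
  solution
}

# Raw varimax criterion: sum over factors of the variance of squared
# loadings. `normalize` applies Kaiser row-normalization first.
varimax_criterion <- function(loadings, normalize = TRUE) {
  L <- loadings
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h < 1e-12] <- 1
    L <- L / h
  }
  n <- nrow(L)
  sq <- L^2
  sum(colSums(sq^2) / n - (colSums(sq) / n)^2)
}

# Optimal planar varimax angle for a column pair (Kaiser's closed form).
planar_varimax_angle <- function(u, v) {
  n <- length(u)
  a <- u^2 - v^2
  b <- 2 * u * v
  A <- sum(a); B <- sum(b)
  C <- sum(a^2 - b^2); D <- sum(2 * a * b)
  num <- D - 2 * A * B / n
  den <- C - (A^2 - B^2) / n
  atan2(num, den) / 4
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the (optionally Kaiser-normalized) varimax
#' criterion by cyclic pairwise planar rotations. The criterion is
#' non-decreasing across sweeps; iteration stops when a full sweep improves
#' it by less than `tol`. On non-convergence a warning carries the criterion
#' trace and the best iterate is returned. Communalities are invariant.
#'
#' @param solution A `q_factor_solution` (or a bare loading matrix).
#' @param normalize Apply Kaiser row-normalization (default `TRUE`).
#' @param tol Convergence tolerance on the criterion gain per sweep.
#' @param max_iter Maximum number of sweeps.
#' @return The rotated solution (same class as the input); for solutions the
#'   rotation is appended to `rotation_log` and the accumulated rotation
#'   matrix is attached as attribute `rotmat` of the loadings.
#' @export
rotate_varimax <- function(solution, normalize = TRUE, tol = 1e-8,
                           max_iter = 1000) {
  is_solution <- inherits(solution, "q_factor_solution")
  L <- if (is_solution) solution$loadings else as.matrix(solution)
  m <- ncol(L)
  if (m < 1) stop_qorient("Need at least one factor.", "qorient_config_error")
  rot <- diag(m)
  if (m > 1) {
    h <- sqrt(rowSums(L^2))
    h[h < 1e-12] <- 1
    W <- if (normalize) L / h else L
    crit_trace <- varimax_criterion(W, normalize = FALSE)
    converged <- FALSE
    for (sweep in seq_len(max_iter)) {
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          phi <- planar_varimax_angle(W[, i], W[, j])
          if (abs(phi) < 1e-15) next
          cs <- cos(phi); sn <- sin(phi)
          Wi <- W[, i] * cs + W[, j] * sn
          Wj <- -W[, i] * sn + W[, j] * cs
          W[, i] <- Wi; W[, j] <- Wj
          ri <- rot[, i] * cs + rot[, j] * sn
          rj <- -rot[, i] * sn + rot[, j] * cs
          rot[, i] <- ri; rot[, j] <- rj
        }
      }
      crit_trace <- c(crit_trace, varimax_criterion(W, normalize = FALSE))
      gain <- diff(utils::tail(crit_trace, 2))
      if (gain < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      rlang::warn("Varimax did not converge; returning best iterate.",
                  data = list(criterion_trace = crit_trace))
    }
    L <- (if (normalize) W * h else W)
  }
  dimnames(L) <- dimnames(if (is_solution) solution$loadings else solution)
  # keep the rotation matrix consistent with the sign convention
  for (j in seq_len(ncol(L))) {
    peak <- which.max(abs(L[, j]))
    if (L[peak, j] < 0) {
      L[, j] <- -L[, j]
      rot[, j] <- -rot[, j]
    }
  }
  if (!is_solution) return(L)
  attr(L, "rotmat") <- rot
  solution$loadings <- L
  solution$rotation_log <- c(solution$rotation_log,
                             list(list(type = "varimax",
                                       normalize = normalize)))
  solution
}

#' Manual Givens rotation of a factor pair
#'
#' Rotates the loading plane of factors `factor_a` and `factor_b` by the
#' given angle; all other columns are unchanged, so communalities are
#' invariant. "Counterclockwise" maps to a positive angle in the (a, b)
#' plane with factor `a` on the abscissa. The rotation is appended to the
#' solution's `rotation_log` so an analysis can be replayed.
#'
#' @param solution A `q_factor_solution`.
#' @param factor_a,factor_b Distinct factor column indices.
#' @param degrees Rotation angle in degrees.
#' @param direction `"counterclockwise"` (default) or `"clockwise"`.
#' @return The rotated `q_factor_solution`.
#' @export
manual_rotate <- function(solution, factor_a, factor_b, degrees,
                          direction = c("counterclockwise", "clockwise")) {
  direction <- match.arg(direction)
  m <- ncol(solution$loadings)
  if (!is_count(factor_a) || !is_count(factor_b) ||
      factor_a > m || factor_b > m) {
    stop_qorient("Factor index out of range.", "qorient_config_error")
  }
  if (factor_a == factor_b) {
    stop_qorient("`factor_a` and `factor_b` must differ.", "qorient_config_error")
  }
  signed <- if (direction == "clockwise") -degrees else degrees
  theta <- signed * pi / 180
  L <- solution$loadings
  a <- L[, factor_a]; b <- L[, factor_b]
  L[, factor_a] <- a * cos(theta) - b * sin(theta)
  L[, factor_b] <- a * sin(theta) + b * cos(theta)
  solution$loadings <- L
  solution$rotation_log <- c(solution$rotation_log,
                             list(list(type = "manual",
                                       pair = c(factor_a, factor_b),
                                       degrees = signed)))
  solution
}

#' Flag defining Q-sorts
#'
#' An institution is flagged as defining on factor `f` when its absolute
#' loading exceeds the significance threshold AND its squared loading
#' strictly exceeds half its communality (the strict-majority rule); at most
#' one factor per institution can satisfy the latter.
#'
#' @param solution A `q_factor_solution`.
#' @param threshold Loading threshold; defaults to the solution's.
#' @return A logical institutions x factors matrix with at most one `TRUE`
#'   per row.
#' @export
flag_defining <- function(solution, threshold = NULL) {
  threshold <- threshold %||% solution$threshold
  if (is.null(threshold) || is.na(threshold) || threshold <= 0) {
    stop_qorient("A positive loading threshold is required.",
                 "qorient_config_error")
  }
  L <- solution$loadings
  h2 <- rowSums(L^2)
  flags <- (abs(L) > threshold) & (L^2 > h2 / 2)
  dimnames(flags) <- dimnames(L)
  flags
}

#' Weighted factor z-scores
#'
#' For each factor, defining sorts are weighted `w = f / (1 - f^2)` (the
#' standard Q-methodology weight, increasing with loading `f`); the factor's
#' statement score is the weighted mean of the defining sorts' grid values,
#' standardized across statements to mean 0, sd 1. The result is the
#' idealized sort the factor's defining institutions collectively present.
#'
#' @param qsorts Statements x institutions `qsort_matrix`.
#' @param solution A `q_factor_solution`.
#' @param flags Defining-sort flags from [flag_defining()].
#' @return A statements x factors matrix of z-scores.
#' @export
factor_zscores <- function(qsorts, solution, flags = flag_defining(solution)) {
  qsorts <- unclass(qsorts)
  L <- solution$loadings
  m <- ncol(L)
  out <- matrix(NA_real_, nrow(qsorts), m,
                dimnames = list(rownames(qsorts), colnames(L)))
  for (f in seq_len(m)) {
    members <- which(flags[, f])
    if (length(members) == 0) {
      stop_qorient(paste0("Factor ", colnames(L)[f] %||% f,
                          " has zero defining sorts."),
                   "qorient_flag_error")
    }
    fl <- L[members, f]
    w <- fl / (1 - fl^2)
    raw <- as.numeric(qsorts[, members, drop = FALSE] %*% w) / sum(w)
    out[, f] <- (raw - mean(raw)) / sd(raw)
  }
  out
}

#' Factor arrays
#'
#' Re-imposes the forced grid on each factor's z-scores: statements are
#' ranked by descending z and assigned grid values exactly as
#' [force_distribution()] (ties by statement index).
#'
#' @param zscores Statements x factors z-score matrix.
#' @param grid A [q_grid()] whose count sum equals the statement count.
#' @return A statements x factors integer matrix of grid values.
#' @export
factor_arrays <- function(zscores, grid = q_grid()) {
  out <- apply(zscores, 2, force_distribution, grid = grid)
  dimnames(out) <- dimnames(zscores)
  out
}

#' Composite reliability and standard error of factor z-scores
#'
#' Spearman-Brown composite reliability for a factor with `p` defining sorts
#' and assumed per-sort reliability `avg_rel_coef`:
#' `CR = (avg_rel_coef * p) / (1 + (p - 1) * avg_rel_coef)`. The standard
#' error of the factor's z-scores is `sqrt(1 - CR)` with CR first rounded to
#' 3 decimals — the reporting convention of standard Q-analysis software,
#' which the published tables follow.
#'
#' @param flags Defining-sort flag matrix (or a named integer vector of
#'   defining-sort counts per factor).
#' @param avg_rel_coef Assumed per-sort reliability (default 0.80).
#' @return A tibble of class `q_reliability`: `factor`, `p`, `avg_rel_coef`,
#'   `composite_reliability` (unrounded), `se_zscores`
#'   (`sqrt(1 - round(CR, 3))`).
#' @examples
#' q_reliability(c(F1 = 180, F2 = 135, F3 = 40, F4 = 5))
#' @export
q_reliability <- function(flags, avg_rel_coef = 0.8) {
  p <- if (is.matrix(flags)) colSums(flags) else flags
  if (any(p < 1)) {
    stop_qorient("Every factor needs at least one defining sort.",
                 "qorient_flag_error")
  }
  cr <- (avg_rel_coef * p) / (1 + (p - 1) * avg_rel_coef)
  out <- tibble::tibble(
    factor = names(p) %||% paste0("F", seq_along(p)),
    p = as.integer(p),
    avg_rel_coef = avg_rel_coef,
    composite_reliability = unname(cr),
    se_zscores = unname(sqrt(1 - round(cr, 3)))
  )
  class(out) <- c("q_reliability", class(out))
  out
}

# z deviates for the supported significance levels.
z_of_alpha <- function(alpha) {
  lookup <- c("0.05" = 1.96, "0.01" = 2.58)
  key <- format(alpha)
  if (!key %in% names(lookup)) {
    stop_qorient(paste0("Unsupported significance level: ", alpha),
                 "qorient_config_error")
  }
  unname(lookup[key])
}

#' Distinguishing statements
#'
#' A statement distinguishes factor `f` at level `alpha` when, for EVERY
#' other factor `g`, `|z_sf - z_sg| > z_alpha * sqrt(SE_f^2 + SE_g^2)`
#' (`z_0.05 = 1.96`, `z_0.01 = 2.58`). Each statement-factor pair is
#' annotated with the highest level attained (the D vs D* convention: `D` at
#' P < 0.05, `D*` at P < 0.01).
#'
#' @param zscores Statements x factors z-score matrix (needs >= 2 factors).
#' @param reliability A [q_reliability()] tibble aligned to the factors.
#' @param levels Significance levels to test, most to least permissive.
#' @return A tibble `statement_id`, `factor`, `level` (numeric alpha),
#'   `mark` (`"D"` or `"D*"`), one row per distinguishing statement-factor
#'   pair.
#' @export
distinguishing_statements <- function(zscores, reliability,
                                      levels = c(0.05, 0.01)) {
  m <- ncol(zscores)
  if (m < 2) {
    stop_qorient("Distinguishing statements need >= 2 factors.",
                 "qorient_config_error")
  }
  se <- reliability$se_zscores
  if (length(se) != m || anyNA(se)) {
    stop_qorient("Reliability SEs must be present for every factor.",
                 "qorient_config_error")
  }
  sed <- outer(se, se, function(a, b) sqrt(a^2 + b^2))
  ids <- rownames(zscores) %||% sprintf("S%02d", seq_len(nrow(zscores)))
  rows <- list()
  for (f in seq_len(m)) {
    others <- setdiff(seq_len(m), f)
    for (s in seq_len(nrow(zscores))) {
      attained <- NA_real_
      for (alpha in sort(levels, decreasing = TRUE)) {
        zc <- z_of_alpha(alpha)
        if (all(abs(zscores[s, f] - zscores[s, others]) >
                zc * sed[f, others])) {
          attained <- alpha
        } else {
          break
        }
      }
      if (!is.na(attained)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          statement_id = ids[s],
          factor = colnames(zscores)[f] %||% paste0("F", f),
          level = attained,
          mark = if (attained <= 0.01) "D*" else "D"
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(statement_id = character(), factor = character(),
                          level = numeric(), mark = character()))
  }
  dplyr::bind_rows(rows)
}

#' Consensus statements
#'
#' Statements that distinguish no factor at `alpha` and whose z-score
#' difference is non-significant for every factor pair.
#'
#' @inheritParams distinguishing_statements
#' @param alpha Significance level (default 0.05).
#' @return A character vector of statement ids.
#' @export
consensus_statements <- function(zscores, reliability, alpha = 0.05) {
  m <- ncol(zscores)
  if (m < 2) {
    stop_qorient("Consensus is undefined for a single factor.",
                 "qorient_config_error")
  }
  se <- reliability$se_zscores
  zc <- z_of_alpha(alpha)
  sed <- outer(se, se, function(a, b) sqrt(a^2 + b^2))
  ids <- rownames(zscores) %||% sprintf("S%02d", seq_len(nrow(zscores)))
  dist <- distinguishing_statements(zscores, reliability, levels = alpha)
  keep <- vapply(seq_len(nrow(zscores)), function(s) {
    pairs_ok <- TRUE
    for (f in seq_len(m - 1)) {
      for (g in (f + 1):m) {
        if (abs(zscores[s, f] - zscores[s, g]) > zc * sed[f, g]) {
          pairs_ok <- FALSE
        }
      }
    }
    pairs_ok && !(ids[s] %in% dist$statement_id)
  }, logical(1))
  ids[keep]
}

#' Run the complete inverted factor analysis
#'
#' Correlation, extraction, Kaiser-Guttman screening, varimax rotation,
#' optional manual rotations, flagging, reliability, z-scores, arrays, and
#' distinguishing/consensus statistics in one call.
#'
#' @param qsorts A statements x institutions `qsort_matrix`.
#' @param n_factors Number of factors to retain; `NULL` (default) uses the
#'   Kaiser-Guttman screen.
#' @param max_factors Factors to examine at extraction (default 8).
#' @param z_crit Critical deviate for the loading threshold (default 2.58).
#' @param rotate `"varimax"` (default) or `"none"`.
#' @param manual_rotations Optional list of `list(pair = c(a, b), degrees =
#'   d)` applied after varimax.
#' @param avg_rel_coef Assumed per-sort reliability.
#' @param kaiser_normalize Kaiser row-normalization inside varimax.
#' @return An object of class `q_analysis`: `solution`, `n_factors`,
#'   `flags`, `reliability`, `zscores`, `arrays`, `distinguishing`,
#'   `consensus`, `correlation`, `grid`.
#' @export
q_analyze <- function(qsorts, n_factors = NULL, max_factors = 8,
                      z_crit = 2.58, rotate = c("varimax", "none"),
                      manual_rotations = list(), avg_rel_coef = 0.8,
                      kaiser_normalize = TRUE) {
  rotate <- match.arg(rotate)
  grid <- attr(qsorts, "grid") %||% q_grid()
  R <- q_correlate(qsorts)
  solution <- q_extract(R, max_factors = min(max_factors, ncol(R)),
                        n_statements = nrow(qsorts), z_crit = z_crit)
  if (is.null(n_factors)) {
    n_factors <- kaiser_guttman_screen(solution)
    if (n_factors < 1) {
      stop_qorient("No admissible factors under the Kaiser-Guttman screen.",
                   "qorient_screen_error")
    }
  }
  retained <- retain_factors(solution, n_factors)
  if (rotate == "varimax" && n_factors > 1) {
    retained <- rotate_varimax(retained, normalize = kaiser_normalize)
  }
  for (mr in manual_rotations) {
    retained <- manual_rotate(retained, mr$pair[1], mr$pair[2], mr$degrees,
                              direction = mr$direction %||% "counterclockwise")
  }
  flags <- flag_defining(retained)
  rel <- q_reliability(flags, avg_rel_coef = avg_rel_coef)
  z <- factor_zscores(qsorts, retained, flags)
  arrays <- factor_arrays(z, grid)
  dist <- if (n_factors >= 2) {
    distinguishing_statements(z, rel)
  } else {
    tibble::tibble(statement_id = character(), factor = character(),
                   level = numeric(), mark = character())
  }
  cons <- if (n_factors >= 2) consensus_statements(z, rel) else character(0)
  structure(
    list(
      solution = retained, n_factors = n_factors, flags = flags,
      reliability = rel, zscores = z, arrays = arrays,
      distinguishing = dist, consensus = cons, correlation = R,
      grid = grid, unrotated = solution
    ),
    class = "q_analysis"
  )
}

#' @export
print.q_factor_solution <- function(x, ...) {
  cat("<q_factor_solution> ", x$n_institutions, " institutions, ",
      ncol(x$loadings), " factors retained\n", sep = "")
  cat("Eigenvalues: ", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("Explained %: ", paste(round(x$explained_pct), collapse = ", "),
      " (cumulative ", round(utils::tail(x$cumulative_pct, 1)), "%)\n", sep = "")
  if (length(x$rotation_log) > 0) {
    cat("Rotations:   ",
        paste(vapply(x$rotation_log, function(r) r$type, character(1)),
              collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
print.q_analysis <- function(x, ...) {
  cat("<q_analysis> ", x$n_factors, " factors, ",
      sum(x$flags), "/", nrow(x$flags), " defining sorts\n", sep = "")
  print(x$reliability)
  invisible(x)
}
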