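# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a factor solution into a long loading table
#'
#' @param x A `q_factor_solution`.
#' @param ... Unused.
#' @return A tibble `institution_id`, `factor`, `loading`, `communality`.
#' @method tidy q_factor_solution
#' @export
tidy.q_factor_solution <- function(x, ...) {
  L <- x$loadings
  h2 <- rowSums(L^2)
  tibble::tibble(
    institution_id = rep(rownames(L) %||% as.character(seq_len(nrow(L))),
                         ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.numeric(L),
    communality = rep(h2, ncol(L))
  )
}

#' Glance at a factor solution
#'
#' @param x A `q_factor_solution`.
#' @param ... Unused.
#' @return A one-row tibble: factor count, total/cumulative explained
#'   variance, rotation count, loading threshold.
#' @method glance q_factor_solution
#' @export
glance.q_factor_solution <- function(x, ...) {
  tibble::tibble(
    n_institutions = x$n_institutions,
    n_factors = ncol(x$loadings),
    cumulative_explained_pct = utils::tail(x$cumulative_pct, 1),
    n_rotations = length(x$rotation_log),
    threshold = x$threshold
  )
}

#' Tidy a full Q analysis into the per-statement result table
#'
#' One row per statement and factor: z-score, array value, and the
#' distinguishing mark where attained.
#'
#' @param x A `q_analysis`.
#' @param ... Unused.
#' @return A tibble `statement_id`, `factor`, `zscore`, `array`, `mark`.
#' @method tidy q_analysis
#' @export
tidy.q_analysis <- function(x, ...) {
  ids <- rownames(x$zscores) %||% sprintf("S%02d", seq_len(nrow(x$zscores)))
  long <- tibble::tibble(
    statement_id = rep(ids, ncol(x$zscores)),
    factor = rep(colnames(x$zscores), each = nrow(x$zscores)),
    zscore = as.numeric(x$zscores),
    array = as.integer(x$arrays)
  )
  dplyr::left_join(long, x$distinguishing[, c("statement_id", "factor", "mark")],
                   by = c("statement_id", "factor"))
}

#' Glance at a Q analysis
#'
#' @param x A `q_analysis`.
#' @param ... Unused.
#' @return A one-row tibble of headline figures: factors, defining sorts,
#'   cumulative explained variance, consensus statement count.
#' @method glance q_analysis
#' @export
glance.q_analysis <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_institutions = nrow(x$flags),
    n_defining = sum(x$flags),
    cumulative_explained_pct = utils::tail(x$solution$cumulative_pct, 1),
    n_distinguishing = nrow(x$distinguishing),
    n_consensus = length(x$consensus)
  )
}

#' Tidy a K-selection diagnostic
#'
#' @param x A `k_selection`.
#' @param ... Unused.
#' @return The per-K metrics tibble with a `chosen` flag.
#' @method tidy k_selection
#' @export
tidy.k_selection <- function(x, ...) {
  dplyr::mutate(x$metrics, chosen = .data$k == x$chosen_k)
}

#' Elbow and validity curves for a K selection
#'
#' Three aligned panels over the K grid: within-cluster sum of squares
#' (elbow), mean silhouette (higher is better), and Davies-Bouldin index
#' (lower is better), with the chosen K marked.
#'
#' @param object A `k_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tidy.k_selection(object)
  long <- tidyr::pivot_longer(df, c("inertia", "silhouette", "dbi"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("inertia", "silhouette", "dbi"),
                        labels = c("within-cluster SS (elbow)",
                                   "mean silhouette", "Davies-Bouldin"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "K", y = NULL,
                  title = paste0("Cluster-count selection (chosen K = ",
                                 object$chosen_k, ")"))
}

#' Scree plot of a factor solution
#'
#' Eigenvalues of the unrotated correlation matrix against factor rank, with
#' the Kaiser-Guttman line at 1.0.
#'
#' @param object A `q_factor_solution`.
#' @param n_show Eigenvalues to display (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot q_factor_solution
#' @export
autoplot.q_factor_solution <- function(object, n_show = 8, ...) {
  vals <- utils::head(object$all_eigenvalues, n_show)
  df <- tibble::tibble(factor = seq_along(vals), eigenvalue = vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::scale_x_continuous(breaks = df$factor) +
    ggplot2::labs(x = "Factor", y = "Eigenvalue", title = "Scree plot")
}

#' Loading map of a Q analysis
#'
#' Institutions' loadings on the first two retained factors, colored by the
#' factor each defining sort is flagged on.
#'
#' @param object A `q_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot q_analysis
#' @export
autoplot.q_analysis <- function(object, ...) {
  L <- object$solution$loadings
  if (ncol(L) < 2) {
    stop_qorient("Loading map needs at least two factors.",
                 "qorient_config_error")
  }
  flagged_on <- apply(object$flags, 1, function(r) {
    if (any(r)) colnames(object$flags)[which(r)] else "none"
  })
  df <- tibble::tibble(F1 = L[, 1], F2 = L[, 2], defining = flagged_on)
  thr <- object$solution$threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$F1, y = .data$F2,
                                   color = .data$defining)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 3) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = 3) +
    ggplot2::labs(x = colnames(L)[1], y = colnames(L)[2],
                  color = "Defining on",
                  title = "Q-sort loadings on the first two factors")
}
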