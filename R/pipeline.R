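# Stage orchestration: a single config drives simulate / build-statements /
# sort / analyze / report, writing every artifact plus a checksummed run
# manifest so a rerun with identical config and inputs is verifiably
# identical for the deterministic stages.

#' Build a run configuration
#'
#' @param out_dir Output directory for all artifacts (created if missing).
#' @param seed Integer seed (mandatory; drives every stochastic stage).
#' @param corpus_path Path to an existing corpus (JSONL/CSV); `NULL` with
#'   `simulate = TRUE` generates one.
#' @param simulate Generate a synthetic corpus first?
#' @param n_institutions,noise_rate Synthetic generator settings (the
#'   four-orientation default configuration is used).
#' @param k Cluster count for statement building; `NULL` selects K over
#'   `k_grid`.
#' @param k_grid Grid for K selection.
#' @param per_cluster Statements per cluster.
#' @param dedup_threshold Near-duplicate cosine threshold.
#' @param variance_target PCA retained-variance fraction.
#' @param grid A [q_grid()]; `NULL` derives a quasi-normal 11-level grid from
#'   the statement count when possible (default grid for 54 statements).
#' @param max_factors Factors examined at extraction.
#' @param n_factors Factors retained; `NULL` uses the Kaiser-Guttman screen.
#' @param z_crit Critical deviate for the loading threshold.
#' @param manual_rotations List of `list(pair = c(a, b), degrees = d)`.
#' @param backend Embedding backend name.
#' @param embedding_dim Hash dimension for the default backend.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed,
                       corpus_path = NULL, simulate = is.null(corpus_path),
                       n_institutions = 60, noise_rate = 0.1,
                       k = 18, k_grid = 2:24, per_cluster = 3,
                       dedup_threshold = 0.95, variance_target = 0.9,
                       grid = NULL, max_factors = 8, n_factors = NULL,
                       z_crit = 2.58, manual_rotations = list(),
                       backend = "hash_tfidf", embedding_dim = 4096) {
  if (missing(seed)) {
    stop_qorient("`seed` is mandatory.", "qorient_config_error")
  }
  if (!simulate) {
    if (is.null(corpus_path) || !file.exists(corpus_path)) {
      stop_qorient("`corpus_path` must name an existing file when `simulate` is FALSE.",
                   "qorient_config_error")
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; CLI flags override file keys.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$grid) && is.character(raw$grid)) {
    raw$grid <- read_q_grid(raw$grid)
  }
  do.call(run_config, raw)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full objective Q pipeline
#'
#' Executes the configured stages in order — simulate (optional), statement
#' building, Q-sorting, factor analysis, reporting — writing each stage's
#' artifacts under `config$out_dir` and finally a JSON manifest with the
#' config snapshot, package version, per-artifact MD5 checksums, and stage
#' timings. Any stage error aborts with the stage name; artifacts already
#' written are preserved.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  timings <- list()
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_qorient(paste0("Stage `", stage, "` failed: ", conditionMessage(e)),
                   "qorient_stage_error")
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    stage_log(stage, "done")
    res
  }
  art <- function(name) {
    p <- file.path(config$out_dir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  corpus <- run_stage("corpus", {
    if (config$simulate) {
      gen <- generate_corpus(default_four_type_config(
        config$n_institutions, seed = config$seed,
        noise_rate = config$noise_rate))
      write_corpus(gen$corpus, art("corpus.jsonl"))
      readr::write_csv(gen$truth, art("ground_truth.csv"), progress = FALSE)
      gen$corpus
    } else {
      read_corpus(config$corpus_path)
    }
  })

  build <- run_stage("build-statements", {
    b <- build_statements(
      corpus, k = config$k, k_grid = config$k_grid,
      variance_target = config$variance_target,
      per_cluster = config$per_cluster,
      dedup_threshold = config$dedup_threshold,
      seed = config$seed, backend = config$backend,
      dim = config$embedding_dim
    )
    write_statements(b$statements, art("statements.csv"))
    if (!is.null(b$k_selection)) {
      readr::write_tsv(tidy(b$k_selection), art("k_selection.tsv"),
                       progress = FALSE)
    }
    b
  })

  grid <- config$grid %||% q_grid()
  qsorts <- run_stage("sort", {
    qs <- build_qsorts(corpus, build$statements, grid = grid,
                       backend = config$backend, dim = config$embedding_dim)
    write_qsorts(qs, art("qsorts.csv"))
    qs
  })

  analysis <- run_stage("analyze", {
    a <- q_analyze(qsorts, n_factors = config$n_factors,
                   max_factors = config$max_factors, z_crit = config$z_crit,
                   manual_rotations = config$manual_rotations)
    readr::write_csv(tidy(a$solution), art("loadings.csv"), progress = FALSE)
    readr::write_tsv(
      tibble::tibble(factor = seq_along(a$unrotated$all_eigenvalues),
                     eigenvalue = a$unrotated$all_eigenvalues),
      art("eigenvalues.tsv"), progress = FALSE)
    readr::write_csv(
      dplyr::mutate(tibble::as_tibble(a$flags),
                    institution_id = rownames(a$flags), .before = 1),
      art("flags.csv"), progress = FALSE)
    readr::write_csv(tidy(a), art("statement_scores.csv"), progress = FALSE)
    readr::write_csv(a$reliability, art("reliability.csv"), progress = FALSE)
    a
  })

  run_stage("report", {
    render_factor_report(analysis, build$statements,
                         art("factor_report.txt"))
    readr::write_tsv(
      tibble::tibble(factor = seq_along(analysis$unrotated$all_eigenvalues),
                     eigenvalue = round(analysis$unrotated$all_eigenvalues, 3)),
      art("scree.tsv"), progress = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("qorient")),
    config = config_snapshot(config),
    artifacts = purrr::map(setNames(artifacts, basename(artifacts)),
                           function(p) unname(tools::md5sum(p))),
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Serializable snapshot of a run_config (grids flattened to plain lists).
config_snapshot <- function(config) {
  snap <- unclass(config)
  if (!is.null(snap$grid)) {
    snap$grid <- list(column_values = snap$grid$column_values,
                      column_counts = snap$grid$column_counts)
  }
  snap
}

#' Render the human-readable factor report
#'
#' Per factor: the statements at the array extremes (+/-5 and +/-4) first,
#' each with its distinguishing mark (`D` at P < 0.05, `D*` at P < 0.01) and
#' all factors' array values side by side; then the remaining distinguishing
#' statements, the consensus list, and the scree data. Regeneration from the
#' same analysis is byte-identical.
#'
#' @param analysis A `q_analysis`.
#' @param statements The `statement_set` the sorts were built from.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
render_factor_report <- function(analysis, statements, path) {
  z <- analysis$zscores
  arr <- analysis$arrays
  ids <- rownames(z) %||% statements$statement_id
  text_of <- setNames(statements$text, statements$statement_id)
  lines <- c("Objective Q-methodology factor report",
             strrep("=", 60))
  gl <- glance(analysis)
  lines <- c(lines, sprintf(
    "%d factors; %d/%d defining sorts; cumulative explained variance %.0f%%",
    gl$n_factors, gl$n_defining, nrow(analysis$flags),
    gl$cumulative_explained_pct), "")
  for (f in colnames(z)) {
    lines <- c(lines, sprintf("Factor %s", f), strrep("-", 60))
    rel <- analysis$reliability[analysis$reliability$factor == f, ]
    lines <- c(lines, sprintf(
      "defining sorts: %d | composite reliability: %.3f | SE of z-scores: %.3f",
      rel$p, round(rel$composite_reliability, 3), round(rel$se_zscores, 3)))
    dist_f <- analysis$distinguishing[analysis$distinguishing$factor == f, ]
    marks <- setNames(dist_f$mark, dist_f$statement_id)
    mark_of <- function(s) {
      m <- unname(marks[s])
      if (length(m) == 0 || is.na(m)) "" else m
    }
    text_at <- function(s) {
      t <- unname(text_of[s])
      if (length(t) == 0 || is.na(t)) "" else t
    }
    extreme <- ids[abs(arr[, f]) >= 4][order(-arr[abs(arr[, f]) >= 4, f])]
    lines <- c(lines, "extreme statements (+/-4, +/-5):")
    for (s in extreme) {
      other <- paste(sprintf("%s=%+d", colnames(arr), arr[s, ]),
                     collapse = " ")
      lines <- c(lines, sprintf("  %-4s %+d %-3s [%s] %s",
                                s, arr[s, f], mark_of(s),
                                other, text_at(s)))
    }
    rest <- setdiff(dist_f$statement_id, extreme)
    if (nrow(dist_f) == 0) {
      lines <- c(lines, "distinguishing statements: none")
    } else if (length(rest) > 0) {
      lines <- c(lines, "other distinguishing statements:")
      for (s in rest) {
        lines <- c(lines, sprintf("  %-4s %+d %-3s z=%.3f",
                                  s, arr[s, f], mark_of(s), z[s, f]))
      }
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "Consensus statements",
             strrep("-", 60),
             if (length(analysis$consensus) == 0) "none" else
               paste(" ", analysis$consensus))
  lines <- c(lines, "", "Scree (unrotated eigenvalues)", strrep("-", 60))
  ev <- utils::head(analysis$unrotated$all_eigenvalues, 8)
  lines <- c(lines, paste(sprintf("F%d=%.3f", seq_along(ev), ev),
                          collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}
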