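#' The shipped sentence template bank
#'
#' Deterministic, slot-filled sentence templates for the synthetic corpus
#' generator: one entry per statement category, grouped into four thematic
#' blocks (`interior`, `layout`, `landscape`, `rehabilitation`). Each category
#' provides at least three templates whose `{slot}` placeholders are filled
#' from the category's option lists.
#'
#' @param path Optional path to an alternative template YAML.
#' @return A tibble with columns `category`, `block`, `templates` (list of
#'   character vectors), `slots` (list of named option lists).
#' @export
sentence_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sentence_templates.yaml",
                                package = "qorient")
  raw <- yaml::read_yaml(path)
  tibble::tibble(
    category = purrr::map_chr(raw$categories, "name"),
    block = purrr::map_chr(raw$categories, "block"),
    templates = purrr::map(raw$categories, function(c) unlist(c$templates)),
    slots = purrr::map(raw$categories, function(c) c$slots %||% list())
  )
}

#' Configure the synthetic corpus generator
#'
#' The generator plants a latent orientation-type mixture: each institution is
#' assigned one type; each of its audit sentences is drawn, with probability
#' `1 - noise_rate`, from a category sampled under the type's row of the
#' emphasis matrix, and otherwise from a uniformly random category.
#'
#' @param n_institutions Number of institutions to generate.
#' @param n_types Number of latent orientation types.
#' @param records_per_institution Single count or `c(min, max)` range of audit
#'   records per institution.
#' @param n_categories Number of statement categories used (must not exceed
#'   the template bank).
#' @param sentences_per_record `c(min, max)` range of sentences per record.
#' @param emphasis_matrix `n_types x n_categories` nonnegative matrix; each row
#'   is normalized to sum to 1 and gives the type's category distribution.
#' @param noise_rate Probability in `[0, 1]` of drawing a sentence's category
#'   uniformly instead of from the emphasis row.
#' @param type_proportions Optional type mixing proportions (default uniform).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param templates Template bank tibble, by default [sentence_templates()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_institutions,
                             n_types = 4,
                             records_per_institution = c(6, 12),
                             n_categories = 18,
                             sentences_per_record = c(3, 6),
                             emphasis_matrix = NULL,
                             noise_rate = 0.1,
                             type_proportions = NULL,
                             seed = 1,
                             templates = sentence_templates()) {
  stopifnot(is_count(n_institutions), is_count(n_types), is_count(n_categories))
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    stop_qorient("`noise_rate` must lie in [0, 1].", "qorient_config_error")
  }
  if (n_categories > nrow(templates)) {
    stop_qorient(
      paste0("`n_categories` (", n_categories, ") exceeds the template bank (",
             nrow(templates), " categories)."),
      "qorient_config_error"
    )
  }
  if (length(records_per_institution) == 1) {
    records_per_institution <- rep(records_per_institution, 2)
  }
  if (length(sentences_per_record) == 1) {
    sentences_per_record <- rep(sentences_per_record, 2)
  }
  if (is.null(emphasis_matrix)) {
    emphasis_matrix <- matrix(1 / n_categories, n_types, n_categories)
  }
  emphasis_matrix <- as.matrix(emphasis_matrix)
  if (!all(dim(emphasis_matrix) == c(n_types, n_categories)) ||
      any(emphasis_matrix < 0)) {
    stop_qorient("`emphasis_matrix` must be a nonnegative n_types x n_categories matrix.",
                 "qorient_config_error")
  }
  emphasis_matrix <- emphasis_matrix / rowSums(emphasis_matrix)
  type_proportions <- type_proportions %||% rep(1 / n_types, n_types)
  type_proportions <- type_proportions / sum(type_proportions)
  if (is.null(rownames(emphasis_matrix))) {
    rownames(emphasis_matrix) <- paste0("type_", seq_len(n_types))
  }
  colnames(emphasis_matrix) <- templates$category[seq_len(n_categories)]
  structure(
    list(
      n_institutions = as.integer(n_institutions),
      n_types = as.integer(n_types),
      records_per_institution = as.integer(records_per_institution),
      n_categories = as.integer(n_categories),
      sentences_per_record = as.integer(sentences_per_record),
      emphasis_matrix = emphasis_matrix,
      noise_rate = noise_rate,
      type_proportions = type_proportions,
      seed = as.integer(seed),
      templates = templates[seq_len(n_categories), ]
    ),
    class = "generator_config"
  )
}

#' Default four-orientation-type generator configuration
#'
#' Emulates the four published orientation types — interior-centric,
#' layout-oriented, landscape-centered, and rehabilitation-driven — by
#' concentrating each type's emphasis mass on its own block of statement
#' categories: 75% of a type's sentence mass is spread uniformly over its
#' block, the remaining 25% uniformly over all other categories, so every
#' institution still mentions every theme occasionally (as real audit text
#' does) while its block dominates.
#'
#' @inheritParams generator_config
#' @return A `generator_config` with a 4 x 18 block-structured emphasis matrix.
#' @export
default_four_type_config <- function(n_institutions, seed = 1,
                                     noise_rate = 0.1, ...) {
  templates <- sentence_templates()
  blocks <- c("interior", "layout", "landscape", "rehabilitation")
  n_cat <- nrow(templates)
  emphasis <- matrix(0, length(blocks), n_cat,
                     dimnames = list(blocks, templates$category))
  for (b in seq_along(blocks)) {
    own <- templates$block == blocks[b]
    emphasis[b, own] <- 0.75 / sum(own)
    emphasis[b, !own] <- 0.25 / sum(!own)
  }
  generator_config(
    n_institutions = n_institutions,
    n_types = length(blocks),
    n_categories = n_cat,
    emphasis_matrix = emphasis,
    noise_rate = noise_rate,
    seed = seed,
    templates = templates,
    ...
  )
}

# Realize one sentence from a category: pick a template uniformly, fill each
# slot uniformly. Consumes RNG.
realize_sentence <- function(templates, category_idx) {
  row <- templates[category_idx, ]
  tpl <- sample(row$templates[[1]], 1)
  for (slot in names(row$slots[[1]])) {
    opts <- unlist(row$slots[[1]][[slot]])
    tpl <- sub(paste0("{", slot, "}"), sample(opts, 1), tpl, fixed = TRUE)
  }
  tpl
}

#' Generate a synthetic audit corpus with planted orientation types
#'
#' Draws each institution's type from the configured mixing proportions, then
#' generates its records sentence by sentence: with probability
#' `1 - noise_rate` the sentence's category is sampled from the type's
#' emphasis row, otherwise uniformly. The ground-truth labels are returned
#' beside the corpus, never embedded in it, so they cannot leak into the
#' pipeline.
#'
#' @param config A `generator_config`.
#' @return A list with elements `corpus` (an [audit_corpus()]) and `truth` (a
#'   tibble `institution_id`, `type`; the emphasis matrix is attached as
#'   attribute `emphasis_matrix`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_institutions
    inst_ids <- sprintf("inst_%03d", seq_len(n))
    types <- sample(rownames(config$emphasis_matrix), n, replace = TRUE,
                    prob = config$type_proportions)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      emph <- config$emphasis_matrix[types[i], ]
      n_rec <- sample(seq(config$records_per_institution[1],
                          config$records_per_institution[2]), 1)
      texts <- character(n_rec)
      for (r in seq_len(n_rec)) {
        n_sent <- sample(seq(config$sentences_per_record[1],
                             config$sentences_per_record[2]), 1)
        sentences <- character(n_sent)
        for (s in seq_len(n_sent)) {
          cat_idx <- if (stats::runif(1) < config$noise_rate) {
            sample.int(config$n_categories, 1)
          } else {
            sample.int(config$n_categories, 1, prob = emph)
          }
          sentences[s] <- realize_sentence(config$templates, cat_idx)
        }
        texts[r] <- paste(sentences, collapse = " ")
      }
      rows[[i]] <- tibble::tibble(
        institution_id = inst_ids[i],
        record_id = sprintf("%s_img_%02d", inst_ids[i], seq_len(n_rec)),
        text = texts
      )
    }
    corpus <- audit_corpus(dplyr::bind_rows(rows))
    truth <- tibble::tibble(institution_id = inst_ids, type = types)
    attr(truth, "emphasis_matrix") <- config$emphasis_matrix
    list(corpus = corpus, truth = truth)
  })
}

#' Score type recovery of a factor analysis against ground truth
#'
#' Matches retained factors to planted types one-to-one (the assignment
#' maximizing agreement over all permutations) and reports the fraction of
#' institutions flagged as defining on the factor matched to their true type.
#'
#' @param flags Defining-sort flag matrix (institutions x factors, rownames =
#'   institution ids), e.g. from [flag_defining()].
#' @param truth Ground-truth tibble from [generate_corpus()] (columns
#'   `institution_id`, `type`).
#' @return A list: `match_rate` (fraction of all institutions defining on
#'   their matched factor), `assignment` (named character vector factor ->
#'   type), `table` (type x factor contingency table of defining sorts).
#' @export
score_recovery <- function(flags, truth) {
  ids <- rownames(flags)
  stopifnot(!is.null(ids), all(ids %in% truth$institution_id))
  type_of <- setNames(truth$type, truth$institution_id)[ids]
  factors <- colnames(flags)
  types <- sort(unique(truth$type))
  tab <- matrix(0L, length(types), length(factors),
                dimnames = list(types, factors))
  for (f in factors) {
    flagged <- ids[flags[, f]]
    t_counts <- table(factor(type_of[flagged], levels = types))
    tab[, f] <- as.integer(t_counts)
  }
  # exact one-to-one assignment over permutations (both sides are tiny)
  k <- min(length(types), length(factors))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- NULL
  best_score <- -1L
  for (p in perms(seq_along(factors))) {
    sel <- p[seq_len(k)]
    score <- sum(tab[cbind(seq_len(k), sel[seq_len(min(k, length(types)))])])
    if (score > best_score) {
      best_score <- score
      best <- sel
    }
  }
  assignment <- setNames(types[seq_len(k)], factors[best[seq_len(k)]])
  list(
    match_rate = best_score / length(unique(truth$institution_id)),
    assignment = assignment,
    table = tab
  )
}
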