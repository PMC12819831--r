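#' Construct an audit corpus
#'
#' An audit corpus holds free-text environmental audit records for a set of
#' institutions: one row per record, with an opaque institution key, a record
#' key unique within the corpus, the audit text, and optional dimension tags.
#' Text is whitespace-normalized at construction (runs of whitespace collapsed,
#' ends stripped); no other mutation is applied.
#'
#' @param records A data frame with columns `institution_id`, `record_id`,
#'   `text`, and optionally `tags` (a list column of character vectors).
#' @return A tibble of class `audit_corpus` with columns `institution_id`,
#'   `record_id`, `text`, `tags`; row order is preserved.
#' @examples
#' audit_corpus(data.frame(
#'   institution_id = "inst-1", record_id = "r1",
#'   text = "Corridor handrails are continuous. Lighting is uniform."
#' ))
#' @export
audit_corpus <- function(records) {
  if (!is.data.frame(records)) {
    stop_qorient("`records` must be a data frame.", "qorient_schema_error")
  }
  required <- c("institution_id", "record_id", "text")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop_qorient(
      paste0("Missing required field(s): ", paste(missing, collapse = ", "), "."),
      "qorient_schema_error"
    )
  }
  out <- tibble::as_tibble(records[, intersect(c(required, "tags"), names(records))])
  if (!"tags" %in% names(out)) {
    out$tags <- vector("list", nrow(out))
  } else if (!is.list(out$tags)) {
    out$tags <- as.list(out$tags)
  }
  if (nrow(out) == 0) {
    stop_qorient("Corpus has no records.", "qorient_empty_corpus_error")
  }
  out$institution_id <- as.character(out$institution_id)
  out$record_id <- as.character(out$record_id)
  out$text <- normalize_ws(as.character(out$text))
  bad <- which(is.na(out$text) | out$text == "")
  if (length(bad) > 0) {
    stop_qorient(
      paste0("Field `text` empty after whitespace normalization at row(s): ",
             paste(head(bad, 5), collapse = ", "), "."),
      "qorient_schema_error"
    )
  }
  key <- paste(out$institution_id, out$record_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_qorient("(institution_id, record_id) pairs must be unique.",
                 "qorient_schema_error")
  }
  class(out) <- c("audit_corpus", class(out))
  out
}

#' Number of institutions / records in a corpus
#'
#' @param corpus An `audit_corpus`.
#' @return An integer count.
#' @export
n_institutions <- function(corpus) {
  length(unique(corpus$institution_id))
}

#' @rdname n_institutions
#' @export
n_records <- function(corpus) {
  nrow(corpus)
}

#' Index of records by institution
#'
#' Partitions the record rows by institution. Every record appears in exactly
#' one element, so the index is lossless and duplication-free.
#'
#' @param corpus An `audit_corpus`.
#' @return A named list of tibbles, one per institution, in first-appearance
#'   order.
#' @export
institution_index <- function(corpus) {
  ids <- unique(corpus$institution_id)
  split(tibble::as_tibble(unclass(corpus)),
        factor(corpus$institution_id, levels = ids))[ids]
}

#' Read an audit corpus from JSONL or CSV
#'
#' JSONL is the canonical interchange format (one JSON object per line with
#' keys `institution_id`, `record_id`, `text`, optional `tags`); CSV uses the
#' identical header. Free text with embedded commas and newlines is fragile in
#' CSV, hence the JSONL default.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; defaults from the file extension.
#' @return An `audit_corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_qorient(paste0("File not found: ", path), "qorient_io_error")
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      stop_qorient("Empty corpus file.", "qorient_empty_corpus_error")
    }
    rows <- purrr::map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    df <- tibble::tibble(
      institution_id = purrr::map_chr(rows, function(r) as.character(r$institution_id %||% NA_character_)),
      record_id = purrr::map_chr(rows, function(r) as.character(r$record_id %||% NA_character_)),
      text = purrr::map_chr(rows, function(r) as.character(r$text %||% NA_character_)),
      tags = purrr::map(rows, function(r) as.character(r$tags %||% character()))
    )
    for (fld in c("institution_id", "record_id", "text")) {
      if (anyNA(df[[fld]])) {
        stop_qorient(paste0("Missing required field `", fld, "` in JSONL record."),
                     "qorient_schema_error")
      }
    }
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (nrow(df) == 0) {
      stop_qorient("Empty corpus file.", "qorient_empty_corpus_error")
    }
    if ("tags" %in% names(df)) {
      df$tags <- purrr::map(df$tags, function(t) {
        if (is.na(t) || t == "") character() else strsplit(t, ";", fixed = TRUE)[[1]]
      })
    }
  }
  audit_corpus(df)
}

#' Write an audit corpus to JSONL or CSV
#'
#' The written file reads back (with [read_corpus()]) to a corpus equal to the
#' input; unicode text survives the round trip.
#'
#' @param corpus An `audit_corpus`.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (!inherits(corpus, "audit_corpus")) {
    corpus <- audit_corpus(corpus)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_qorient(paste0("Directory does not exist: ", dir), "qorient_io_error")
  }
  if (format == "jsonl") {
    lines <- purrr::pmap_chr(
      list(corpus$institution_id, corpus$record_id, corpus$text, corpus$tags),
      function(i, r, t, g) {
        jsonlite::toJSON(
          list(institution_id = i, record_id = r, text = t, tags = as.character(g)),
          auto_unbox = TRUE
        )
      }
    )
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- tibble::tibble(
      institution_id = corpus$institution_id,
      record_id = corpus$record_id,
      text = corpus$text,
      tags = purrr::map_chr(corpus$tags, paste, collapse = ";")
    )
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' The shipped dimension catalogue
#'
#' The indicator catalogue used to instruct an external image-auditing model:
#' indoor, outdoor, and free dimensions, each with its indicator text. Loaded
#' verbatim from the YAML shipped with the package.
#'
#' @param path Optional path to an alternative catalogue YAML.
#' @return A tibble with columns `group` (`indoor`/`outdoor`/`free`), `name`,
#'   `indicators`.
#' @export
dimension_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dimension_catalogue.yaml",
                                package = "qorient")
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw$dimensions, function(d) {
    tibble::tibble(group = d$group, name = d$name, indicators = d$indicators)
  })
  if (anyDuplicated(out$name)) {
    stop_qorient("Dimension names must be unique.", "qorient_schema_error")
  }
  out$group <- factor(out$group, levels = c("indoor", "outdoor", "free"))
  out
}

#' Run an external audit adapter over image references
#'
#' The image-auditing step itself (a multimodal model describing institution
#' photographs) is outside this package; it is exposed only as an adapter
#' contract. An adapter is a plain function `function(image_ref, catalogue)`
#' returning one free-text audit description; no network code lives in the
#' core.
#'
#' @param images A data frame with columns `institution_id`, `record_id`, and
#'   `image_ref` (an opaque reference the adapter understands).
#' @param adapter A function of `(image_ref, catalogue)` returning a single
#'   non-empty character string.
#' @param catalogue A dimension catalogue tibble, by default
#'   [dimension_catalogue()].
#' @return An `audit_corpus` with one record per image.
#' @export
audit_with_adapter <- function(images, adapter, catalogue = dimension_catalogue()) {
  stopifnot(is.function(adapter))
  required <- c("institution_id", "record_id", "image_ref")
  missing <- setdiff(required, names(images))
  if (length(missing) > 0) {
    stop_qorient(
      paste0("Missing required field(s): ", paste(missing, collapse = ", "), "."),
      "qorient_schema_error"
    )
  }
  text <- purrr::map_chr(images$image_ref, function(ref) {
    as.character(adapter(ref, catalogue))
  })
  audit_corpus(tibble::tibble(
    institution_id = images$institution_id,
    record_id = images$record_id,
    text = text
  ))
}

#' @export
print.audit_corpus <- function(x, ...) {
  cat("<audit_corpus> ", n_records(x), " records, ",
      n_institutions(x), " institutions\n", sep = "")
  NextMethod()
}
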