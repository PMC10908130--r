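# Corpus input/output and validation.
#
# A corpus is a data.frame (class "safe_corpus") with one row per
# bibliographic record and columns:
#   record_id  opaque unique string
#   title      character (may be empty)
#   abstract   character (may be empty)
#   year       integer or NA
#   label      "relevant" | "irrelevant"  (the oracle label, simulation mode)
#   key_paper  logical; key papers must carry label "relevant"
# plus attributes "validated" (logical) and "validation_report" (character).

#' Construct a screening corpus
#'
#' Low-level constructor checking the corpus invariants: unique record ids,
#' labels in `{relevant, irrelevant}`, and every key paper labeled relevant.
#'
#' @param records data.frame with columns `record_id`, `title`, `abstract`,
#'   `year`, `label`, `key_paper`.
#' @return a `safe_corpus` object.
#' @export
safe_corpus <- function(records) {
  need <- c("record_id", "title", "abstract", "year", "label", "key_paper")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("corpus is missing columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$record_id <- as.character(records$record_id)
  records$title <- as.character(records$title)
  records$abstract <- as.character(records$abstract)
  records$year <- suppressWarnings(as.integer(records$year))
  records$key_paper <- as.logical(records$key_paper)
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup)) stop("duplicate record_id: ", paste(unique(dup), collapse = ", "))
  bad <- !records$label %in% c("relevant", "irrelevant")
  if (any(bad)) {
    stop("unknown label value(s) in row(s) ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(records$label[bad]), collapse = ", "))
  }
  kp_bad <- records$key_paper & records$label != "relevant"
  if (any(kp_bad)) {
    stop("key paper(s) not labeled relevant: ",
         paste(records$record_id[kp_bad], collapse = ", "))
  }
  rownames(records) <- NULL
  structure(records,
            validated = FALSE,
            validation_report = character(),
            class = c("safe_corpus", "data.frame"))
}

#' Total number of records in a corpus
#' @param corpus a `safe_corpus`.
#' @return integer count `T`.
#' @export
corpus_size <- function(corpus) nrow(corpus)

# map raw label values (1/0, relevant/irrelevant, included/excluded,
# case-insensitive) onto the canonical pair; unknown values are an error
# naming the offending rows -- silent coercion hides label bugs.
canonical_labels <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(lx))
  out[lx %in% c("1", "relevant", "included", "true")] <- "relevant"
  out[lx %in% c("0", "irrelevant", "excluded", "false")] <- "irrelevant"
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("unknown label value(s) in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Read a bibliographic corpus
#'
#' Reads a labeled screening corpus from CSV, or from a RIS file paired with
#' a separate label CSV.  The CSV format has a header and columns
#' `record_id, title, abstract, year, <label_column>` and optionally
#' `key_paper`.  Label values may be any of `1/0`,
#' `relevant/irrelevant`, `included/excluded` (case-insensitive); anything
#' else is an error naming the row.  Record order follows file order.
#'
#' @param path path to the corpus file.
#' @param format `"csv"` or `"ris"`.
#' @param label_column name of the label column (CSV), default `"label"`.
#' @param labels_path for `format = "ris"`: path to a CSV with columns
#'   `record_id` and `<label_column>` keyed by the RIS `ID` tag.
#' @param key_paper_ids optional character vector of record ids to flag as
#'   key papers (in addition to any in-file `key_paper` column).
#' @return a `safe_corpus`.
#' @export
read_corpus <- function(path, format = c("csv", "ris"), label_column = "label",
                        labels_path = NULL, key_paper_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    if (!label_column %in% names(raw))
      stop("label column '", label_column, "' not found in ", path)
    for (col in c("record_id", "title", "abstract"))
      if (!col %in% names(raw)) stop("missing required column '", col, "' in ", path)
    df <- data.frame(
      record_id = raw$record_id,
      title = raw$title,
      abstract = raw$abstract,
      year = if ("year" %in% names(raw)) raw$year else NA_integer_,
      label = canonical_labels(raw[[label_column]]),
      key_paper = if ("key_paper" %in% names(raw))
        tolower(trimws(raw$key_paper)) %in% c("1", "true", "yes") else FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    refs <- read_ris(path)
    if (is.null(labels_path)) stop("format = 'ris' requires labels_path")
    if (!file.exists(labels_path)) stop("file not found: ", labels_path)
    lab <- utils::read.csv(labels_path, colClasses = "character")
    if (!all(c("record_id", label_column) %in% names(lab)))
      stop("labels file must have columns record_id and ", label_column)
    idx <- match(refs$record_id, lab$record_id)
    if (anyNA(idx)) {
      stop("no label supplied for record(s): ",
           paste(refs$record_id[is.na(idx)], collapse = ", "))
    }
    df <- refs
    df$label <- canonical_labels(lab[[label_column]][idx])
    df$key_paper <- FALSE
  }
  if (!is.null(key_paper_ids)) {
    absent <- setdiff(key_paper_ids, df$record_id)
    if (length(absent))
      stop("key paper id(s) not present in corpus: ", paste(absent, collapse = ", "))
    df$key_paper <- df$key_paper | df$record_id %in% key_paper_ids
  }
  safe_corpus(df)
}

# Minimal RIS reader for the tags used in screening exports:
# TY (type, starts a reference), TI/T1 (title), AB/N2 (abstract),
# PY/Y1 (year), ID (record id), ER (end of reference).
read_ris <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    data.frame(
      record_id = cur$id %||% paste0("ris", length(recs) + 1L),
      title = cur$ti %||% "",
      abstract = cur$ab %||% "",
      year = suppressWarnings(as.integer(sub("^([0-9]{4}).*", "\\1", cur$py %||% ""))),
      stringsAsFactors = FALSE
    )
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Z][A-Z0-9])  - ?(.*)$", ln))[[1]]
    if (length(m) == 0) next
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "TY") {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
      cur <- list()
    } else if (is.null(cur)) {
      next
    } else if (tag %in% c("TI", "T1")) {
      cur$ti <- val
    } else if (tag %in% c("AB", "N2")) {
      cur$ab <- val
    } else if (tag %in% c("PY", "Y1")) {
      cur$py <- val
    } else if (tag == "ID") {
      cur$id <- val
    } else if (tag == "ER") {
      recs[[length(recs) + 1L]] <- flush(cur)
      cur <- NULL
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
  if (!length(recs)) stop("no references found in RIS file: ", path)
  do.call(rbind, recs)
}

#' Write a corpus to CSV
#'
#' @param corpus a `safe_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  df <- as.data.frame(corpus)
  df$key_paper <- as.integer(df$key_paper)
  df$label <- as.integer(df$label == "relevant")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a screening corpus
#'
#' Input-quality checks in the garbage-in/garbage-out spirit of screening
#' practice: flags records with neither title nor abstract, exact duplicate
#' (normalized title, abstract) pairs, and missing years.  Warnings never
#' drop records; deduplication (optional) keeps the first occurrence.
#' Simulation requires at least one relevant oracle label (the procedure is
#' undefined with zero relevant records).
#'
#' @param corpus a `safe_corpus`.
#' @param dedupe drop later members of duplicate text pairs? Default `FALSE`.
#' @return the (possibly deduplicated) corpus, with attribute
#'   `validation_report` (character vector of warnings) and
#'   `validated = TRUE`.
#' @export
validate_corpus <- function(corpus, dedupe = FALSE) {
  stopifnot(inherits(corpus, "safe_corpus"))
  if (nrow(corpus) == 0L) stop("corpus has zero records")
  if (!any(corpus$label == "relevant"))
    stop("corpus has zero relevant oracle labels; screening simulation is undefined")
  report <- character()
  key <- paste(normalize_text(corpus$title), normalize_text(corpus$abstract), sep = "\x1f")
  dup <- duplicated(key)
  if (any(dup)) {
    report <- c(report, sprintf(
      "%d duplicate (title, abstract) pair(s): %s", sum(dup),
      paste(corpus$record_id[dup], collapse = ", ")))
  }
  empty <- !nzchar(normalize_text(corpus$title)) & !nzchar(normalize_text(corpus$abstract))
  if (any(empty)) {
    report <- c(report, sprintf(
      "%d record(s) with empty title and abstract: %s", sum(empty),
      paste(corpus$record_id[empty], collapse = ", ")))
  }
  empty_ab <- !nzchar(normalize_text(corpus$abstract)) & !empty
  if (any(empty_ab)) {
    report <- c(report, sprintf(
      "%d record(s) with missing abstract (ranked on title alone): %s",
      sum(empty_ab), paste(corpus$record_id[empty_ab], collapse = ", ")))
  }
  if (anyNA(corpus$year)) {
    report <- c(report, sprintf(
      "%d record(s) with missing year: %s", sum(is.na(corpus$year)),
      paste(corpus$record_id[is.na(corpus$year)], collapse = ", ")))
  }
  out <- corpus
  if (dedupe && any(dup)) {
    out <- corpus[!dup, , drop = FALSE]
    rownames(out) <- NULL
    out <- safe_corpus(out)
  }
  attr(out, "validation_report") <- report
  attr(out, "validated") <- TRUE
  out
}

#' @export
print.safe_corpus <- function(x, ...) {
  cat(sprintf("<safe_corpus> %d records (%d relevant, %d key papers)%s\n",
              nrow(x), sum(x$label == "relevant"), sum(x$key_paper),
              if (isTRUE(attr(x, "validated"))) ", validated" else ""))
  rep <- attr(x, "validation_report")
  if (length(rep)) cat(paste0("  warning: ", rep, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a screening log to CSV
#'
#' One row per screening decision: step index, record id, phase (1-4), the
#' rank at which the record was presented, the assigned label, and the
#' cumulative number of relevant records found.  Re-reading the file
#' reconstructs the recall curve exactly.
#'
#' @param state a `screening_state` (see [run_safe()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screening_log <- function(state, path) {
  log <- screening_log(state)
  if (nrow(log) == 0L) stop("screening state is empty")
  log$cum_relevant <- cumsum(log$label == "relevant")
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Read a screening log written by [write_screening_log()]
#'
#' @param path path to the log CSV.
#' @return a data.frame with columns `step`, `record_id`, `phase`,
#'   `rank_presented`, `label`, `cum_relevant`.
#' @export
read_screening_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  log <- utils::read.csv(path, colClasses = c(record_id = "character"))
  need <- c("step", "record_id", "phase", "rank_presented", "label")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("screening log is missing columns: ", paste(miss, collapse = ", "))
  log$cum_relevant <- cumsum(log$label == "relevant")
  log
}
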