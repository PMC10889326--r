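#' Merge all observers' responses for a project
#'
#' One row per stored response, joined with the master-side image attributes
#' (original filename, data group) and session attributes (observer label
#' and group). Rows from sessions that never reached the end are included
#' and flagged `session_complete = FALSE`, so the master can see work in
#' progress; summaries exclude them by default.
#'
#' @param store a `bs_store`.
#' @param project_id project identifier.
#' @return data frame with columns `session_id`, `observer_label`,
#'   `observer_group`, `session_complete`, `image_id`, `original_name`,
#'   `data_group`, `question_id`, `prompt`, `value`, `value_num`,
#'   `measurements`, `submitted_at`.
#' @export
merge_responses <- function(store, project_id) {
  get_project(store, project_id)  # not-found check
  DBI::dbGetQuery(store$con,
    "SELECT r.session_id, s.observer_label, s.observer_group,
            s.completed AS session_complete,
            r.image_id, i.original_name, i.data_group,
            r.question_id, q.prompt, r.value, r.value_num, r.measurements,
            r.submitted_at
     FROM responses r
     JOIN sessions  s ON r.session_id  = s.session_id
     JOIN images    i ON r.image_id    = i.image_id
     JOIN questions q ON r.question_id = q.question_id
     WHERE s.project_id = ?
     ORDER BY r.session_id, r.submitted_at, q.pos",
    params = list(project_id)) |> transform_complete()
}

transform_complete <- function(df) {
  df$session_complete <- as.logical(df$session_complete)
  df
}

# The grouping axes a summary can break results down by, mapped to the
# merged-table columns that realize them.
AXIS_COLUMNS <- c(observer = "observer_label", data_group = "data_group",
                  observer_group = "observer_group", image = "image_id")

# Core summary on an already-merged response table; shared by the live path
# and the CSV re-import path so both provably aggregate identically.
summarize_table <- function(tab, group_by = character()) {
  bs_check(all(group_by %in% names(AXIS_COLUMNS)), "validation",
           sprintf("grouping axes must be among: %s",
                   paste(names(AXIS_COLUMNS), collapse = ", ")))
  if (!nrow(tab)) {
    out <- data.frame(matrix(character(0), 0, length(group_by)))
    names(out) <- group_by
    out$n <- integer(0); out$mean <- numeric(0); out$sd <- numeric(0)
    return(out)
  }
  cols <- AXIS_COLUMNS[group_by]
  key <- if (length(cols)) {
    do.call(paste, c(lapply(cols, function(cc) ifelse(is.na(tab[[cc]]), "", tab[[cc]])),
                     sep = "\r"))
  } else rep("", nrow(tab))
  pieces <- split(seq_len(nrow(tab)), key)
  rows <- lapply(pieces, function(idx) {
    sub <- tab[idx, , drop = FALSE]
    v <- sub$value_num
    lab <- lapply(cols, function(cc) sub[[cc]][1])
    names(lab) <- group_by
    c(lab, list(n = length(v), mean = mean(v),
                sd = if (length(v) >= 2L) stats::sd(v) else NA_real_))
  })
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  if (length(group_by)) {
    out <- out[do.call(order, c(as.list(out[group_by]), list(method = "radix"))), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summarize responses for one question
#'
#' Computes n, mean, and sample standard deviation (n-1 denominator; absent
#' when n < 2) of the numeric encoding of a question's answers, optionally
#' broken down by any combination of grouping axes: `observer`,
#' `data_group`, `observer_group`, `image`. `group_by = character()` yields
#' the single combined row over all observers and images. Combinations with
#' no responses are omitted.
#'
#' Numeric questions summarize their values directly; single-choice
#' questions use the numeric value declared per choice label at project
#' creation. A single-choice question whose selected labels carry no numeric
#' encoding cannot be averaged and signals `bs_tally_only_error` — use
#' [tally_responses()] for it.
#'
#' @param store a `bs_store`.
#' @param project_id project identifier.
#' @param question_id the question to summarize.
#' @param group_by character vector of axes (possibly empty).
#' @param include_incomplete include responses from unfinished sessions
#'   (default `FALSE`: partial randomized subsets would bias group means).
#' @return data frame of aggregate rows: one column per axis, plus `n`,
#'   `mean`, `sd`.
#' @export
summarize_responses <- function(store, project_id, question_id,
                                group_by = character(), include_incomplete = FALSE) {
  tab <- merge_responses(store, project_id)
  tab <- tab[tab$question_id == question_id, , drop = FALSE]
  if (!include_incomplete) tab <- tab[tab$session_complete, , drop = FALSE]
  if (nrow(tab) && anyNA(tab$value_num)) {
    bs_abort("tally_only",
             "question has answers without a numeric encoding; use tally_responses()")
  }
  summarize_table(tab, group_by)
}

#' Per-image answer tallies
#'
#' Counts, for every image, how many observers gave each answer. For
#' single-choice questions the counts are over choice labels; for numeric
#' questions they are over distinct numeric values (documented convenience).
#' Zero-count labels are omitted.
#'
#' @inheritParams summarize_responses
#' @return data frame with `image_id`, `original_name`, `value`, `count`.
#' @export
tally_responses <- function(store, project_id, question_id,
                            include_incomplete = FALSE) {
  tab <- merge_responses(store, project_id)
  tab <- tab[tab$question_id == question_id, , drop = FALSE]
  if (!include_incomplete) tab <- tab[tab$session_complete, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(image_id = character(0), original_name = character(0),
                      value = character(0), count = integer(0)))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(tab))),
                          by = list(image_id = tab$image_id,
                                    original_name = tab$original_name,
                                    value = tab$value),
                          FUN = sum)
  agg <- agg[order(agg$image_id, agg$value, method = "radix"), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Flatten one response's measurement JSON into the export columns.
flatten_measurements <- function(mjson) {
  ms <- measurements_from_json(mjson)
  if (!length(ms)) {
    return(list(n_measurements = 0L, measurement_summary = "", measurements_json = "[]"))
  }
  summ <- vapply(ms, function(m) {
    v <- if (!is.null(m$calibrated_value))
      sprintf("%s=%s %s", m$kind, format(m$calibrated_value, digits = 12), m$calibrated_units)
    else
      sprintf("%s=%s %s", m$kind, paste(format(m$raw_value, digits = 12), collapse = "/"), m$units)
    v
  }, character(1))
  list(n_measurements = length(ms),
       measurement_summary = paste(summ, collapse = "; "),
       measurements_json = mjson)
}

#' Export a project's responses as CSV
#'
#' RFC 4180 CSV (UTF-8, header row, quoted fields where needed, decimal
#' point never comma): one row per response with the master-side context and
#' flattened measurement columns. The numeric encoding is written with 15
#' significant digits so re-importing and re-summarizing reproduces the
#' in-memory aggregates.
#'
#' @param store a `bs_store`.
#' @param project_id project identifier.
#' @param path optional file path to write to.
#' @return invisibly when `path` given; otherwise a single string with the
#'   CSV content.
#' @export
export_csv <- function(store, project_id, path = NULL) {
  tab <- merge_responses(store, project_id)
  flat <- lapply(tab$measurements, flatten_measurements)
  out <- data.frame(
    image_original_name = tab$original_name,
    image_id = tab$image_id,
    data_group = tab$data_group,
    observer_label = tab$observer_label,
    observer_group = tab$observer_group,
    session_id = tab$session_id,
    session_complete = tab$session_complete,
    question = tab$prompt,
    question_id = tab$question_id,
    answer = tab$value,
    answer_numeric = vapply(tab$value_num, function(v)
      if (is.na(v)) "" else format(v, digits = 15), character(1)),
    n_measurements = vapply(flat, `[[`, integer(1), "n_measurements"),
    measurement_summary = vapply(flat, `[[`, character(1), "measurement_summary"),
    measurements_json = vapply(flat, `[[`, character(1), "measurements_json"),
    submitted_at = tab$submitted_at,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  txt <- format_rfc4180(out)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(path))
  }
  txt
}

# RFC 4180 serialization: fields are quoted only when they contain a comma,
# a quote or a line break; embedded quotes double.
format_rfc4180 <- function(df) {
  esc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl('[",\n\r]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  cells <- vapply(df, esc, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(esc(names(df)), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Re-import an exported CSV into a merged-response table
#'
#' Parses a CSV produced by [export_csv()] back into the column layout of
#' [merge_responses()], for downstream re-aggregation (round-trip checks,
#' offline analysis).
#'
#' @param csv a CSV string or a file path.
#' @return data frame compatible with [summarize_table()]-based summaries.
#' @export
import_csv <- function(csv) {
  src <- if (file.exists(csv)) csv else textConnection(csv)
  tab <- utils::read.csv(src, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  data.frame(
    session_id = tab$session_id,
    observer_label = tab$observer_label,
    observer_group = tab$observer_group,
    session_complete = tab$session_complete %in% c("TRUE", "true", "1"),
    image_id = tab$image_id,
    original_name = tab$image_original_name,
    data_group = tab$data_group,
    question_id = tab$question_id,
    prompt = tab$question,
    value = tab$answer,
    value_num = suppressWarnings(as.numeric(tab$answer_numeric)),
    measurements = tab$measurements_json,
    submitted_at = tab$submitted_at,
    stringsAsFactors = FALSE
  )
}
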