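#' Define a question
#'
#' A question is answered by every observer for every image, either as a
#' single choice from a fixed list of labels or as a free numeric value.
#' Choice labels may carry a numeric encoding (e.g. `"Grade 0.5"` -> 0.5) so
#' ordinal grading scales can be averaged; labels without one are tally-only.
#'
#' @param prompt the text shown to observers.
#' @param kind `"single_choice"` or `"numeric"`.
#' @param choices character vector of >= 2 distinct labels (single_choice only).
#' @param values optional numeric vector parallel to `choices` giving each
#'   label's numeric encoding; `NA` entries leave a label tally-only.
#' @param units optional unit string (numeric questions only).
#' @return a `bs_question` object.
#' @export
#' @examples
#' question("OARSI grade", "single_choice",
#'          choices = c("Grade 0", "Grade 1"), values = c(0, 1))
#' question("medial angle", "numeric", units = "deg")
question <- function(prompt, kind = c("single_choice", "numeric"),
                     choices = NULL, values = NULL, units = NULL) {
  kind <- match.arg(kind)
  bs_check(is_string(prompt) && nzchar(prompt), "validation", "question prompt must be non-empty text")
  if (kind == "single_choice") {
    bs_check(is.character(choices) && length(choices) >= 2L,
             "validation", "single-choice question needs at least 2 choices")
    bs_check(!anyDuplicated(choices), "validation",
             "duplicate choice labels within one question")
    if (!is.null(values)) {
      bs_check(is.numeric(values) && length(values) == length(choices),
               "validation", "choice values must be numeric and parallel to choices")
    } else {
      values <- rep(NA_real_, length(choices))
    }
    units <- NULL
  } else {
    bs_check(is.null(choices), "validation", "numeric question takes no choices")
    values <- NULL
    if (!is.null(units)) bs_check(is_string(units), "validation", "units must be a string")
  }
  structure(list(question_id = NULL, prompt = prompt, kind = kind,
                 choices = choices, values = values, units = units),
            class = "bs_question")
}

#' Create a project
#'
#' A project bundles a name, an ordered list of questions, optional data
#' groups (experimental strata of images, hidden from observers) and optional
#' observer groups (experience strata selectable at session start). A fresh
#' non-guessable share token is generated; sharing starts disabled.
#'
#' @param store a `bs_store`.
#' @param name non-empty project name.
#' @param questions list of [question()] objects (at least one).
#' @param data_groups,observer_groups character vectors of group labels
#'   (possibly empty).
#' @return the persisted project, as returned by [get_project()].
#' @export
create_project <- function(store, name, questions,
                           data_groups = character(), observer_groups = character()) {
  bs_check(is_string(name) && nzchar(name), "validation", "project name must be non-empty")
  if (inherits(questions, "bs_question")) questions <- list(questions)
  bs_check(is.list(questions) && length(questions) >= 1L &&
             all(vapply(questions, inherits, logical(1), "bs_question")),
           "validation", "a project needs at least one question")
  bs_check(is.character(data_groups) && !anyDuplicated(data_groups),
           "validation", "data_groups must be distinct labels")
  bs_check(is.character(observer_groups) && !anyDuplicated(observer_groups),
           "validation", "observer_groups must be distinct labels")

  project_id <- new_id()
  token <- new_token()
  DBI::dbWithTransaction(store$con, {
    DBI::dbExecute(store$con,
      "INSERT INTO projects (project_id, name, share_token, share_enabled,
         data_groups, observer_groups, created_at) VALUES (?,?,?,0,?,?,?)",
      params = list(project_id, name, token,
                    jsonlite::toJSON(data_groups), jsonlite::toJSON(observer_groups),
                    utc_now()))
    for (i in seq_along(questions)) {
      q <- questions[[i]]
      qid <- new_id()
      ch <- if (q$kind == "single_choice") {
        as.character(jsonlite::toJSON(
          data.frame(label = q$choices, value = q$values), dataframe = "rows", na = "null"))
      } else NA_character_
      DBI::dbExecute(store$con,
        "INSERT INTO questions (question_id, project_id, pos, prompt, kind, units, choices)
         VALUES (?,?,?,?,?,?,?)",
        params = list(qid, project_id, i, q$prompt, q$kind, q$units %||% NA_character_, ch))
    }
  })
  get_project(store, project_id)
}

#' Fetch a project with its questions and image records
#'
#' @param store a `bs_store`.
#' @param project_id project identifier.
#' @return a `bs_project` list: `project_id`, `name`, `share_token`,
#'   `share_enabled`, `data_groups`, `observer_groups`, `questions` (list),
#'   `images` (data frame of master-visible image records).
#' @export
get_project <- function(store, project_id) {
  p <- DBI::dbGetQuery(store$con, "SELECT * FROM projects WHERE project_id = ?",
                       params = list(project_id))
  bs_check(nrow(p) == 1L, "not_found", sprintf("no project '%s'", project_id))
  qs <- DBI::dbGetQuery(store$con,
    "SELECT * FROM questions WHERE project_id = ? ORDER BY pos", params = list(project_id))
  questions <- lapply(seq_len(nrow(qs)), function(i) {
    row <- qs[i, ]
    ch <- NULL; vals <- NULL
    if (!is.na(row$choices)) {
      tab <- jsonlite::fromJSON(row$choices)
      ch <- tab$label
      vals <- as.numeric(tab$value)
    }
    structure(list(question_id = row$question_id, prompt = row$prompt, kind = row$kind,
                   choices = ch, values = vals,
                   units = if (is.na(row$units)) NULL else row$units),
              class = "bs_question")
  })
  imgs <- DBI::dbGetQuery(store$con,
    "SELECT image_id, original_name, media_kind, data_group, n_frames,
            width_px, height_px, spacing_row_mm, spacing_col_mm, spacing_source
     FROM images WHERE project_id = ? ORDER BY pos", params = list(project_id))
  structure(list(
    project_id = p$project_id, name = p$name,
    share_token = p$share_token, share_enabled = as.logical(p$share_enabled),
    share_expires = if (is.na(p$share_expires)) NULL else p$share_expires,
    data_groups = as.character(jsonlite::fromJSON(p$data_groups)),
    observer_groups = as.character(jsonlite::fromJSON(p$observer_groups)),
    questions = questions, images = imgs, created_at = p$created_at
  ), class = "bs_project")
}

#' @export
print.bs_project <- function(x, ...) {
  cat("<bs_project> ", x$name, "\n",
      "  id: ", x$project_id, "\n",
      "  questions: ", length(x$questions),
      "  images: ", nrow(x$images),
      "  data groups: ", if (length(x$data_groups)) paste(x$data_groups, collapse = ", ") else "(none)",
      "\n  sharing: ", if (x$share_enabled) "enabled" else "disabled", "\n", sep = "")
  invisible(x)
}

#' Enable or disable a project's share link
#'
#' The share token itself is constant for the project's lifetime; the toggle
#' (plus an optional expiry timestamp) implements temporary validity.
#'
#' @inheritParams get_project
#' @param enabled logical flag.
#' @param expires optional ISO-8601 UTC timestamp after which the token stops
#'   resolving even while enabled; `NULL` (default) means no expiry.
#' @return the updated project.
#' @export
set_share_enabled <- function(store, project_id, enabled, expires = NULL) {
  bs_check(is_flag(enabled), "validation", "enabled must be TRUE or FALSE")
  n <- DBI::dbExecute(store$con,
    "UPDATE projects SET share_enabled = ?, share_expires = ? WHERE project_id = ?",
    params = list(as.integer(enabled), expires %||% NA_character_, project_id))
  bs_check(n == 1L, "not_found", sprintf("no project '%s'", project_id))
  get_project(store, project_id)
}

#' Resolve a share token to a project id
#'
#' Unknown tokens and disabled-but-known tokens fail with distinguishable
#' condition classes (`bs_not_found_error` vs `bs_access_denied_error`) so the
#' master's logs can tell them apart; the HTTP layer presents both identically
#' to observers.
#'
#' @param store a `bs_store`.
#' @param token share token string.
#' @return the project id.
#' @export
resolve_token <- function(store, token) {
  bs_check(is_string(token), "validation", "token must be a string")
  row <- DBI::dbGetQuery(store$con,
    "SELECT project_id, share_enabled, share_expires FROM projects WHERE share_token = ?",
    params = list(token))
  bs_check(nrow(row) == 1L, "not_found", "unknown share token")
  enabled <- as.logical(row$share_enabled)
  if (enabled && !is.na(row$share_expires)) {
    enabled <- utc_now() < row$share_expires
  }
  bs_check(enabled, "access_denied", "share link is disabled")
  row$project_id
}

#' Export / import a project as a JSON document
#'
#' A versioned, self-contained backup of one project: definition, image
#' records with base64 payloads referenced by content hash, and all sessions
#' and responses. Importing into another store reproduces the project
#' field-for-field (ids included).
#'
#' @inheritParams get_project
#' @return `export_project_json()`: a JSON string. `import_project_json()`:
#'   the imported project's id.
#' @export
export_project_json <- function(store, project_id) {
  p <- get_project(store, project_id)  # validates existence
  grab <- function(sql) DBI::dbGetQuery(store$con, sql, params = list(project_id))
  proj <- grab("SELECT * FROM projects WHERE project_id = ?")
  qs <- grab("SELECT * FROM questions WHERE project_id = ? ORDER BY pos")
  imgs <- grab("SELECT * FROM images WHERE project_id = ? ORDER BY pos")
  frames <- DBI::dbGetQuery(store$con,
    "SELECT f.* FROM frames f JOIN images i ON f.image_id = i.image_id
     WHERE i.project_id = ? ORDER BY f.image_id, f.frame_index", params = list(project_id))
  sess <- grab("SELECT * FROM sessions WHERE project_id = ?")
  resp <- DBI::dbGetQuery(store$con,
    "SELECT r.* FROM responses r JOIN sessions s ON r.session_id = s.session_id
     WHERE s.project_id = ?", params = list(project_id))
  b64 <- function(col) vapply(col, function(b) openssl::base64_encode(b), character(1))
  sha <- function(col) vapply(col, function(b) as.character(openssl::sha256(b)), character(1))
  imgs$content_sha256 <- sha(imgs$original_blob)
  imgs$original_blob <- b64(imgs$original_blob)
  if (nrow(frames)) {
    frames$anon_blob <- b64(frames$anon_blob)
    frames$render_png <- ifelse(
      vapply(frames$render_png, is.null, logical(1)), NA_character_,
      vapply(frames$render_png, function(b) if (is.null(b)) NA_character_ else openssl::base64_encode(b), character(1)))
  }
  jsonlite::toJSON(list(format = "blindscore-project", format_version = 1L,
                        project = proj, questions = qs, images = imgs,
                        frames = frames, sessions = sess, responses = resp),
                   dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
}

#' @rdname export_project_json
#' @param json a JSON string produced by `export_project_json()`.
#' @export
import_project_json <- function(store, json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  bs_check(identical(doc$format, "blindscore-project") && doc$format_version == 1L,
           "validation", "not a blindscore project document")
  con <- store$con
  ins <- function(table, df, cols) {
    if (is.null(df) || !NROW(df)) return(invisible(NULL))
    df <- df[, cols, drop = FALSE]
    ph <- paste(rep("?", length(cols)), collapse = ",")
    sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", table, paste(cols, collapse = ","), ph)
    for (i in seq_len(nrow(df))) {
      DBI::dbExecute(con, sql, params = unname(as.list(df[i, ])))
    }
  }
  DBI::dbWithTransaction(con, {
    ins("projects", doc$project, c("project_id","name","share_token","share_enabled",
                                   "share_expires","data_groups","observer_groups","created_at"))
    ins("questions", doc$questions, c("question_id","project_id","pos","prompt","kind","units","choices"))
    imgs <- doc$images
    if (NROW(imgs)) {
      for (i in seq_len(nrow(imgs))) {
        blob <- openssl::base64_decode(imgs$original_blob[i])
        bs_check(as.character(openssl::sha256(blob)) == imgs$content_sha256[i],
                 "validation", "image payload hash mismatch on import")
        DBI::dbExecute(con,
          "INSERT INTO images (image_id, project_id, pos, original_name, media_kind,
             data_group, n_frames, width_px, height_px, spacing_row_mm, spacing_col_mm,
             spacing_source, original_blob) VALUES (?,?,?,?,?,?,?,?,?,?,?,?,?)",
          params = c(unname(as.list(imgs[i, c("image_id","project_id","pos","original_name",
                                              "media_kind","data_group","n_frames","width_px",
                                              "height_px","spacing_row_mm","spacing_col_mm",
                                              "spacing_source")])),
                     list(list(blob))))
      }
    }
    fr <- doc$frames
    if (NROW(fr)) {
      for (i in seq_len(nrow(fr))) {
        DBI::dbExecute(con,
          "INSERT INTO frames (image_id, frame_index, media_kind, anon_blob, render_png)
           VALUES (?,?,?,?,?)",
          params = list(fr$image_id[i], fr$frame_index[i], fr$media_kind[i],
                        list(openssl::base64_decode(fr$anon_blob[i])),
                        if (is.na(fr$render_png[i])) list(NULL)
                        else list(openssl::base64_decode(fr$render_png[i]))))
      }
    }
    ins("sessions", doc$sessions, c("session_id","project_id","observer_label","observer_group",
                                    "ordering","cursor","completed","rng_seed","started_at"))
    ins("responses", doc$responses, c("session_id","image_id","question_id","value",
                                      "value_num","measurements","submitted_at"))
  })
  doc$project$project_id
}
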