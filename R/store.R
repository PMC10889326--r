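SCHEMA_VERSION <- 1L

#' Open a study store
#'
#' A store is a single-file embedded SQLite database holding every project,
#' its questions, anonymized images (and their master-side originals),
#' observer sessions and responses. Opening a path that does not yet contain
#' a schema initializes one; the schema carries a version number so future
#' releases can migrate in place.
#'
#' @param path file path for the database, or `":memory:"` for a transient
#'   in-process store (useful in tests).
#' @return a `bs_store` handle.
#' @export
#' @examples
#' st <- store_open(":memory:")
#' store_close(st)
store_open <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  init_schema(con)
  structure(list(con = con, path = path), class = "bs_store")
}

#' @rdname store_open
#' @param store a `bs_store` handle.
#' @export
store_close <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.bs_store <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM projects")$n
  cat("<bs_store> ", x$path, " (", n, " project", if (n != 1) "s", ")\n", sep = "")
  invisible(x)
}

init_schema <- function(con) {
  have <- DBI::dbListTables(con)
  if ("meta" %in% have) {
    v <- DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key='schema_version'")$value
    bs_check(length(v) == 1L && as.integer(v) <= SCHEMA_VERSION,
             "validation", "store schema is newer than this package understands")
    return(invisible(NULL))
  }
  stmts <- c(
    "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT NOT NULL)",
    "CREATE TABLE projects (
       project_id      TEXT PRIMARY KEY,
       name            TEXT NOT NULL,
       share_token     TEXT NOT NULL UNIQUE,
       share_enabled   INTEGER NOT NULL DEFAULT 0,
       share_expires   TEXT,
       data_groups     TEXT NOT NULL,
       observer_groups TEXT NOT NULL,
       created_at      TEXT NOT NULL)",
    "CREATE TABLE questions (
       question_id TEXT PRIMARY KEY,
       project_id  TEXT NOT NULL REFERENCES projects(project_id),
       pos         INTEGER NOT NULL,
       prompt      TEXT NOT NULL,
       kind        TEXT NOT NULL CHECK (kind IN ('single_choice','numeric')),
       units       TEXT,
       choices     TEXT)",
    "CREATE TABLE images (
       image_id        TEXT PRIMARY KEY,
       project_id      TEXT NOT NULL REFERENCES projects(project_id),
       pos             INTEGER NOT NULL,
       original_name   TEXT NOT NULL,
       media_kind      TEXT NOT NULL,
       data_group      TEXT,
       n_frames        INTEGER NOT NULL,
       width_px        INTEGER NOT NULL,
       height_px       INTEGER NOT NULL,
       spacing_row_mm  REAL,
       spacing_col_mm  REAL,
       spacing_source  TEXT,
       original_blob   BLOB NOT NULL)",
    "CREATE TABLE frames (
       image_id    TEXT NOT NULL REFERENCES images(image_id),
       frame_index INTEGER NOT NULL,
       media_kind  TEXT NOT NULL,
       anon_blob   BLOB NOT NULL,
       render_png  BLOB,
       PRIMARY KEY (image_id, frame_index))",
    "CREATE TABLE sessions (
       session_id     TEXT PRIMARY KEY,
       project_id     TEXT NOT NULL REFERENCES projects(project_id),
       observer_label TEXT,
       observer_group TEXT,
       ordering       TEXT NOT NULL,
       cursor         INTEGER NOT NULL DEFAULT 0,
       completed      INTEGER NOT NULL DEFAULT 0,
       rng_seed       INTEGER NOT NULL,
       started_at     TEXT NOT NULL)",
    "CREATE TABLE responses (
       session_id   TEXT NOT NULL REFERENCES sessions(session_id),
       image_id     TEXT NOT NULL REFERENCES images(image_id),
       question_id  TEXT NOT NULL REFERENCES questions(question_id),
       value        TEXT NOT NULL,
       value_num    REAL,
       measurements TEXT NOT NULL DEFAULT '[]',
       submitted_at TEXT NOT NULL,
       PRIMARY KEY (session_id, image_id, question_id))",
    "CREATE TABLE events (
       event_id   INTEGER PRIMARY KEY AUTOINCREMENT,
       session_id TEXT,
       type       TEXT NOT NULL,
       detail     TEXT,
       at         TEXT NOT NULL)"
  )
  for (s in stmts) DBI::dbExecute(con, s)
  DBI::dbExecute(con, "INSERT INTO meta (key, value) VALUES ('schema_version', ?)",
                 params = list(as.character(SCHEMA_VERSION)))
  invisible(NULL)
}

log_event <- function(store, type, session_id = NA_character_, detail = NA_character_) {
  DBI::dbExecute(store$con,
    "INSERT INTO events (session_id, type, detail, at) VALUES (?,?,?,?)",
    params = list(session_id, type, detail, utc_now()))
  invisible(NULL)
}
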