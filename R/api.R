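# HTTP layer. The router is a pure function from a request record to a
# response record, so the whole wire contract — including blinding — is
# testable in-process; serve() mounts the same router on httpuv.
#
# Two principals exist. The project master authenticates every master route
# with a shared admin secret (header `x-admin-secret`). Observers never
# authenticate: possession of an enabled share token starts a session, and
# the session id is the only capability for the rest of the pass. Frame
# bytes are reachable only through per-session HMAC-signed URLs, so image
# locations can never be fetched directly or from another session.

#' Create an API application
#'
#' @param store an open `bs_store`.
#' @param admin_secret shared secret for master routes.
#' @return a `bs_api` app object for [api_handle()] / [serve()].
#' @export
api_app <- function(store, admin_secret) {
  bs_check(is_string(admin_secret) && nchar(admin_secret) >= 8L,
           "validation", "admin_secret must be at least 8 characters")
  structure(list(store = store, admin_secret = admin_secret,
                 signing_key = new_token(48L),
                 control = new.env(parent = emptyenv())),
            class = "bs_api")
}

api_json <- function(status, body) {
  list(status = status,
       headers = list("Content-Type" = "application/json; charset=utf-8"),
       body = as.character(jsonlite::toJSON(body, auto_unbox = TRUE, null = "null",
                                            digits = NA)))
}

# Observer-facing errors are deliberately generic: no filenames, group
# labels or metadata values ever appear in an error body.
api_error <- function(status, code, message) {
  api_json(status, list(error = list(code = code, message = message)))
}

status_of_condition <- function(e) {
  if (inherits(e, "bs_not_found_error")) c(404L, "not_found")
  else if (inherits(e, "bs_access_denied_error")) c(403L, "access_denied")
  else if (inherits(e, "bs_session_finished_error")) c(410L, "session_finished")
  else if (inherits(e, "bs_incomplete_submission_error")) c(422L, "incomplete_submission")
  else if (inherits(e, "bs_unsupported_media_error")) c(415L, "unsupported_media")
  else if (inherits(e, "bs_empty_project_error")) c(409L, "empty_project")
  else if (inherits(e, "bs_validation_error")) c(400L, "validation")
  else c(500L, "internal")
}

frame_sig <- function(app, session_id, image_id, frame_index) {
  msg <- paste(session_id, image_id, frame_index, sep = "|")
  as.vector(as.character(openssl::sha256(charToRaw(msg), key = charToRaw(app$signing_key))))
}

observer_item_body <- function(app, session_id) {
  item <- current_item(app$store, session_id)
  k <- item$image$n_frames
  urls <- vapply(seq_len(k), function(i) {
    sprintf("/api/sessions/%s/frames/%d?sig=%s", session_id, i,
            frame_sig(app, session_id, item$image$image_id, i))
  }, character(1))
  item$image$frame_urls <- urls
  item
}

#' Handle one API request
#'
#' @param app a `bs_api` from [api_app()].
#' @param method HTTP method.
#' @param path request path, e.g. `"/api/projects"`.
#' @param query named list of query parameters.
#' @param headers named list of request headers (lower-cased names).
#' @param body request body: a raw vector or JSON string.
#' @return response list: `status`, `headers`, `body` (string or raw).
#' @export
api_handle <- function(app, method, path, query = list(), headers = list(),
                       body = NULL) {
  tryCatch(
    api_dispatch(app, toupper(method), path, query, headers, body),
    bs_error = function(e) {
      sc <- status_of_condition(e)
      status <- as.integer(sc[1])
      # master routes may see the detail; observers get the generic code only
      msg <- if (identical(headers[["x-admin-secret"]], app$admin_secret))
        conditionMessage(e) else sc[2]
      api_error(status, sc[2], msg)
    },
    error = function(e) api_error(500L, "internal", "internal error")
  )
}

parse_body <- function(body) {
  if (is.null(body)) return(list())
  if (is.raw(body)) body <- rawToChar(body)
  if (!nzchar(body)) return(list())
  jsonlite::fromJSON(body, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

require_admin <- function(app, headers) {
  ok <- identical(headers[["x-admin-secret"]], app$admin_secret)
  bs_check(ok, "access_denied", "admin secret required")
}

api_dispatch <- function(app, method, path, query, headers, body) {
  store <- app$store
  seg <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]

  if (method == "GET" && path == "/api/health") {
    return(api_json(200L, list(status = "ok")))
  }
  if (method == "POST" && path == "/api/shutdown") {
    require_admin(app, headers)
    assign("stop", TRUE, envir = app$control)
    return(api_json(200L, list(stopping = TRUE)))
  }

  # ---- master routes -------------------------------------------------------
  if (length(seg) >= 2L && seg[1] == "api" && seg[2] == "projects") {
    require_admin(app, headers)
    if (method == "POST" && length(seg) == 2L) {
      b <- parse_body(body)
      qs <- lapply(b$questions, function(q) {
        question(q$prompt, q$kind,
                 choices = if (is.null(q$choices)) NULL else unlist(q$choices),
                 values = if (is.null(q$values)) NULL else unlist(q$values),
                 units = q$units)
      })
      p <- create_project(store, b$name, qs,
                          data_groups = as.character(unlist(b$data_groups %||% list())),
                          observer_groups = as.character(unlist(b$observer_groups %||% list())))
      return(api_json(201L, list(project_id = p$project_id,
                                 share_token = p$share_token,
                                 question_ids = vapply(p$questions, `[[`, character(1),
                                                       "question_id"))))
    }
    pid <- seg[3]
    if (method == "GET" && length(seg) == 3L) {
      p <- get_project(store, pid)
      return(api_json(200L, list(
        project_id = p$project_id, name = p$name, share_token = p$share_token,
        share_enabled = p$share_enabled, data_groups = p$data_groups,
        observer_groups = p$observer_groups, n_images = nrow(p$images))))
    }
    if (method == "POST" && length(seg) == 4L && seg[4] == "share") {
      b <- parse_body(body)
      p <- set_share_enabled(store, pid, isTRUE(b$enabled))
      return(api_json(200L, list(share_enabled = p$share_enabled,
                                 share_token = p$share_token)))
    }
    if (method == "POST" && length(seg) == 4L && seg[4] == "images") {
      b <- parse_body(body)
      payload <- openssl::base64_decode(b$content_base64)
      rec <- ingest_image(store, pid, payload, b$name %||% "upload",
                          data_group = b$data_group)
      return(api_json(201L, list(image_id = rec$image_id, media_kind = rec$media_kind,
                                 n_frames = rec$n_frames)))
    }
    if (method == "GET" && length(seg) == 4L && seg[4] == "results") {
      return(api_json(200L, master_results(store, pid,
                                           query$view %||% "combined",
                                           query$question)))
    }
    if (method == "GET" && length(seg) == 4L && seg[4] == "export.csv") {
      return(list(status = 200L,
                  headers = list("Content-Type" = "text/csv; charset=utf-8"),
                  body = export_csv(store, pid)))
    }
  }

  # ---- observer routes -----------------------------------------------------
  if (length(seg) == 4L && seg[1] == "api" && seg[2] == "observe" &&
      seg[4] == "sessions" && method == "POST") {
    b <- parse_body(body)
    s <- start_session(store, seg[3], observer_group = b$observer_group,
                       observer_label = b$observer_label)
    return(api_json(201L, list(session_id = s$session_id, n_images = s$n_images)))
  }
  if (length(seg) >= 3L && seg[1] == "api" && seg[2] == "sessions") {
    sid <- seg[3]
    if (method == "GET" && length(seg) == 4L && seg[4] == "current") {
      return(api_json(200L, observer_item_body(app, sid)))
    }
    if (method == "POST" && length(seg) == 4L && seg[4] == "submit") {
      b <- parse_body(body)
      ms <- if (is.null(b$measurements_json)) list()
            else measurements_from_json(b$measurements_json)
      pr <- submit_and_advance(app$store, sid, b$answers, ms)
      return(api_json(200L, pr))
    }
    if (method == "GET" && length(seg) == 4L && seg[4] == "progress") {
      return(api_json(200L, session_progress(app$store, sid)))
    }
    if (method == "GET" && length(seg) == 5L && seg[4] == "frames") {
      idx <- suppressWarnings(as.integer(seg[5]))
      bs_check(!is.na(idx) && idx >= 1L, "validation", "bad frame index")
      s <- get_session(app$store, sid)
      if (s$completed) bs_abort("session_finished", "session finished")
      image_id <- s$ordering[s$cursor + 1L]
      expect <- frame_sig(app, sid, image_id, idx)
      bs_check(identical(query$sig, expect), "access_denied", "invalid frame signature")
      row <- DBI::dbGetQuery(app$store$con,
        "SELECT render_png, anon_blob, media_kind FROM frames
         WHERE image_id = ? AND frame_index = ?", params = list(image_id, idx))
      bs_check(nrow(row) == 1L, "not_found", "no such frame")
      bytes <- row$render_png[[1]] %||% row$anon_blob[[1]]
      ctype <- if (!is.null(row$render_png[[1]])) "image/png" else "application/octet-stream"
      return(list(status = 200L, headers = list("Content-Type" = ctype), body = bytes))
    }
  }

  api_error(404L, "not_found", "no such route")
}

# Results document mirroring the master's views: combined, per_observer,
# per_group (data and observer groups), per_image (summary + tally).
master_results <- function(store, project_id, view, question_id = NULL) {
  p <- get_project(store, project_id)
  if (is.null(question_id)) question_id <- p$questions[[1]]$question_id
  summ_or_tally <- function(axes) {
    tryCatch(list(rows = summarize_responses(store, project_id, question_id, axes)),
             bs_tally_only_error = function(e) list(tally_only = TRUE))
  }
  res <- switch(view,
    combined = summ_or_tally(character()),
    per_observer = summ_or_tally("observer"),
    per_group = list(by_data_group = summ_or_tally("data_group")$rows,
                     by_observer_group = summ_or_tally("observer_group")$rows),
    per_image = list(summary = summ_or_tally("image")$rows,
                     tally = tally_responses(store, project_id, question_id)),
    bs_abort("validation", sprintf("unknown view '%s'", view)))
  list(project_id = project_id, question_id = question_id, view = view,
       results = res)
}

#' Serve the API over HTTP
#'
#' Mounts the router on httpuv and blocks until a `POST /api/shutdown`
#' (master-authenticated) arrives or the process is interrupted.
#'
#' @param db_path path to the store database file.
#' @param port TCP port.
#' @param admin_secret shared master secret.
#' @param host interface to bind (default loopback).
#' @return invisibly, after the server stops.
#' @export
serve <- function(db_path, port, admin_secret, host = "127.0.0.1") {
  store <- store_open(db_path)
  on.exit(store_close(store), add = TRUE)
  app <- api_app(store, admin_secret)
  handler <- function(req) {
    n <- as.integer(req$CONTENT_LENGTH %||% "0")
    body <- if (!is.na(n) && n > 0L) req$rook.input$read(n) else NULL
    q <- parse_query_string(req$QUERY_STRING %||% "")
    hdrs <- list()
    if (!is.null(req$HTTP_X_ADMIN_SECRET)) hdrs[["x-admin-secret"]] <- req$HTTP_X_ADMIN_SECRET
    resp <- api_handle(app, req$REQUEST_METHOD, req$PATH_INFO, q, hdrs, body)
    list(status = resp$status, headers = resp$headers, body = resp$body)
  }
  srv <- httpuv::startServer(host, port, list(call = handler))
  on.exit(httpuv::stopServer(srv), add = TRUE)
  while (!isTRUE(app$control$stop)) httpuv::service(250)
  httpuv::service(100)  # flush the shutdown response
  invisible(NULL)
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs)
  if (!nzchar(qs)) return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) utils::URLdecode(p[2] %||% ""))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}
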