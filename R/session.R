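# A session is one observer's single randomized pass over a project's
# images. The contract enforced here is the heart of the blinding design:
# (i) the presentation order is a fresh uniform permutation per session, so
# two observers — or two passes by the same observer — never share an order;
# (ii) navigation is forward-only: there is exactly one current item, no
# operation accepts an image selector, and the cursor never decreases; and
# (iii) everything served to the observer goes through the anonymized view.

# Fisher-Yates shuffle driven by R's RNG under a stored per-session seed, so
# an ordering can be re-derived for audit. sample() would serve, but an
# explicit loop keeps the permutation algorithm part of the tested surface.
fisher_yates <- function(n, seed) {
  with_seed(seed, {
    idx <- seq_len(n)
    if (n > 1L) for (i in n:2) {
      j <- 1L + as.integer(floor(stats::runif(1) * i))
      if (j > i) j <- i  # guard against runif returning exactly 1
      tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
    }
    idx
  })
}

#' Start an observer session
#'
#' Resolves a share token (so disabled links refuse here), validates the
#' chosen observer group, draws a fresh presentation order uniformly from all
#' permutations of the project's images, and persists the session with its
#' RNG seed. The session id doubles as the resumption handle: reloading a
#' browser mid-study continues at the same cursor with the same ordering.
#'
#' @param store a `bs_store`.
#' @param token the project's share token.
#' @param observer_group optional label; must be one of the project's
#'   observer groups when given.
#' @param observer_label optional free-text label for per-observer result
#'   views (repeated passes under one label stay separate sessions).
#' @param seed optional explicit RNG seed (for reproducible simulations);
#'   default draws a fresh seed from the CSPRNG.
#' @return a `bs_session` list (`session_id`, `project_id`, `n_images`, ...).
#' @export
start_session <- function(store, token, observer_group = NULL,
                          observer_label = NULL, seed = NULL) {
  project_id <- resolve_token(store, token)
  proj <- get_project(store, project_id)
  bs_check(nrow(proj$images) >= 1L, "empty_project",
           "project has no images to present")
  if (!is.null(observer_group)) {
    bs_check(observer_group %in% proj$observer_groups, "validation",
             sprintf("'%s' is not an observer group of this project", observer_group))
  }
  seed <- if (is.null(seed)) csprng_seed() else as.integer(seed)
  ordering <- proj$images$image_id[fisher_yates(nrow(proj$images), seed)]
  session_id <- new_id()
  DBI::dbExecute(store$con,
    "INSERT INTO sessions (session_id, project_id, observer_label, observer_group,
       ordering, cursor, completed, rng_seed, started_at) VALUES (?,?,?,?,?,0,0,?,?)",
    params = list(session_id, project_id, observer_label %||% NA_character_,
                  observer_group %||% NA_character_,
                  as.character(jsonlite::toJSON(ordering)), seed, utc_now()))
  log_event(store, "session_started", session_id)
  get_session(store, session_id)
}

#' @rdname start_session
#' @param session_id session identifier.
#' @export
get_session <- function(store, session_id) {
  s <- DBI::dbGetQuery(store$con, "SELECT * FROM sessions WHERE session_id = ?",
                       params = list(session_id))
  bs_check(nrow(s) == 1L, "not_found", sprintf("no session '%s'", session_id))
  structure(list(session_id = s$session_id, project_id = s$project_id,
                 observer_label = if (is.na(s$observer_label)) NULL else s$observer_label,
                 observer_group = if (is.na(s$observer_group)) NULL else s$observer_group,
                 ordering = as.character(jsonlite::fromJSON(s$ordering)),
                 cursor = s$cursor, completed = as.logical(s$completed),
                 rng_seed = s$rng_seed, n_images = length(jsonlite::fromJSON(s$ordering))),
            class = "bs_session")
}

#' @export
print.bs_session <- function(x, ...) {
  cat("<bs_session> ", x$session_id, "\n  progress: ", x$cursor, "/", x$n_images,
      if (x$completed) " (completed)", "\n", sep = "")
  invisible(x)
}

#' The observer's current item
#'
#' Returns the blinded payload for the item at the session cursor: the
#' anonymized image view, the project's questions, and progress. Calling it
#' repeatedly without submitting returns the same item — there is exactly one
#' open item at any time. A completed session signals `bs_session_finished`.
#'
#' @param store a `bs_store`.
#' @param session_id session identifier.
#' @return list with `image` (anonymized view), `questions`, `progress`.
#' @export
current_item <- function(store, session_id) {
  s <- get_session(store, session_id)
  if (s$completed) bs_abort("session_finished", "all images have been assessed")
  image_id <- s$ordering[s$cursor + 1L]
  proj <- get_project(store, s$project_id)
  qs <- lapply(proj$questions, function(q) {
    list(question_id = q$question_id, prompt = q$prompt, kind = q$kind,
         choices = q$choices, units = q$units)
  })
  log_event(store, "item_served", session_id, image_id)
  list(image = anonymized_view(store, image_id),
       questions = qs,
       progress = list(k = s$cursor, n = s$n_images))
}

# Numeric encoding of one answer against its question; NA when none applies.
encode_answer <- function(q, value) {
  if (q$kind == "numeric") {
    num <- suppressWarnings(as.numeric(value))
    bs_check(length(num) == 1L && is.finite(num), "validation",
             sprintf("answer to '%s' must be a finite number", q$prompt))
    list(value = as.character(num), value_num = num)
  } else {
    bs_check(is_string(value) && value %in% q$choices, "validation",
             sprintf("answer to '%s' must be one of its choices", q$prompt))
    v <- q$values[match(value, q$choices)]
    list(value = value, value_num = if (is.null(v) || is.na(v)) NA_real_ else v)
  }
}

#' Submit answers for the current item and advance
#'
#' Stores one response per question for the current image and moves the
#' cursor forward by exactly one, atomically: a submission that fails
#' validation (missing answer, wrong type) leaves cursor and responses
#' untouched. Once an item has been advanced past it can never be fetched or
#' resubmitted — the forward-only contract.
#'
#' @param store a `bs_store`.
#' @param session_id session identifier.
#' @param answers named list/vector mapping question_id to the answer value.
#' @param measurements optional list of `bs_measurement` annotations, stored
#'   with every response of this item.
#' @return progress list `(k, n, completed)`.
#' @export
submit_and_advance <- function(store, session_id, answers, measurements = list()) {
  s <- get_session(store, session_id)
  if (s$completed) bs_abort("session_finished", "all images have been assessed")
  proj <- get_project(store, s$project_id)
  qids <- vapply(proj$questions, function(q) q$question_id, character(1))
  missing <- setdiff(qids, names(answers))
  if (length(missing)) {
    bs_abort("incomplete_submission",
             sprintf("missing answer for %d question(s)", length(missing)))
  }
  image_id <- s$ordering[s$cursor + 1L]
  mjson <- measurements_to_json(measurements)
  encoded <- lapply(proj$questions, function(q) encode_answer(q, answers[[q$question_id]]))
  now <- utc_now()
  DBI::dbWithTransaction(store$con, {
    for (i in seq_along(proj$questions)) {
      DBI::dbExecute(store$con,
        "INSERT INTO responses (session_id, image_id, question_id, value, value_num,
           measurements, submitted_at) VALUES (?,?,?,?,?,?,?)",
        params = list(session_id, image_id, qids[i], encoded[[i]]$value,
                      encoded[[i]]$value_num, mjson, now))
    }
    new_cursor <- s$cursor + 1L
    DBI::dbExecute(store$con,
      "UPDATE sessions SET cursor = ?, completed = ? WHERE session_id = ?",
      params = list(new_cursor, as.integer(new_cursor == s$n_images), session_id))
  })
  log_event(store, "item_submitted", session_id, image_id)
  list(k = s$cursor + 1L, n = s$n_images, completed = (s$cursor + 1L) == s$n_images)
}

#' Session progress
#'
#' @param store a `bs_store`.
#' @param session_id session identifier.
#' @return list `(k, n, completed)`: items completed out of total.
#' @export
session_progress <- function(store, session_id) {
  s <- get_session(store, session_id)
  list(k = s$cursor, n = s$n_images, completed = s$completed)
}
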