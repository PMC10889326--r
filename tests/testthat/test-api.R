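# In-process exercise of the HTTP router: same request/response records the
# httpuv adapter passes through, no sockets needed.

SECRET <- "test-admin-secret"

admin_hdr <- list(`x-admin-secret` = SECRET)

req_json <- function(app, method, path, body = NULL, headers = list(), query = list()) {
  resp <- api_handle(app, method, path, query = query, headers = headers,
                     body = if (is.null(body)) NULL else
                       as.character(jsonlite::toJSON(body, auto_unbox = TRUE, null = "null")))
  parsed <- if (is.character(resp$body) &&
                grepl("json", resp$headers[["Content-Type"]] %||% "", fixed = TRUE))
    jsonlite::fromJSON(resp$body, simplifyDataFrame = TRUE) else NULL
  list(status = resp$status, body = parsed, raw = resp)
}

make_demo_app <- function(st) {
  demo <- build_demo_project(st, seed = 8, image_px = 48L)
  list(app = api_app(st, SECRET), demo = demo)
}

test_that("master routes require the admin secret; observer tokens do not unlock them", {
  st <- local_store()
  x <- make_demo_app(st)
  pid <- x$demo$project$project_id

  r <- req_json(x$app, "GET", paste0("/api/projects/", pid, "/results"))
  expect_identical(r$status, 403L)
  # a share token is not an admin credential
  r2 <- req_json(x$app, "GET", paste0("/api/projects/", pid, "/results"),
                 headers = list(`x-admin-secret` = x$demo$project$share_token))
  expect_identical(r2$status, 403L)
  r3 <- req_json(x$app, "GET", paste0("/api/projects/", pid, "/results"),
                 headers = admin_hdr)
  expect_identical(r3$status, 200L)
})

test_that("all four result views render over the API", {
  st <- local_store()
  x <- make_demo_app(st)
  pid <- x$demo$project$project_id
  for (view in c("combined", "per_observer", "per_group", "per_image")) {
    r <- req_json(x$app, "GET", paste0("/api/projects/", pid, "/results"),
                  headers = admin_hdr, query = list(view = view))
    expect_identical(r$status, 200L)
    expect_identical(r$body$view, view)
  }
  per_image <- req_json(x$app, "GET", paste0("/api/projects/", pid, "/results"),
                        headers = admin_hdr, query = list(view = "per_image"))
  expect_identical(nrow(per_image$body$results$summary), 24L)
  per_group <- req_json(x$app, "GET", paste0("/api/projects/", pid, "/results"),
                        headers = admin_hdr, query = list(view = "per_group"))
  expect_identical(nrow(per_group$body$results$by_data_group), 4L)

  csv <- api_handle(x$app, "GET", paste0("/api/projects/", pid, "/export.csv"),
                    headers = admin_hdr)
  expect_identical(csv$status, 200L)
  expect_identical(csv$body, export_csv(st, pid))
})

test_that("disabled tokens are refused and look identical to unknown ones for observers", {
  st <- local_store()
  x <- make_demo_app(st)
  set_share_enabled(st, x$demo$project$project_id, FALSE)
  token <- x$demo$project$share_token
  disabled <- req_json(x$app, "POST", paste0("/api/observe/", token, "/sessions"),
                       body = list())
  unknown <- req_json(x$app, "POST", "/api/observe/not-a-token/sessions",
                      body = list())
  expect_identical(disabled$status, 403L)
  expect_identical(unknown$status, 404L)
  # the observer-facing message reveals nothing beyond the code
  expect_false(grepl("project|share", disabled$body$error$message, ignore.case = TRUE))
})

test_that("an observer session runs start-to-finish over the router, blinded", {
  st <- local_store()
  p <- create_project(st, "wire-blind", list(question("g", "numeric")),
                      data_groups = c("Placebo", "Verum"))
  planted <- c("WIRE^LEAK", "Wire Clinic")
  for (i in 1:3) {
    syn <- make_synthetic_dicom(48, 48, 1, NULL,
                                planted_tags = list(PatientName = planted[1],
                                                    InstitutionName = planted[2]),
                                seed = i)
    ingest_image(st, p$project_id, syn$dicom, sprintf("verum_%d.dcm", i),
                 data_group = "Verum")
  }
  set_share_enabled(st, p$project_id, TRUE)
  p <- get_project(st, p$project_id)
  app <- api_app(st, SECRET)
  qid <- p$questions[[1]]$question_id

  transcript <- character()
  boot <- req_json(app, "POST", paste0("/api/observe/", p$share_token, "/sessions"),
                   body = list(observer_label = "obs-A"))
  expect_identical(boot$status, 201L)
  sid <- boot$body$session_id
  transcript <- c(transcript, body_text(boot$raw))

  for (i in 1:3) {
    cur <- api_handle(app, "GET", paste0("/api/sessions/", sid, "/current"))
    expect_identical(cur$status, 200L)
    transcript <- c(transcript, body_text(cur))
    item <- jsonlite::fromJSON(cur$body)
    # the signed frame URL serves bytes for this session...
    furl <- item$image$frame_urls[1]
    parts <- strsplit(furl, "?sig=", fixed = TRUE)[[1]]
    fr <- api_handle(app, "GET", parts[1], query = list(sig = parts[2]))
    expect_identical(fr$status, 200L)
    expect_true(is.raw(fr$body))
    transcript <- c(transcript, body_text(fr))
    # ...but not with a bad signature, and not for another session
    bad <- api_handle(app, "GET", parts[1], query = list(sig = "forged"))
    expect_identical(bad$status, 403L)

    sub <- req_json(app, "POST", paste0("/api/sessions/", sid, "/submit"),
                    body = list(answers = setNames(list(i * 1.5), qid)))
    expect_identical(sub$status, 200L)
    transcript <- c(transcript, body_text(sub$raw))
  }
  done <- api_handle(app, "GET", paste0("/api/sessions/", sid, "/current"))
  expect_identical(done$status, 410L)
  extra <- req_json(app, "POST", paste0("/api/sessions/", sid, "/submit"),
                    body = list(answers = setNames(list(9), qid)))
  expect_identical(extra$status, 410L)

  # wire-level blinding: the full transcript holds none of the secrets
  full <- paste(transcript, collapse = "\n")
  for (bad in c(planted, "verum_", "Verum", "Placebo")) {
    expect_false(grepl(bad, full, fixed = TRUE, useBytes = TRUE),
                 label = paste("leak:", bad))
  }
})

test_that("a frame URL from one session is rejected in another", {
  st <- local_store()
  x <- make_demo_app(st)
  token <- x$demo$project$share_token
  s1 <- req_json(x$app, "POST", paste0("/api/observe/", token, "/sessions"), body = list())
  s2 <- req_json(x$app, "POST", paste0("/api/observe/", token, "/sessions"), body = list())
  cur <- req_json(x$app, "GET", paste0("/api/sessions/", s1$body$session_id, "/current"))
  furl <- cur$body$image$frame_urls[1]
  parts <- strsplit(furl, "?sig=", fixed = TRUE)[[1]]
  # rewrite the path to session 2 but keep session 1's signature
  alien <- sub(s1$body$session_id, s2$body$session_id, parts[1], fixed = TRUE)
  r <- api_handle(x$app, "GET", alien, query = list(sig = parts[2]))
  expect_identical(r$status, 403L)
})

test_that("project creation and upload work through the API", {
  st <- local_store()
  app <- api_app(st, SECRET)
  created <- req_json(app, "POST", "/api/projects", headers = admin_hdr,
                      body = list(name = "api-made",
                                  questions = list(list(prompt = "len", kind = "numeric",
                                                        units = "mm")),
                                  data_groups = list("A")))
  expect_identical(created$status, 201L)
  pid <- created$body$project_id

  syn <- make_synthetic_png(48, 48, 1, NULL, seed = 3)
  up <- req_json(app, "POST", paste0("/api/projects/", pid, "/images"),
                 headers = admin_hdr,
                 body = list(name = "x.png", data_group = "A",
                             content_base64 = openssl::base64_encode(syn$png)))
  expect_identical(up$status, 201L)
  expect_identical(up$body$media_kind, "png")

  sh <- req_json(app, "POST", paste0("/api/projects/", pid, "/share"),
                 headers = admin_hdr, body = list(enabled = TRUE))
  expect_true(sh$body$share_enabled)

  # bad uploads surface as unsupported media
  bad <- req_json(app, "POST", paste0("/api/projects/", pid, "/images"),
                  headers = admin_hdr,
                  body = list(name = "junk.bin",
                              content_base64 = openssl::base64_encode(as.raw(1:5))))
  expect_identical(bad$status, 415L)
})
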