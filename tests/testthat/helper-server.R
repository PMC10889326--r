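# Launch a real blindscore server in a background R process and return a
# handle with its base URL and a stop function. Used by the end-to-end HTTP
# tests; everything else exercises the router in-process.

start_bg_server <- function(db_path, secret, timeout_s = 30) {
  rscript <- file.path(R.home("bin"), "Rscript")
  log <- tempfile("server", fileext = ".log")
  for (attempt in 1:5) {
    port <- sample(21000:45000, 1)
    code <- sprintf("blindscore::serve('%s', port = %d, admin_secret = '%s')",
                    db_path, port, secret)
    system2(rscript, c("-e", shQuote(code)), wait = FALSE,
            stdout = log, stderr = log)
    base <- sprintf("http://127.0.0.1:%d", port)
    deadline <- Sys.time() + timeout_s
    up <- FALSE
    while (Sys.time() < deadline) {
      ok <- tryCatch(httr::status_code(httr::GET(paste0(base, "/api/health"),
                                                 httr::timeout(2))) == 200L,
                     error = function(e) FALSE)
      if (ok) { up <- TRUE; break }
      # a port clash kills the child immediately; try a fresh port
      if (any(grepl("Failed to create server", readLines(log, warn = FALSE)))) break
      Sys.sleep(0.2)
    }
    if (up) {
      stop_fn <- function() {
        tryCatch(httr::POST(paste0(base, "/api/shutdown"),
                            httr::add_headers(`x-admin-secret` = secret),
                            httr::timeout(5)),
                 error = function(e) NULL)
        invisible(NULL)
      }
      return(list(base = base, stop = stop_fn, log = log))
    }
  }
  stop("could not start a background server; log tail: ",
       paste(utils::tail(readLines(log, warn = FALSE), 5), collapse = " | "))
}
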