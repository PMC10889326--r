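# Four responses for one image — the worked grading example: two observers
# at grade 0.5 and two at grade 1 tally to {0.5: 2, 1: 2} and average to
# 0.75 with sample SD ~0.2887.
make_fig4_project <- function(st) {
  p <- create_project(st, "tally",
                      list(question("grade", "single_choice",
                                    choices = c("Grade 0.5", "Grade 1"),
                                    values = c(0.5, 1))))
  syn <- make_synthetic_png(48, 48, 1, NULL, seed = 1)
  ingest_image(st, p$project_id, syn$png, "87-86.jpg.png")
  set_share_enabled(st, p$project_id, TRUE)
  p <- get_project(st, p$project_id)
  qid <- p$questions[[1]]$question_id
  for (ans in c("Grade 0.5", "Grade 0.5", "Grade 1", "Grade 1")) {
    s <- start_session(st, p$share_token, observer_label = ans)
    submit_and_advance(st, s$session_id, setNames(list(ans), qid))
  }
  list(p = p, qid = qid)
}

test_that("the worked four-observer tally and summary reproduce exactly", {
  st <- local_store()
  fx <- make_fig4_project(st)
  tal <- tally_responses(st, fx$p$project_id, fx$qid)
  expect_identical(nrow(tal), 2L)
  expect_identical(tal$count[tal$value == "Grade 0.5"], 2L)
  expect_identical(tal$count[tal$value == "Grade 1"], 2L)

  summ <- summarize_responses(st, fx$p$project_id, fx$qid, group_by = "image")
  expect_identical(summ$n, 4L)
  expect_equal(summ$mean, 0.75)
  # cross-check against the independent routine
  expect_equal(summ$sd, sd(c(0.5, 0.5, 1, 1)))
  expect_equal(summ$sd, 0.2886751, tolerance = 1e-6)
})

test_that("merge joins master-side context and flags incomplete sessions", {
  st <- local_store()
  demo <- build_demo_project(st, seed = 5, image_px = 48L)
  pid <- demo$project$project_id
  tab <- merge_responses(st, pid)
  expect_identical(nrow(tab), 96L)  # 4 observers x 24 images x 1 question
  expect_true(all(tab$session_complete))
  expect_setequal(unique(tab$data_group), c("2", "4", "8", "12"))
  expect_true(all(grepl("^specimen_wk", tab$original_name)))

  # a half-done extra session appears flagged in merge, excluded from summaries
  qid <- demo$question_id
  s <- start_session(st, demo$project$share_token, observer_label = "partial")
  for (i in 1:12) {
    item <- current_item(st, s$session_id)
    submit_and_advance(st, s$session_id, setNames(list("Grade 3"), qid))
  }
  tab2 <- merge_responses(st, pid)
  expect_identical(nrow(tab2), 108L)
  expect_identical(sum(!tab2$session_complete), 12L)
  combined <- summarize_responses(st, pid, qid)
  expect_identical(combined$n, 96L)
  with_partial <- summarize_responses(st, pid, qid, include_incomplete = TRUE)
  expect_identical(with_partial$n, 108L)
})

test_that("tallies conserve counts and the grand mean is the weighted group mean", {
  st <- local_store()
  demo <- build_demo_project(st, seed = 13, image_px = 48L)
  pid <- demo$project$project_id; qid <- demo$question_id

  tal <- tally_responses(st, pid, qid)
  per_image <- tapply(tal$count, tal$image_id, sum)
  expect_true(all(per_image == 4L))  # every observer answered every image

  grand <- summarize_responses(st, pid, qid)
  for (axes in list("data_group", "observer", c("observer_group", "data_group"))) {
    g <- summarize_responses(st, pid, qid, group_by = axes)
    expect_identical(sum(g$n), grand$n)
    expect_equal(sum(g$n * g$mean) / sum(g$n), grand$mean, tolerance = 1e-9)
  }
  # single-response groups have no SD
  per_obs_img <- summarize_responses(st, pid, qid, group_by = c("observer", "image"))
  expect_true(all(per_obs_img$n == 1L))
  expect_true(all(is.na(per_obs_img$sd)))
})

test_that("a question without numeric encoding is tally-only", {
  st <- local_store()
  p <- create_project(st, "colors",
                      list(question("dominant stain", "single_choice",
                                    choices = c("red", "blue"))))
  syn <- make_synthetic_png(48, 48, 1, NULL, seed = 1)
  ingest_image(st, p$project_id, syn$png, "a.png")
  set_share_enabled(st, p$project_id, TRUE)
  p <- get_project(st, p$project_id)
  qid <- p$questions[[1]]$question_id
  s <- start_session(st, p$share_token)
  submit_and_advance(st, s$session_id, setNames(list("red"), qid))
  expect_error(summarize_responses(st, p$project_id, qid),
               class = "bs_tally_only_error")
  tal <- tally_responses(st, p$project_id, qid)
  expect_identical(tal$count, 1L)
})

test_that("CSV export is RFC-4180 parseable and round-trips the aggregates", {
  st <- local_store()
  demo <- build_demo_project(st, seed = 21, image_px = 48L)
  pid <- demo$project$project_id; qid <- demo$question_id

  csv <- export_csv(st, pid)
  lines <- strsplit(csv, "\n", fixed = TRUE)[[1]]
  expect_length(lines, 97L)  # header + 96 responses
  expect_match(lines[1], "^image_original_name,image_id,data_group")

  back <- import_csv(csv)
  expect_identical(nrow(back), 96L)
  for (axes in list(character(), "data_group", c("observer", "data_group"))) {
    live <- summarize_responses(st, pid, qid, group_by = axes)
    sub <- back[back$question_id == qid & back$session_complete, , drop = FALSE]
    redone <- blindscore:::summarize_table(sub, axes)
    expect_equal(redone$n, live$n)
    expect_equal(redone$mean, live$mean, tolerance = 1e-12)
    expect_equal(redone$sd, live$sd, tolerance = 1e-12)
  }
})

test_that("answer labels containing commas and quotes are quoted per RFC 4180", {
  st <- local_store()
  p <- create_project(st, "quoting",
                      list(question("finding", "single_choice",
                                    choices = c("normal", "fibrillation, severe \"grade\""),
                                    values = c(0, 1))))
  syn <- make_synthetic_png(48, 48, 1, NULL, seed = 1)
  ingest_image(st, p$project_id, syn$png, "a.png")
  set_share_enabled(st, p$project_id, TRUE)
  p <- get_project(st, p$project_id)
  s <- start_session(st, p$share_token)
  submit_and_advance(st, s$session_id,
                     setNames(list("fibrillation, severe \"grade\""),
                              p$questions[[1]]$question_id))
  csv <- export_csv(st, p$project_id)
  expect_match(csv, "\"fibrillation, severe \"\"grade\"\"\"", fixed = TRUE)
  back <- import_csv(csv)
  expect_identical(back$value, "fibrillation, severe \"grade\"")
})

test_that("tally conservation holds on a fuzzed response set", {
  st <- local_store()
  grades <- seq(0, 6, by = 0.5)
  p <- create_project(st, "fuzz",
                      list(question("g", "single_choice",
                                    choices = paste("Grade", grades), values = grades)))
  for (i in 1:5) {
    syn <- make_synthetic_png(48, 48, 1, NULL, seed = 100 + i)
    ingest_image(st, p$project_id, syn$png, sprintf("f%d.png", i))
  }
  set_share_enabled(st, p$project_id, TRUE)
  p <- get_project(st, p$project_id)
  qid <- p$questions[[1]]$question_id
  set.seed(17)
  n_obs <- 40L
  for (ob in seq_len(n_obs)) {
    s <- start_session(st, p$share_token, observer_label = paste0("o", ob))
    for (k in 1:5) {
      lab <- sample(p$questions[[1]]$choices, 1)
      submit_and_advance(st, s$session_id, setNames(list(lab), qid))
    }
  }
  tab <- merge_responses(st, p$project_id)
  expect_identical(nrow(tab), 200L)
  tal <- tally_responses(st, p$project_id, qid)
  # brute-force recount oracle
  recount <- table(paste(tab$image_id, tab$value, sep = "\r"))
  expect_identical(sum(tal$count), 200L)
  for (r in seq_len(nrow(tal))) {
    key <- paste(tal$image_id[r], tal$value[r], sep = "\r")
    expect_identical(tal$count[r], as.integer(recount[[key]]))
  }
  per_image <- tapply(tal$count, tal$image_id, sum)
  expect_true(all(per_image == n_obs))
})
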