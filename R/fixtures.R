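# Synthetic study material with known ground truth. These generators stand
# in for real histology/radiography uploads: every planted quantity (blob
# centers, calibration-bar endpoints, DICOM tags, per-image true grades) is
# returned alongside the bytes, so ingestion, measurement and aggregation
# can be tested end-to-end with no external data.

# Place n disjoint discs by rejection sampling; a retry cap of 1000 per disc
# turns an over-dense request into a clean generation error instead of an
# endless loop.
place_blobs <- function(width, height, n_blobs, r_range, margin) {
  centers <- matrix(numeric(0), ncol = 3)  # x, y, r
  for (b in seq_len(n_blobs)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      r <- stats::runif(1, r_range[1], r_range[2])
      x <- stats::runif(1, r + margin, width - 1 - r - margin)
      y <- stats::runif(1, r + margin, height - 1 - r - margin)
      ok <- !nrow(centers) ||
        all(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) > centers[, 3] + r + 2)
      if (ok) {
        centers <- rbind(centers, c(x, y, r))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      bs_abort("generation",
               sprintf("could not place %d disjoint blobs in %dx%d px", n_blobs, width, height))
    }
  }
  centers
}

# Disc radii scale with the image so dense requests stay placeable on the
# small rasters used in tests as well as realistically sized ones.
blob_radius_range <- function(width, height) {
  s <- min(width, height)
  c(max(2, 0.02 * s), max(2.5, 0.05 * s))
}

# Rasterize discs + a horizontal calibration bar onto a [0,1] grayscale
# matrix (h x w). Bar ground-truth endpoints are bar_px apart.
raster_scene <- function(width, height, centers, bar_px, bg, fg, bar_val) {
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  img <- matrix(bg, nrow = height, ncol = width)
  for (b in seq_len(nrow(centers))) {
    inside <- (xs - centers[b, 1])^2 + (ys - centers[b, 2])^2 <= centers[b, 3]^2
    img[inside] <- fg
  }
  bar <- NULL
  if (!is.null(bar_px) && bar_px > 0) {
    bs_check(bar_px <= width - 8, "generation", "calibration bar longer than the image")
    y0 <- height - 6
    x0 <- floor((width - bar_px) / 2)
    img[y0 + 1, (x0 + 1):(x0 + bar_px + 1)] <- bar_val
    img[y0 + 2, (x0 + 1):(x0 + bar_px + 1)] <- bar_val
    bar <- list(p1 = c(x0, y0), p2 = c(x0 + bar_px, y0), length_px = bar_px)
  }
  list(img = img, bar = bar)
}

#' Generate a synthetic PNG with known ground truth
#'
#' A gray background with `n_blobs` disjoint dark discs (countable objects)
#' and a horizontal calibration bar whose ground-truth endpoints are exactly
#' `bar_px` pixels apart. Deterministic for a fixed seed.
#'
#' @param width_px,height_px image size (each >= 32).
#' @param n_blobs number of discs to place.
#' @param bar_px calibration-bar length in px, or `NULL` for no bar.
#' @param seed RNG seed.
#' @return list with `png` (raw bytes) and `truth`
#'   (`blobs` data frame x/y/r, `bar` endpoints, `colors`).
#' @export
make_synthetic_png <- function(width_px = 256L, height_px = 256L, n_blobs = 10L,
                               bar_px = 100L, seed = 1L) {
  bs_check(width_px >= 32L && height_px >= 32L, "validation",
           "synthetic images must be at least 32 px in each dimension")
  with_seed(seed, {
    centers <- place_blobs(width_px, height_px, n_blobs,
                           blob_radius_range(width_px, height_px), margin = 2)
    sc <- raster_scene(width_px, height_px, centers, bar_px,
                       bg = 220 / 255, fg = 40 / 255, bar_val = 0)
    arr <- array(rep(sc$img, 3L), dim = c(height_px, width_px, 3L))
    list(png = png::writePNG(arr),
         truth = list(
           blobs = if (nrow(centers))
             data.frame(x = centers[, 1], y = centers[, 2], r = centers[, 3])
           else data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
           bar = sc$bar,
           colors = list(background = c(220L, 220L, 220L),
                         blob = c(40L, 40L, 40L), bar = c(0L, 0L, 0L))))
  })
}

#' Generate a synthetic DICOM file with known ground truth
#'
#' The same scene as [make_synthetic_png()] rasterized into a 16-bit
#' grayscale secondary-capture DICOM, with arbitrary identifying elements
#' planted (to exercise the anonymization path) and optional PixelSpacing.
#'
#' @inheritParams make_synthetic_png
#' @param planted_tags named list of string elements to embed, e.g.
#'   `list(PatientName = "TEST^LEAK", PatientID = "12345")`.
#' @param pixel_spacing_mm_per_px optional spacing; scalar for isotropic or
#'   length-2 `c(row, col)` for anisotropic.
#' @param rescale optional `c(slope, intercept)` to plant as rescale elements.
#' @return list with `dicom` (raw bytes) and `truth` (as for the PNG
#'   generator, plus `planted_tags` and `pixel_spacing`).
#' @export
make_synthetic_dicom <- function(width_px = 128L, height_px = 128L, n_blobs = 5L,
                                 bar_px = 100L, planted_tags = list(),
                                 pixel_spacing_mm_per_px = NULL,
                                 rescale = NULL, seed = 1L) {
  bs_check(width_px >= 32L && height_px >= 32L, "validation",
           "synthetic images must be at least 32 px in each dimension")
  with_seed(seed, {
    centers <- place_blobs(width_px, height_px, n_blobs,
                           blob_radius_range(width_px, height_px), margin = 2)
    sc <- raster_scene(width_px, height_px, centers, bar_px,
                       bg = 0.1, fg = 0.85, bar_val = 1)
    px <- matrix(as.integer(round(sc$img * 4000)), nrow = height_px)
    extra <- planted_tags
    if (!is.null(pixel_spacing_mm_per_px)) {
      sp <- pixel_spacing_mm_per_px
      extra$PixelSpacing <- if (length(sp) == 1L) c(sp, sp) else sp
    }
    if (!is.null(rescale)) {
      extra$RescaleSlope <- rescale[1]
      extra$RescaleIntercept <- rescale[2]
    }
    list(dicom = dcm_write(px, extra),
         truth = list(
           blobs = data.frame(x = centers[, 1], y = centers[, 2], r = centers[, 3]),
           bar = sc$bar,
           values = list(background = 0.1 * 4000, blob = 0.85 * 4000, bar = 4000),
           planted_tags = planted_tags,
           pixel_spacing = pixel_spacing_mm_per_px))
  })
}

#' Simulate an observer cohort scoring images
#'
#' Each simulated observer answers every image with the grade nearest to
#' `true_score + Gaussian noise`; exact midpoint ties go to the lower grade.
#' This is the simplest noise model for a bounded ordinal score — a stand-in
#' for real raters, not a claim about their behavior.
#'
#' @param true_scores named numeric vector: true score per image key.
#' @param n_observers number of simulated observers.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   grade units.
#' @param grade_set sorted numeric vector of available grades.
#' @param seed RNG seed; the full response set is deterministic per seed.
#' @return data frame with `observer` (1..n), `image`, `true_score`,
#'   `answer` (a member of `grade_set`).
#' @export
simulate_observers <- function(true_scores, n_observers, noise_sd,
                               grade_set, seed = 1L) {
  bs_check(length(true_scores) >= 1L && !is.null(names(true_scores)),
           "validation", "true_scores must be a named numeric vector")
  bs_check(is.numeric(grade_set) && length(grade_set) >= 1L &&
             !is.unsorted(grade_set, strictly = TRUE),
           "validation", "grade_set must be sorted strictly increasing")
  with_seed(seed, {
    rows <- expand.grid(observer = seq_len(n_observers),
                        image = names(true_scores),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$observer), , drop = FALSE]
    truth <- true_scores[rows$image]
    noisy <- truth + stats::rnorm(nrow(rows), 0, noise_sd)
    # which.min takes the first (= lower) grade on exact-distance ties
    rows$true_score <- as.numeric(truth)
    rows$answer <- vapply(noisy, function(v) grade_set[which.min(abs(grade_set - v))],
                          numeric(1))
    rownames(rows) <- NULL
    rows
  })
}

# "Grade 0", "Grade 0.5", ..., "Grade 6" with their numeric encodings.
oarsi_choices <- function() {
  grades <- seq(0, 6, by = 0.5)
  list(labels = paste("Grade", vapply(grades, function(g)
         format(g, trim = TRUE, drop0trailing = TRUE), character(1))),
       values = grades)
}

#' Build a fully populated demonstration project
#'
#' Replicates the shape of a typical blinded grading study: 24 synthetic
#' images in four data groups `"2"`, `"4"`, `"8"`, `"12"` (six each,
#' emulating weeks after intervention), one single-choice grading question
#' with numerically encoded grades 0-6 in half steps, and four simulated
#' observers who each complete a full randomized session. The per-group true
#' mean grades rise monotonically across the groups (progressive
#' degeneration), so group summaries have a known signal to recover.
#'
#' @param store a `bs_store`.
#' @param seed master seed controlling images, session orders and simulated
#'   answers.
#' @param noise_sd observer noise in grade units (default 0.5).
#' @param n_observers number of simulated observers (default 4).
#' @param image_px side length of the generated square images (default 96).
#' @return list with `project` (the populated `bs_project`), `question_id`,
#'   `truth` (data frame image/original_name/data_group/true_score),
#'   `group_true_means` (named vector), `sessions` (ids).
#' @export
build_demo_project <- function(store, seed = 1L, noise_sd = 0.5,
                               n_observers = 4L, image_px = 96L) {
  groups <- c("2", "4", "8", "12")
  group_means <- c(`2` = 1, `4` = 2, `8` = 3.5, `12` = 5)
  oarsi <- oarsi_choices()
  proj <- create_project(
    store, "Demo grading study",
    list(question("OARSI grade", "single_choice",
                  choices = oarsi$labels, values = oarsi$values)),
    data_groups = groups,
    observer_groups = c("PhD student", "Postdoc"))

  truth <- with_seed(seed, {
    df <- data.frame(
      original_name = sprintf("specimen_wk%s_%02d.png", rep(groups, each = 6L), 1:6),
      data_group = rep(groups, each = 6L),
      stringsAsFactors = FALSE)
    df$true_score <- pmin(6, pmax(0, group_means[df$data_group] +
                                       stats::rnorm(nrow(df), 0, 0.3)))
    df
  })

  truth$image_id <- NA_character_
  for (i in seq_len(nrow(truth))) {
    syn <- make_synthetic_png(image_px, image_px,
                              n_blobs = 2L + (i %% 4L), bar_px = NULL,
                              seed = seed * 1000L + i)
    rec <- ingest_image(store, proj$project_id, syn$png,
                        truth$original_name[i], truth$data_group[i])
    truth$image_id[i] <- rec$image_id
  }

  set_share_enabled(store, proj$project_id, TRUE)
  proj <- get_project(store, proj$project_id)
  qid <- proj$questions[[1]]$question_id

  true_scores <- stats::setNames(truth$true_score, truth$image_id)
  sims <- simulate_observers(true_scores, n_observers, noise_sd,
                             grade_set = oarsi$values, seed = seed + 7L)
  label_of <- stats::setNames(oarsi$labels, as.character(oarsi$values))

  session_ids <- character(n_observers)
  for (ob in seq_len(n_observers)) {
    sess <- start_session(store, proj$share_token,
                          observer_group = proj$observer_groups[1L + (ob %% 2L)],
                          observer_label = sprintf("Observer %d", ob),
                          seed = seed * 100L + ob)
    session_ids[ob] <- sess$session_id
    obs_rows <- sims[sims$observer == ob, , drop = FALSE]
    answer_of <- stats::setNames(label_of[as.character(obs_rows$answer)], obs_rows$image)
    repeat {
      item <- tryCatch(current_item(store, sess$session_id),
                       bs_session_finished_error = function(e) NULL)
      if (is.null(item)) break
      ans <- stats::setNames(list(unname(answer_of[item$image$image_id])), qid)
      submit_and_advance(store, sess$session_id, ans)
    }
  }

  list(project = get_project(store, proj$project_id),
       question_id = qid,
       truth = truth,
       group_true_means = tapply(truth$true_score, truth$data_group, mean)[groups],
       sessions = session_ids)
}
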