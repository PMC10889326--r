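# Shared helpers: every fixture is generated in code at test time.

local_store <- function(env = parent.frame()) {
  st <- store_open(":memory:")
  withr::defer(store_close(st), envir = env)
  st
}

# A minimal valid project: one numeric question, optional groups.
make_project <- function(st, name = "P", data_groups = character(),
                         observer_groups = character()) {
  create_project(st, name, list(question("score", "numeric")),
                 data_groups = data_groups, observer_groups = observer_groups)
}

# A shared, enabled project with n small synthetic images.
make_imaged_project <- function(st, n_images = 3L, seed = 42L, ...) {
  p <- make_project(st, ...)
  for (i in seq_len(n_images)) {
    syn <- make_synthetic_png(48, 48, n_blobs = 1L, bar_px = NULL,
                              seed = seed + i)
    ingest_image(st, p$project_id, syn$png, sprintf("img_%02d.png", i))
  }
  set_share_enabled(st, p$project_id, TRUE)
}

# Independent polygon-area oracle: triangulate by fanning from a kernel
# point and sum absolute triangle areas. Exact for any polygon star-shaped
# around `center` — a different computation path than the single shoelace
# sum (per-triangle cross products, absolute values, explicit closing edge).
fan_triangulation_area <- function(pts, center) {
  n <- nrow(pts)
  total <- 0
  for (i in seq_len(n)) {
    u <- pts[i, ] - center
    v <- pts[if (i == n) 1L else i + 1L, ] - center
    total <- total + abs(u[1] * v[2] - u[2] * v[1]) / 2
  }
  total
}

# Random simple polygon, star-shaped around (20, 20): jittered
# equally-spaced angles (every angular gap stays below pi, so the center is
# in the polygon's kernel and the fan decomposition is exact) with random
# radii.
random_star_polygon <- function(n, seed) {
  set.seed(seed)
  ang <- (0:(n - 1)) * 2 * pi / n + runif(n, 0, 0.8 * pi / n)
  r <- runif(n, 2, 10)
  cbind(20 + r * cos(ang), 20 + r * sin(ang))
}

# Independent Mann-Whitney oracle, coded separately from the package: direct
# enumeration of labelings with a plain rank-free pair count.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  ucount <- function(aa, bb) {
    s <- 0
    for (x in aa) for (y in bb) s <- s + (x > y) + 0.5 * (x == y)
    s
  }
  u_obs <- ucount(a, b)
  mu <- na * (n - na) / 2
  sel <- utils::combn(n, na)
  us <- numeric(ncol(sel))
  for (k in seq_len(ncol(sel))) {
    us[k] <- ucount(pooled[sel[, k]], pooled[-sel[, k]])
  }
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Serialize an API response body for leak grepping.
body_text <- function(resp) {
  if (is.raw(resp$body)) rawToChar(resp$body[resp$body != as.raw(0)]) else resp$body
}
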