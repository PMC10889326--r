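#' Random identifiers and tokens
#'
#' Identifiers are random hex strings from the OS CSPRNG; they carry no
#' information about the original filename, upload order, or content, so an
#' observer can never reconstruct metadata from an id. Share tokens use a
#' URL-safe alphabet and 32 characters drawn from 192 random bits, well above
#' the 128-bit non-guessability floor.
#' @keywords internal
new_id <- function(prefix = "") {
  paste0(prefix, paste(format(openssl::rand_bytes(16)), collapse = ""))
}

#' @keywords internal
new_token <- function(n_chars = 32L) {
  alphabet <- c(letters, LETTERS, 0:9, "-", "_")  # 64 symbols, URL-safe
  bytes <- as.integer(openssl::rand_bytes(n_chars))
  paste(alphabet[(bytes %% 64L) + 1L], collapse = "")
}

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
# Used wherever determinism under a stored seed is part of the contract.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Fresh 31-bit seed from the CSPRNG (set.seed needs a 32-bit signed integer).
csprng_seed <- function() {
  b <- as.integer(openssl::rand_bytes(4))
  as.integer((b[1] %% 128L) * 16777216L + b[2] * 65536L + b[3] * 256L + b[4])
}

#' Natural-order sort of file names
#'
#' Orders names so that embedded integers compare numerically: `img2 < img10`.
#' Used to give zip-stack frames a deterministic, human-expected order.
#' @param x character vector of names.
#' @return `x` reordered.
#' @keywords internal
natural_sort <- function(x) {
  if (length(x) < 2L) return(x)
  # Pad every digit run to a fixed width so lexicographic == natural order.
  pad <- function(s) {
    m <- gregexpr("[0-9]+", s)[[1]]
    if (m[1] == -1L) return(tolower(s))
    parts <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    padded <- sprintf("%020d", as.numeric(parts))
    out <- s
    regmatches(out, gregexpr("[0-9]+", out)) <- list(padded)
    tolower(out)
  }
  keys <- vapply(x, pad, character(1))
  x[order(keys, x, method = "radix")]
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
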