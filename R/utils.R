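# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Deterministic per-point RNG substream: keyed by (master seed, row, col) so
# grids are reproducible and independent of traversal order. Kept < 2^31.
derive_seed <- function(seed, row, col) {
  as.integer((as.numeric(seed) + row * 100003 + col * 193) %% 2147483647L)
}

# Run `code` under `seed` without clobbering the caller's RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Decimal text at 9 significant digits: the on-disk number format for all
# CSV artifacts, so write -> read -> write reproduces identical bytes.
fmt_num <- function(x) {
  trimws(formatC(x, digits = 9L, format = "g"))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# md5 of the canonical JSON serialization (used as the config hash carried
# by pipeline artifacts).
hash_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(tf))
}
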