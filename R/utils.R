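#' @importFrom rlang abort .data :=
#' @importFrom dplyr %>%
#' @importFrom tibble tibble as_tibble
NULL

# Internal error helper: all user-facing errors carry a cldatlas_* class so
# callers (and tests) can match on condition class rather than message text.
cld_abort <- function(message, class) {
  abort(message, class = c(paste0("cldatlas_", class), "cldatlas_error"))
}

# Derive a stream-specific 32-bit seed from a master seed, so independent
# random components (sequences, tree, mutations, ...) do not share a stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) * 69069L + stream * 1013L) %% 2147483647L
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)
}
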