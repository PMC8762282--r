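# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# population (1/n) standard deviation; the package standardises with this
# throughout so that location-scale operations are exactly idempotent
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

assert_count <- function(x, name, positive = FALSE) {
  if (!is_count(x) || (positive && x <= 0)) {
    stopf("`%s` must be a %s integer, got %s", name,
          if (positive) "positive" else "non-negative",
          paste(format(x), collapse = ","))
  }
  invisible(as.integer(x))
}

# derive a stream-specific child seed from a user seed, kept below 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtN", "TGCAtgcaN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
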