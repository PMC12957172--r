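# Internal helpers: deterministic RNG substreams, pair keys, chapter numbering.

# Stable string hash (djb2 reduced mod a Mersenne prime). Used only to derive
# RNG substream seeds, so the only requirements are determinism across
# platforms and good dispersion across keys.
hash_key <- function(key) {
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  h
}

# Derive a per-stage seed from the root seed and a string key. Keeping each
# stage/condition/pair on its own substream means adding one condition to a
# config does not perturb draws for unrelated stages.
substream_seed <- function(root, key) {
  as.integer((hash_key(key) + as.numeric(root) * 48271) %% 2147483646 + 1)
}

# Evaluate `code` under the substream RNG without touching the global state.
with_stream <- function(root, key, code) {
  withr::with_seed(substream_seed(root, key), code)
}

# Canonical unordered pair identity, lexicographic.
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "|")
}

# Roman-numeral ICD-10 chapter -> integer (I -> 1, ..., XXII -> 22).
chapter_number <- function(chapter) {
  as.integer(utils::as.roman(as.character(chapter)))
}

roman_chapters <- function(n) {
  as.character(utils::as.roman(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
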