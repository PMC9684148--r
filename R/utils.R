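# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Residue codes: A (GlcNAc) = TRUE, D (GlcN) = FALSE.
.chain_bits <- function(sequences) {
  lapply(sequences, function(s) utf8ToInt(s) == 65L)
}

.bits_to_string <- function(bits) {
  intToUtf8(ifelse(bits, 65L, 68L))
}

.assert_alphabet <- function(sequences, where = "sequence") {
  for (i in seq_along(sequences)) {
    bad <- regexpr("[^AD]", sequences[[i]])
    if (bad > 0L)
      stop(sprintf("invalid character '%s' in %s %d at position %d (alphabet is {A, D})",
                   substr(sequences[[i]], bad, bad), where, i, bad), call. = FALSE)
  }
  invisible(TRUE)
}
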