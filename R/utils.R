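# Small shared helpers.

str_rev <- function(x) {
  vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# substr() that returns "" for an empty/invalid span instead of surprises.
substr_safe <- function(x, start, stop) {
  if (is.na(start) || is.na(stop) || stop < start) return("")
  substr(x, start, stop)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Deterministic content hash used to stamp report tables.
config_hash <- function(x) rlang::hash(x)

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so cohort generation never perturbs it.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
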