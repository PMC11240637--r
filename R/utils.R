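DNA_BASES <- c("A", "C", "G", "T")

## half-up decimal rounding, as population-genetics reports conventionally
## print (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

is_unambiguous <- function(chars) chars %in% DNA_BASES

## scalar integer check for argument validation
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
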