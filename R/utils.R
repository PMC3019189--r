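# internal helpers: seed derivation, temporary RNG state, symbol encoding

# Deterministic child seeds: one root seed, children derived per purpose and
# index so experiments replay identically regardless of evaluation order.
child_seed <- function(root, purpose, ...) {
  stopifnot(is.numeric(root), length(root) == 1L)
  mod <- 2147483629 # prime < 2^31
  h <- root %% mod
  h <- (h * 48271 + sum(utf8ToInt(purpose))) %% mod
  idx <- c(...)
  primes <- c(104729, 1299709, 15485863, 32452843)
  for (i in seq_along(idx)) {
    h <- (h * 69621 + (idx[[i]] %% mod) * primes[((i - 1L) %% 4L) + 1L]) %% mod
  }
  as.integer(h %% mod) + 1L
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream; a NULL seed just evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split a sequence string (or pass a character vector through) and map the
# symbols to 1-based alphabet indices, reporting the first offender.
encode_symbols <- function(model, x, id = NULL) {
  chars <- if (length(x) == 1L && nchar(x[[1L]]) != 1L) strsplit(x, "", fixed = TRUE)[[1L]] else x
  idx <- match(chars, model$alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("symbol '%s' at position %d%s is not in the model alphabet {%s}",
                 chars[bad], bad,
                 if (is.null(id)) "" else sprintf(" of record '%s'", id),
                 paste(model$alphabet, collapse = ",")),
         call. = FALSE)
  }
  idx
}

decode_states <- function(model, idx) model$states[idx]

collapse_chr <- function(x) paste(x, collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a
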