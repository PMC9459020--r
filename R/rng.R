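# Per-purpose RNG streams. One root seed deterministically spawns a child
# seed per stream ("generate", "growth", "death"), so adding draws to one
# stream never perturbs the others. Stream states are full .Random.seed
# blobs kept in an environment and swapped in around each draw.

STREAM_KINDS <- c("generate", "growth", "death")

make_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_global_seed(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  children <- sample.int(.Machine$integer.max - 1L, length(STREAM_KINDS))
  for (i in seq_along(STREAM_KINDS)) {
    set.seed(children[i])
    assign(STREAM_KINDS[i], get(".Random.seed", envir = globalenv()), envir = env)
  }
  env
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate expr with the named stream's RNG state active; persist the
# advanced state back into the stream and restore the caller's RNG.
with_stream <- function(streams, kind, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", get(kind, envir = streams), envir = globalenv())
  res <- expr
  assign(kind, get(".Random.seed", envir = globalenv()), envir = streams)
  restore_global_seed(old)
  res
}
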