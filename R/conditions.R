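# Classed conditions so callers (and the CLI) can map failures to exit codes:
# usage -> 1, validation/format/lookup -> 2, io -> 3.

snet_abort <- function(message, class) {
  stop(structure(
    class = c(class, "screenet_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_validation <- function(message) {
  snet_abort(message, "screenet_validation_error")
}

abort_format <- function(message) {
  snet_abort(message, c("screenet_format_error", "screenet_validation_error"))
}

abort_lookup <- function(message) {
  snet_abort(message, c("screenet_lookup_error", "screenet_validation_error"))
}

abort_io <- function(message) {
  snet_abort(message, "screenet_io_error")
}

abort_usage <- function(message) {
  snet_abort(message, "screenet_usage_error")
}

# Run code under a fixed RNG seed without clobbering the caller's RNG state.
with_stream_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed from a base seed and a text label, kept
# inside the 32-bit signed range R's set.seed() accepts.
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}
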