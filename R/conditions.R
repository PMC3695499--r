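## Classed conditions so callers (and the command-line wrapper) can map
## failure modes to distinct exit codes: usage vs data vs I/O.

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rnasphere_usage_error", "rnasphere_error")))
}

stop_data <- function(msg, ..., class = character()) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "rnasphere_data_error", "rnasphere_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rnasphere_io_error", "rnasphere_error")))
}

## Run `code` with the RNG seeded to `seed`, restoring any pre-existing
## RNG state afterwards. All stochastic operations in the package go
## through this, so no call leaks state into the caller's session.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
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

`%||%` <- function(a, b) if (is.null(a)) b else a
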