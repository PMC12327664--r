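# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

abort_schema <- function(msg) abort(msg, class = "benthoscan_schema_error")
abort_config <- function(msg) abort(msg, class = "benthoscan_config_error")
abort_degenerate <- function(msg) abort(msg, class = "benthoscan_degenerate_error")
abort_state <- function(msg) abort(msg, class = "benthoscan_state_error")

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

# Stable fingerprint of an R object (configs, manifests); text-based so it does
# not depend on serialization internals.
fingerprint <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
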