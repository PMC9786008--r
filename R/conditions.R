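# Condition classes used across the package. Every error raised by moladr
# carries a subclass so callers (and the CLI) can distinguish bad user input
# from bad data from internal failures.

moladr_error <- function(class, message, ..., call = sys.call(-1)) {
  structure(
    class = c(class, "moladr_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

#' @noRd
stop_featurize <- function(message, smiles = NULL, id = NULL) {
  stop(moladr_error("moladr_featurize_error", message, smiles = smiles, id = id))
}

#' @noRd
stop_config <- function(message, field = NULL) {
  stop(moladr_error("moladr_config_error", message, field = field))
}

#' @noRd
stop_validation <- function(message, ...) {
  stop(moladr_error("moladr_validation_error", message, ...))
}

#' @noRd
stop_io <- function(message, path = NULL) {
  stop(moladr_error("moladr_io_error", message, path = path))
}

#' @noRd
stop_not_implemented <- function(message) {
  stop(moladr_error("moladr_not_implemented_error", message))
}

#' @noRd
stop_divergence <- function(message, epoch = NULL) {
  stop(moladr_error("moladr_divergence_error", message, epoch = epoch))
}

# Seed scoping: run `expr` under a given seed without disturbing the caller's
# RNG stream. Used by every stochastic entry point so that seeded calls are
# reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
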