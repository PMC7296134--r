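# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
abort_netrecov <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "netrecov_error")))
}

# Structured error for malformed/missing files; `file` names the offender.
#' @keywords internal
#' @noRd
abort_load <- function(msg, file = NULL) {
  abort_netrecov(msg, class = "netrecov_load_error", file = file)
}

#' @keywords internal
#' @noRd
abort_numeric <- function(msg, residual = NULL) {
  abort_netrecov(msg, class = "netrecov_numeric_error", residual = residual)
}

#' @keywords internal
#' @noRd
abort_undefined <- function(msg) {
  abort_netrecov(msg, class = "netrecov_undefined_statistic")
}

# Derive a vector of reproducible sub-seeds from one master seed without
# disturbing the caller's RNG state. Sub-seeds stay below 2^31 - 1.
#' @keywords internal
#' @noRd
spawn_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a local RNG seed, restoring the caller's stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
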