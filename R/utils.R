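# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Names of the four individual metrics, in canonical order.
metric_names <- function() c("cas", "miv", "mdm", "mdl")

#' Canonical display labels of the four difference metrics
#'
#' Returns the field-standard abbreviations (CAS, MIV, MDM, MDL) in the
#' canonical order used throughout the package for metric vectors, weight
#' vectors and thresholds.
#'
#' @return Character vector of length four.
#' @export
metric_labels <- function() c("CAS", "MIV", "MDM", "MDL")
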