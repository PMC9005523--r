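# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all percentage and display
#' rounding so that e.g. 62.5 renders as 63 and 10.53 as 11, matching the
#' convention of the cohort summary tables this package reproduces (R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(10.53)        # 11
#' round_half_up(62.5)         # 63
#' round_half_up(8.6758, 1)    # 8.7
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers/tests can distinguish structural from
# validation from usage errors.
abort_mbd <- function(msg, class = "mbd_validation_error") {
  stop(errorCondition(msg, class = c(class, "mbd_error", "error", "condition")))
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else suppressWarnings(rm(".Random.seed", envir = ge))
  }, add = TRUE)
  set.seed(seed)
  expr
}
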