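# Classed conditions so callers (and tests) can discriminate failure modes.

arcv_stop <- function(msg, class, call = sys.call(-1L)) {
  stop(errorCondition(msg, class = c(class, "arcv_error"), call = call))
}

arcv_warn <- function(msg, class = "arcv_warning") {
  warning(warningCondition(msg, class = c(class, "arcv_warning")))
}

# Evaluate `expr` under a deterministic RNG stream without disturbing the
# caller's stream. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    arcv_stop(sprintf("'%s' must be a finite numeric scalar", name),
              "arcv_validation_error")
  if (positive && x <= 0)
    arcv_stop(sprintf("'%s' must be positive", name), "arcv_validation_error")
  invisible(x)
}
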