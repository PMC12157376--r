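# Shared internal helpers: classed errors (the CLI maps the classes to exit
# codes) and a local, restoring RNG scope so seeded operations never disturb
# the caller's stream.

pf_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pf_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

pf_stop_input   <- function(msg) pf_stop(msg, "pf_invalid_input")
pf_stop_data    <- function(msg) pf_stop(msg, "pf_data_error")
pf_stop_numeric <- function(msg) pf_stop(msg, "pf_numeric_error")

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    pf_stop_input(sprintf("'%s' must be a numeric matrix", name))
  if (anyNA(x))
    pf_stop_input(sprintf("'%s' contains missing values", name))
  invisible(x)
}
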