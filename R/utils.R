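`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and the CLI) can distinguish bad input from
# malformed files and geometric degeneracies.
darc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "darc_error")))
}
darc_input_error <- function(msg) darc_error(msg, "darc_input_error")
darc_format_error <- function(msg) darc_error(msg, "darc_format_error")
darc_geometry_error <- function(msg) darc_error(msg, "darc_geometry_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) darc_input_error("coordinate matrix must have 3 columns")
    return(x)
  }
  if (is.numeric(x) && length(x) == 3) return(matrix(x, nrow = 1))
  darc_input_error("expected a 3-vector or an n x 3 matrix of coordinates")
}
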