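# Internal helpers shared across modules.

#' @keywords internal
geomean <- function(x) exp(mean(log(x)))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded generators do not perturb it.
# seed = NULL draws from the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validation that names the offending field, so errors surface with the
# parameter a user must fix.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

# Expand a scalar or per-group named vector to one value per group label.
# Used throughout the cohort generator so every covariate parameter may be
# given once or per diagnostic group.
per_group <- function(x, groups, field) {
  if (length(x) == 1L && is.null(names(x))) {
    out <- rep(unname(x), length(groups))
    names(out) <- groups
    return(out)
  }
  missing <- setdiff(groups, names(x))
  if (length(missing))
    stop(sprintf("invalid '%s': no value for group '%s'", field, missing[1L]),
         call. = FALSE)
  x[groups]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
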