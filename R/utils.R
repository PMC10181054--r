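# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed` and
#' restores the previous RNG state afterwards, so calling simulation functions
#' never perturbs user-level random streams.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97L * as.numeric(offset)) %% 2147483647)
}

stop_if_not_scalar_prob <- function(x, name, open_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x <= 1 && (if (open_zero) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single value in %s", name,
                 if (open_zero) "(0, 1]" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

# Column standard deviations without the matrixStats dependency.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}
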