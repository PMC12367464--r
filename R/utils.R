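#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded operations
#' (simulation, permutation tests) do not disturb the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# One Dirichlet draw via normalized gammas; alpha strictly positive.
rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha > 0))
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # pathological underflow guard
  g / sum(g)
}

# abort helper keeping call noise out of user-facing errors
sq_stop <- function(...) stop(..., call. = FALSE)

sq_warn <- function(...) warning(..., call. = FALSE)

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
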