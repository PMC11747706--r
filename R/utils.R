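`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number stream set from `seed`, then
#' restores the caller's stream so surrounding code is unaffected. A `NULL`
#' seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed deterministically
#'
#' Maps a parent seed and a stream index to a reproducible child seed
#' inside the 32-bit integer range expected by `set.seed()`. Used
#' throughout the package to give every simulation cell or replicate its
#' own independent, reproducible stream (e.g. the per-cell seeds of
#' [pta_grid()]).
#'
#' @param seed parent integer seed.
#' @param i stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(i) * 8191) %%
               2147483647)
}

# sample() without its scalar-x surprise: a length-1 candidate set is returned
# as-is instead of being treated as 1:x.
resample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

stop_bad <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad(name, " must be a single finite number")
  }
  if (strict && x <= lower) stop_bad(name, " must be > ", lower)
  if (!strict && x < lower) stop_bad(name, " must be >= ", lower)
  invisible(x)
}
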