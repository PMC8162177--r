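#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb an outer simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Orthonormalize the columns of a matrix
#'
#' Thin-QR orthonormalization with a deterministic sign convention
#' (largest-magnitude entry of each column made positive) so the result
#' depends only on the input, not on LAPACK sign choices.
#'
#' @param m numeric matrix with `nrow(m) >= ncol(m)`.
#' @return matrix of the same shape with orthonormal columns.
#' @keywords internal
orthonormalize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= ncol(m))
  q <- qr.Q(qr(m))[, seq_len(ncol(m)), drop = FALSE]
  sgn <- apply(q, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  sweep(q, 2L, sgn, `*`)
}

#' Cosine similarity of two vectors
#'
#' @param a,b numeric vectors of equal length, at least one entry nonzero each.
#' @return cosine in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine undefined for a zero-norm vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

# column-wise sample SD without forming per-column loops
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows for a standard deviation")
  mu <- colMeans(x)
  sqrt(pmax(colSums(sweep(x, 2L, mu)^2) / (n - 1L), 0))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid("non-finite values in %s", what)
  invisible(x)
}
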