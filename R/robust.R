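#' Robust simple regression of many responses on one predictor
#'
#' Fits `y_j = b1_j + b2_j * x` independently for every column `j` of `Y` by
#' iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, scale = MAD/0.6745, at most 50 iterations,
#' tolerance 1e-8), the standard default of robust fitting routines.
#' All columns share the design, so the per-column weighted normal equations
#' are solved in closed form with column sums — thousands of dimensions fit
#' in a few passes over the data.
#'
#' Slope p-values are two-tailed t tests from the final weighted
#' least-squares step (n - 2 degrees of freedom).
#'
#' @param Y numeric matrix `n x p` of responses (one column per dimension).
#' @param x numeric predictor of length `n` (the ratings).
#' @param max_iter,tol IRLS controls.
#' @return list with numeric vectors `b1`, `b2`, `p` (length `p`) and the
#'   number of IRLS iterations used.
#' @export
robust_simple_regression <- function(Y, x, max_iter = 50L, tol = 1e-8) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (n < 3L) stop_invalid("need at least 3 observations")
  if (length(x) != n) stop_invalid("length(x) must equal nrow(Y)")
  check_finite(Y, "responses"); check_finite(x, "predictor")
  vx <- stats::var(x)
  if (vx == 0) stop_invalid("degenerate design: predictor (ratings) is constant")

  cc <- 4.685
  xbar <- mean(x)
  x2 <- x * x
  xY <- x * Y
  # OLS start
  b2 <- drop(crossprod(x - xbar, Y)) / ((n - 1) * vx)
  b1 <- colMeans(Y) - b2 * xbar
  W <- matrix(1, n, p)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    R <- Y - tcrossprod(x, b2) - rep(b1, each = n)
    s <- vapply(seq_len(p), function(j) stats::median(abs(R[, j])),
                numeric(1)) / 0.6745
    # dead columns (perfect fit, zero scale) keep plain LS weights via U = 0
    inv <- ifelse(s > .Machine$double.eps^0.5, 1 / (cc * s), 0)
    U <- R * rep(inv, each = n)
    W <- (1 - U * U)^2 * (U > -1 & U < 1)
    sw <- colSums(W)
    swx <- drop(crossprod(x, W))
    swxx <- drop(crossprod(x2, W))
    swy <- colSums(W * Y)
    swxy <- colSums(W * xY)
    det <- sw * swxx - swx^2
    b2_new <- (sw * swxy - swx * swy) / det
    b1_new <- (swxx * swy - swx * swxy) / det
    delta <- max(abs(b2_new - b2), abs(b1_new - b1))
    b1 <- b1_new; b2 <- b2_new
    if (delta < tol * max(1, max(abs(b1), abs(b2))) || iter >= max_iter) break
  }
  # final weighted-LS slope standard errors
  R <- Y - outer(x, b2) - rep(b1, each = n)
  sw <- colSums(W); swx <- colSums(W * x); swxx <- colSums(W * x^2)
  det <- sw * swxx - swx^2
  sigma2 <- colSums(W * R^2) / pmax(sw - 2, 1)
  se2 <- sigma2 * sw / det
  tstat <- ifelse(se2 > 0, b2 / sqrt(se2), 0)
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[se2 <= 0] <- 1          # exact fit: no evidence against anything
  list(b1 = unname(b1), b2 = unname(b2), p = unname(pval),
       iterations = iter)
}

#' Gaussian-copula mutual information between one variable and many
#'
#' Rank-normalizes each variable (empirical CDF mapped through the standard
#' normal quantile function) and computes the Gaussian mutual information
#' `-0.5 * log(1 - rho^2)` of the transformed pairs; a robust,
#' parameter-free lower-bound estimator of mutual information.
#'
#' @param Y numeric matrix `n x p`.
#' @param x numeric vector length `n`.
#' @return numeric vector of `p` nonnegative MI estimates (nats).
#' @export
gaussian_copula_mi <- function(Y, x) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(length(x) == n)
  gz <- function(v) stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  zx <- gz(x)
  Z <- apply(Y, 2L, gz)
  rho <- drop(stats::cor(zx, Z))
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  -0.5 * log(1 - rho^2)
}

#' Benjamini-Hochberg discovery mask
#'
#' @param p numeric p-values in \[0, 1\].
#' @param q FDR level.
#' @return logical vector: TRUE where the BH-adjusted p-value is `<= q`.
#' @export
bh_mask <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  stats::p.adjust(p, method = "BH") <= q
}
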