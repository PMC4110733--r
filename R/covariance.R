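#' Empirical covariance of an expression matrix
#'
#' Computes the maximum-likelihood covariance over samples,
#' `S_ij = (1/n) * sum_k (x_ik - xbar_i)(x_jk - xbar_j)` (denominator `n`,
#' matching the Gaussian log-likelihood the graphical lasso maximises).
#' With `standardize = TRUE` (default) the matrix is rescaled to a
#' correlation matrix, `diag(S) = 1` — genes are measured on heterogeneous
#' scales, so the penalty then treats them symmetrically.
#'
#' @param m An expression matrix (typically log2-scale, post-normalization),
#'   or a bare genes-by-samples numeric matrix.
#' @param standardize Rescale to a correlation matrix (a gene with zero
#'   variance is then an error).
#' @return A symmetric p-by-p numeric matrix with gene labels as dimnames.
#' @export
empirical_covariance <- function(m, standardize = TRUE) {
  v <- if (inherits(m, "grn_expr")) expr_values(m) else {
    if (!is.matrix(m) || !is.numeric(m)) stop_("`m` must be an expression matrix or numeric matrix")
    m
  }
  n <- ncol(v)
  if (n < 2L) stop_("need at least 2 samples to estimate a covariance")
  xc <- v - rowMeans(v)
  S <- tcrossprod(xc) / n
  if (standardize) {
    d <- sqrt(diag(S))
    if (any(d < 1e-12)) {
      stop_("zero-variance gene(s) under standardize: ",
            paste(rownames(v)[d < 1e-12], collapse = ", "))
    }
    S <- S / tcrossprod(d)
    diag(S) <- 1
  }
  dimnames(S) <- list(rownames(v), rownames(v))
  S
}

#' Penalized Gaussian log-likelihood objective
#'
#' The criterion the graphical lasso maximises over positive-definite
#' precision matrices:
#' `log det(Theta) - trace(S Theta) - lambda * sum(|Theta|)`,
#' where the L1 norm runs over *all* entries, diagonal included.
#'
#' @param theta Symmetric positive-definite candidate precision matrix.
#' @param S Covariance matrix (same dimension).
#' @param lambda Non-negative penalty weight.
#' @return The objective value (a single number; larger is better).
#' @export
penalized_objective <- function(theta, S, lambda) {
  check_symmetric(theta, "theta", tol = 1e-8)
  check_symmetric(S, "S")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_("`lambda` must be a single non-negative number")
  }
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch)) stop_("`theta` must be positive definite")
  2 * sum(log(diag(ch))) - sum(S * theta) - lambda * sum(abs(theta))
}

#' Convert a -log10(lambda) grid to penalty values
#'
#' Regularisation strengths are conventionally reported as `-log10(lambda)`
#' (larger value = weaker penalty = denser network); this maps a reported
#' grid back to raw `lambda` values, `lambda_i = 10^(-v_i)`.
#'
#' @param neglog10_values Numeric vector of `-log10(lambda)` values.
#' @return Numeric vector of `lambda` values.
#' @examples
#' lambda_grid(c(0, 1, 1.2))
#' @export
lambda_grid <- function(neglog10_values) {
  if (!is.numeric(neglog10_values)) stop_("`neglog10_values` must be numeric")
  10^(-neglog10_values)
}
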