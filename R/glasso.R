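#' Lasso subproblem by cyclic coordinate descent
#'
#' Approximately minimises `0.5 * t(beta) %*% W11 %*% beta - t(s12) %*% beta
#' + lambda * sum(|beta|)` — the per-column subproblem of the graphical
#' lasso, whose stationarity condition `W11 beta - s12 + lambda sign(beta) = 0`
#' is the gradient equation of an ordinary lasso regression. Each cyclic
#' update is the exact scalar minimiser
#' `beta_j <- soft(s12_j - sum_{k != j} W11_jk beta_k, lambda) / W11_jj`,
#' iterated until the largest coordinate change is below
#' `tol * max(1, max |beta|)` *and* the stationarity (subgradient) residual —
#' `|W11 beta - s12 + lambda sign(beta)|` on active coordinates,
#' `max(0, |W11 beta - s12| - lambda)` on zero ones — is below `10 * tol`.
#'
#' @param W11 Symmetric matrix with strictly positive diagonal
#'   (`(p-1) x (p-1)` in the glasso context).
#' @param s12 Right-hand-side vector.
#' @param lambda Non-negative L1 penalty.
#' @param beta_init Starting point (defaults to zero; glasso warm-starts it).
#' @param tol Convergence tolerance on coordinate changes.
#' @param max_iter Iteration cap; if hit, the best iterate is returned with a
#'   warning.
#' @return The coefficient vector `beta`. Exact zeros are produced by the
#'   soft-thresholding, not by rounding.
#' @examples
#' lasso_cd(matrix(1.1), 0.5, 0.1)  # soft(0.5, 0.1)/1.1 = 0.36364
#' @export
lasso_cd <- function(W11, s12, lambda, beta_init = NULL, tol = 1e-8, max_iter = 1000L) {
  check_symmetric(W11, "W11", tol = 1e-8)
  q <- ncol(W11)
  if (length(s12) != q) stop_("`s12` length must match `W11` dimension")
  if (any(diag(W11) <= 0)) stop_("`W11` must have a strictly positive diagonal")
  if (lambda < 0) stop_("`lambda` must be non-negative")
  if (is.null(beta_init)) beta_init <- numeric(q)
  res <- lasso_cd_(W11, s12, lambda, beta_init, tol, as.integer(max_iter))
  if (!res$converged) {
    warning("lasso coordinate descent hit max_iter = ", max_iter,
            " before converging; returning best iterate", call. = FALSE)
  }
  res$beta
}

# inner CD kernel, no validation (hot path)
lasso_cd_ <- function(W11, s12, lambda, beta, tol, max_iter) {
  q <- length(beta)
  Wb <- as.vector(W11 %*% beta)  # running W11 %*% beta
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    max_delta <- 0
    for (j in seq_len(q)) {
      bj <- beta[j]
      r <- s12[j] - Wb[j] + W11[j, j] * bj
      bn <- soft_threshold(r, lambda) / W11[j, j]
      if (bn != bj) {
        Wb <- Wb + W11[, j] * (bn - bj)
        beta[j] <- bn
        d <- abs(bn - bj)
        if (d > max_delta) max_delta <- d
      }
    }
    if (max_delta <= tol * max(1, max(abs(beta)))) {
      grad <- Wb - s12
      nz <- beta != 0
      kkt <- max(0, abs(grad[nz] + lambda * sign(beta[nz])),
                 abs(grad[!nz]) - lambda)
      if (kkt <= 10 * tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(beta = beta, iters = it, converged = converged)
}

#' Graphical lasso by block coordinate descent
#'
#' Estimates a sparse precision matrix `Theta` maximising the penalised
#' log-likelihood of [penalized_objective()]. The working variable is
#' `W ~ Theta^{-1}`, initialised at `S + lambda * I` with its diagonal fixed
#' thereafter. The solver cycles through the columns: with column `j`
#' partitioned last, the off-diagonal block `w12` solves a lasso regression
#' of `s12` on `W11` ([lasso_cd()], warm-started from the previous cycle's
#' coefficients), and `w12 <- W11 beta` is written back. Cycling repeats
#' until the mean absolute change of the off-diagonal of `W` falls below
#' `tol * mean |off-diagonal of S|`. The precision matrix is then recovered
#' column-wise from the final `beta`s ([recover_precision()]).
#'
#' @param S Covariance (or correlation) matrix, e.g. from
#'   [empirical_covariance()].
#' @param lambda Non-negative penalty; larger values give sparser networks.
#' @param tol Relative convergence tolerance for the outer loop.
#' @param max_outer,max_inner Iteration caps for the outer cycles and the
#'   inner lasso.
#' @param penalize_diagonal If `TRUE` (the algorithm as published), the
#'   diagonal of `W` is `diag(S) + lambda`; if `FALSE` it is `diag(S)`
#'   (the convention of some other implementations, kept as an option for
#'   cross-checks).
#' @param zero_eps Off-diagonal entries of the symmetrised `Theta` with
#'   absolute value below this are set to exact zero (safety net on top of
#'   the exact zeros that soft-thresholding already produces).
#' @param init Optional warm start: a previous `glasso_fit` on the same `S`
#'   (used internally by [glasso_path()]).
#' @return An object of class `glasso_fit`: a list with elements `theta`
#'   (sparse precision estimate), `W` (covariance estimate), `betas`
#'   (`(p-1) x p` matrix of final per-column lasso coefficients), `S`,
#'   `lambda`, `labels`, `outer_iters`, `converged`. Non-convergence gives a
#'   usable fit flagged `converged = FALSE`. Use [tidy()] for the edge list,
#'   [glance()] for a one-row summary, [extract_network()] for the network.
#' @examples
#' S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' fit <- glasso_fit(S, lambda = 0.1)
#' fit$theta
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, max_outer = 100L, max_inner = 1000L,
                       penalize_diagonal = TRUE, zero_eps = 1e-8, init = NULL) {
  check_symmetric(S, "S")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stop_("`lambda` must be a single non-negative number")
  }
  if (tol <= 0) stop_("`tol` must be positive")
  max_outer <- check_count(max_outer, "max_outer", min = 1L)
  max_inner <- check_count(max_inner, "max_inner", min = 1L)
  p <- ncol(S)
  labels <- colnames(S)
  if (is.null(labels)) labels <- sprintf("g%02d", seq_len(p))
  diag_w <- diag(S) + if (penalize_diagonal) lambda else 0

  if (p == 1L) {
    theta <- matrix(1 / diag_w, 1L, 1L, dimnames = list(labels, labels))
    return(new_glasso_fit_(theta, matrix(diag_w, 1L, 1L, dimnames = list(labels, labels)),
                           matrix(0, 0L, 1L), S, lambda, labels, 0L, TRUE,
                           penalize_diagonal, zero_eps))
  }

  if (!is.null(init)) {
    stopifnot(inherits(init, "glasso_fit"), ncol(init$W) == p)
    W <- unname(init$W)
    betas <- init$betas
  } else {
    W <- unname(S)
    betas <- matrix(0, p - 1L, p)
  }
  diag(W) <- diag_w
  Su <- unname(S)
  off <- which(row(Su) != col(Su))
  s_scale <- mean(abs(Su[off]))
  if (s_scale <= 0) s_scale <- 1  # diagonal S: fall back to absolute tolerance
  inner_tol <- tol / 100

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_outer)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      res <- lasso_cd_(W11, Su[idx, j], lambda, betas[, j], inner_tol, max_inner)
      betas[, j] <- res$beta
      w12 <- as.vector(W11 %*% res$beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)[off]) <= tol * s_scale) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("graphical lasso did not converge in ", max_outer,
            " outer cycles (lambda = ", signif(lambda, 4), ")", call. = FALSE)
  }
  dimnames(W) <- list(labels, labels)
  theta <- recover_precision(W, betas, zero_eps = zero_eps)
  new_glasso_fit_(theta, W, betas, S, lambda, labels, it, converged,
                  penalize_diagonal, zero_eps)
}

new_glasso_fit_ <- function(theta, W, betas, S, lambda, labels, outer_iters,
                            converged, penalize_diagonal, zero_eps) {
  structure(
    list(theta = theta, W = W, betas = betas, S = S, lambda = lambda,
         labels = labels, outer_iters = outer_iters, converged = converged,
         penalize_diagonal = penalize_diagonal, zero_eps = zero_eps),
    class = "glasso_fit"
  )
}

#' Recover the precision matrix from the glasso working state
#'
#' With column `j` partitioned last, the identity `W Theta = I` gives
#' `theta_22 = 1 / (w22 - t(w12) beta)` and `theta_12 = -beta * theta_22`,
#' where `beta` is the final lasso solution for that column and
#' `w12 = W11 beta`. The column-wise assembly is symmetrised by averaging
#' with its transpose; exact zeros of `beta` propagate to exact zeros of
#' `theta_12`, and off-diagonals below `zero_eps` are zeroed after
#' symmetrisation.
#'
#' @param W The converged covariance estimate (p x p).
#' @param betas `(p-1) x p` matrix whose column `j` is the lasso solution for
#'   target column `j`.
#' @param zero_eps Post-symmetrisation zero threshold (0 disables it).
#' @return The symmetric precision estimate `Theta` with `W`'s dimnames.
#' @export
recover_precision <- function(W, betas, zero_eps = 0) {
  check_symmetric(W, "W", tol = 1e-8)
  p <- ncol(W)
  if (p > 1L && (!is.matrix(betas) || nrow(betas) != p - 1L || ncol(betas) != p)) {
    stop_("`betas` must be a (p-1) x p matrix of per-column lasso solutions")
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    b <- if (p > 1L) betas[, j] else numeric(0)
    denom <- W[j, j] - sum(W[idx, j] * b)
    if (denom <= 0) {
      stop_("numerical failure recovering column ", j, ": w22 - t(w12) beta <= 0")
    }
    t22 <- 1 / denom
    theta[j, j] <- t22
    theta[idx, j] <- -b * t22
  }
  theta <- (theta + t(theta)) / 2
  if (zero_eps > 0) {
    small <- abs(theta) <= zero_eps & row(theta) != col(theta)
    theta[small] <- 0
  }
  dimnames(theta) <- dimnames(W)
  theta
}

#' Fit the graphical lasso along a penalty grid with warm starts
#'
#' Fits are computed in order of decreasing `lambda` (sparse to dense), each
#' warm-started from the previous solution, and returned in the order of the
#' input grid. Warm starting only affects speed, not the solutions.
#'
#' @param S Covariance matrix.
#' @param lambdas Vector of non-negative penalties (e.g. from
#'   [lambda_grid()]).
#' @inheritParams glasso_fit
#' @return A list of `glasso_fit` objects, one per `lambda`, input order.
#' @export
glasso_path <- function(S, lambdas, tol = 1e-4, max_outer = 100L, max_inner = 1000L,
                        penalize_diagonal = TRUE, zero_eps = 1e-8) {
  if (!is.numeric(lambdas) || length(lambdas) == 0L || any(lambdas < 0)) {
    stop_("`lambdas` must be a non-empty vector of non-negative penalties")
  }
  ord <- order(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  prev <- NULL
  for (k in ord) {
    prev <- glasso_fit(S, lambdas[k], tol = tol, max_outer = max_outer,
                       max_inner = max_inner, penalize_diagonal = penalize_diagonal,
                       zero_eps = zero_eps, init = prev)
    fits[[k]] <- prev
  }
  fits
}

#' Extract the gene network implied by a precision matrix
#'
#' Each non-zero off-diagonal entry of the precision matrix is a conditional
#' dependency between two genes, i.e. an undirected edge. An edge `(i, j)`
#' with `i < j` is reported when `|theta_ij| > zero_eps`.
#'
#' @param x A `glasso_fit` or a symmetric precision matrix.
#' @param labels Gene labels (taken from `x` when available).
#' @param zero_eps Magnitude below which an entry counts as zero.
#' @return A [gene_network()] over all `labels` (isolated genes included as
#'   nodes).
#' @export
extract_network <- function(x, labels = NULL, zero_eps = 1e-8) {
  if (inherits(x, "glasso_fit")) {
    theta <- x$theta
    if (is.null(labels)) labels <- x$labels
    if (missing(zero_eps)) zero_eps <- x$zero_eps
  } else {
    theta <- x
  }
  check_symmetric(theta, "theta", tol = 1e-8)
  p <- ncol(theta)
  if (is.null(labels)) {
    labels <- colnames(theta)
    if (is.null(labels)) labels <- sprintf("g%02d", seq_len(p))
  }
  if (length(labels) != p) stop_("`labels` length must match the matrix dimension")
  sel <- which(upper.tri(theta) & abs(theta) > zero_eps, arr.ind = TRUE)
  edges <- if (nrow(sel)) {
    data.frame(from = labels[sel[, 1L]], to = labels[sel[, 2L]],
               stringsAsFactors = FALSE)
  } else NULL
  gene_network(edges, nodes = labels)
}

#' @export
print.glasso_fit <- function(x, ...) {
  p <- length(x$labels)
  ne <- sum(abs(x$theta[upper.tri(x$theta)]) > x$zero_eps)
  cat(sprintf(
    "Graphical lasso fit: p = %d, lambda = %.6g (-log10 = %.3g)\n%d edge(s); %d outer cycle(s); %s\n",
    p, x$lambda, -log10(x$lambda), ne, x$outer_iters,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Tidy the edges of a graphical lasso fit
#'
#' @param x A `glasso_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated edge: `gene_a`, `gene_b`, and
#'   `theta` (the symmetrised precision entry; its negative, rescaled, is the
#'   partial correlation).
#' @method tidy glasso_fit
#' @export
tidy.glasso_fit <- function(x, ...) {
  sel <- which(upper.tri(x$theta) & abs(x$theta) > x$zero_eps, arr.ind = TRUE)
  tibble::tibble(
    gene_a = x$labels[sel[, 1L]],
    gene_b = x$labels[sel[, 2L]],
    theta = x$theta[sel]
  )
}

#' One-row summary of a graphical lasso fit
#'
#' @param x A `glasso_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `lambda`, `neglog10_lambda`, `n_edges`,
#'   `objective` (the penalised log-likelihood), `outer_iters`, `converged`.
#' @method glance glasso_fit
#' @export
glance.glasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    neglog10_lambda = -log10(x$lambda),
    n_edges = sum(abs(x$theta[upper.tri(x$theta)]) > x$zero_eps),
    objective = penalized_objective(x$theta, x$S, x$lambda),
    outer_iters = x$outer_iters,
    converged = x$converged
  )
}
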