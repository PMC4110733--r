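test_that("empirical covariance matches a brute-force summation oracle", {
  set.seed(1)
  v <- matrix(rnorm(12), 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  m <- expr_matrix(v, scale = "log2")
  S <- empirical_covariance(m, standardize = FALSE)
  # direct summation, denominator n
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    oracle[i, j] <- sum((v[i, ] - mean(v[i, ])) * (v[j, ] - mean(v[j, ]))) / 4
  }
  expect_equal(unname(S), oracle, tolerance = 1e-12)

  # standardized: unit diagonal, perfectly correlated rows -> 1
  v2 <- rbind(a = 1:4 + 0.5, b = 2 * (1:4) + 3)
  S2 <- empirical_covariance(expr_matrix(v2, scale = "log2"))
  expect_equal(unname(diag(S2)), c(1, 1))
  expect_equal(S2[1, 2], 1, tolerance = 1e-12)

  # constant row: zero row/column unstandardized, error standardized
  v3 <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  S3 <- empirical_covariance(v3, standardize = FALSE)
  expect_equal(unname(S3[1, ]), c(0, 0))
  expect_error(empirical_covariance(v3, standardize = TRUE), "zero-variance")
  expect_error(empirical_covariance(v3[, 1, drop = FALSE]), "2 samples")
})

test_that("penalized objective agrees with closed forms and an eigen oracle", {
  p <- 3
  expect_equal(penalized_objective(diag(p), diag(p), 0), -p)
  expect_equal(penalized_objective(diag(2), diag(2), 1), -4)  # -2 - 2
  set.seed(2)
  A <- matrix(rnorm(9), 3)
  theta <- crossprod(A) + diag(3)
  S <- crossprod(matrix(rnorm(9), 3)) / 3
  expect_equal(penalized_objective(theta, S, 0.3),
               objective_eigen(theta, S, 0.3), tolerance = 1e-10)
  expect_error(penalized_objective(matrix(c(1, 2, 2, 1), 2), diag(2), 0),
               "positive definite")
})

test_that("lasso coordinate descent solves scalar and shrinkage cases exactly", {
  # scalar closed form: soft(0.5, 0.1)/1.1
  b <- lasso_cd(matrix(1.1), 0.5, 0.1)
  expect_equal(b, soft_threshold(0.5, 0.1) / 1.1, tolerance = 1e-10)

  # full shrinkage fixed point
  W11 <- diag(c(1.2, 1.5, 1.1))
  expect_equal(lasso_cd(W11, c(0.3, -0.2, 0.1), lambda = 0.35), c(0, 0, 0))

  expect_error(lasso_cd(diag(c(1, -1)), c(0, 0), 0.1), "positive diagonal")
})

test_that("lasso CD satisfies the subgradient conditions and beats random candidates", {
  obj <- function(beta, W11, s12, lambda) {
    0.5 * sum(beta * (W11 %*% beta)) - sum(s12 * beta) + lambda * sum(abs(beta))
  }
  set.seed(3)
  for (rep in 1:10) {
    A <- matrix(rnorm(16), 4)
    W11 <- crossprod(A) + diag(4) * 0.5
    s12 <- rnorm(4)
    lambda <- runif(1, 0.05, 0.4)
    tol <- 1e-9
    beta <- lasso_cd(W11, s12, lambda, tol = tol, max_iter = 10000)
    # subgradient conditions of the stationarity equation
    grad <- as.vector(W11 %*% beta) - s12
    nz <- beta != 0
    if (any(nz)) expect_lt(max(abs(grad[nz] + lambda * sign(beta[nz]))), 10 * tol)
    if (any(!nz)) expect_lte(max(abs(grad[!nz])), lambda + 10 * tol)
    # no random feasible point does better
    cand <- matrix(rnorm(4 * 2000, sd = 2), nrow = 4)
    cand_obj <- apply(cand, 2, obj, W11 = W11, s12 = s12, lambda = lambda)
    expect_lte(obj(beta, W11, s12, lambda), min(cand_obj) + 1e-12)
    # and a quadratic-programming polish via optim from the solution's support
    polish <- optim(beta, obj, W11 = W11, s12 = s12, lambda = lambda,
                    method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
    expect_lte(obj(beta, W11, s12, lambda), polish$value + 1e-6)
  }
})

test_that("glasso reproduces the p=2 closed form and its network", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  fit <- glasso_fit(S, lambda = 0.1, tol = 1e-10)
  expect_true(fit$converged)
  # W = [[1.1, .4], [.4, 1.1]]; theta = [[1.0476, -0.38095], ...]
  expect_equal(unname(fit$W), matrix(c(1.1, 0.4, 0.4, 1.1), 2), tolerance = 1e-8)
  beta <- soft_threshold(0.5, 0.1) / 1.1
  t22 <- 1 / (1.1 - 0.4 * beta)
  expect_equal(unname(fit$theta), matrix(c(t22, -beta * t22, -beta * t22, t22), 2),
               tolerance = 1e-8)
  expect_equal(round(fit$theta[1, 2], 5), -0.38095)

  net <- extract_network(fit)
  expect_equal(as.data.frame(net), data.frame(from = "A", to = "B"),
               ignore_attr = TRUE)

  # lambda >= |s12| kills the edge: theta diagonal
  fit2 <- glasso_fit(S, lambda = 0.6)
  expect_equal(fit2$theta[1, 2], 0)
  expect_equal(n_edges(extract_network(fit2)), 0L)
})

test_that("unpenalized glasso recovers the matrix inverse", {
  set.seed(4)
  A <- matrix(rnorm(9), 3)
  S <- crossprod(A) / 3 + diag(3) * 0.5
  dimnames(S) <- list(letters[1:3], letters[1:3])
  fit <- glasso_fit(S, lambda = 0, tol = 1e-10, zero_eps = 0)
  expect_lt(max(abs(fit$theta - solve(S))), 1e-5)
})

test_that("converged fits satisfy W theta = I and the fixed-diagonal rule", {
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(rnorm(25), 5)
    S <- crossprod(A) / 5 + diag(5) * 0.3
    lambda <- runif(1, 0.02, 0.3)
    fit <- glasso_fit(S, lambda, tol = 1e-9)
    expect_true(fit$converged)
    # diagonal of W fixed at diag(S) + lambda throughout
    expect_equal(unname(diag(fit$W)), unname(diag(S)) + lambda, tolerance = 1e-12)
    # recovery identity (pre-zeroing theta, so use zero_eps = 0 recovery)
    theta_raw <- recover_precision(fit$W, fit$betas, zero_eps = 0)
    expect_lt(max(abs(fit$W %*% theta_raw - diag(5))), 1e-6)
  }
})

test_that("recover_precision handles the diagonal case and rejects bad denominators", {
  W <- diag(c(2, 4), 2)
  theta <- recover_precision(W, matrix(0, 1, 2))
  expect_equal(unname(theta), diag(c(0.5, 0.25), 2))
  Wbad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(recover_precision(Wbad, matrix(2, 1, 2)), "numerical failure")
})

test_that("the estimated network is permutation-equivariant", {
  set.seed(6)
  A <- matrix(rnorm(36), 6)
  S <- crossprod(A) / 6 + diag(6) * 0.4
  dimnames(S) <- list(letters[1:6], letters[1:6])
  fit <- glasso_fit(S, 0.1, tol = 1e-8)
  perm <- sample(6)
  Sp <- S[perm, perm]
  fitp <- glasso_fit(Sp, 0.1, tol = 1e-8)
  expect_equal(fitp$theta, fit$theta[perm, perm], tolerance = 1e-6)
  expect_equal(as.data.frame(extract_network(fitp)),
               as.data.frame(extract_network(fit)))
})

test_that("large penalties empty the network; the lattice maps lambdas correctly", {
  set.seed(7)
  A <- matrix(rnorm(20), 4)
  S <- crossprod(A) / 5
  lam_max <- max(abs(S[row(S) != col(S)]))
  fit <- glasso_fit(S, lam_max * 1.0001)
  expect_equal(n_edges(extract_network(fit)), 0L)

  expect_equal(lambda_grid(0), 1)
  expect_equal(lambda_grid(1.2), 10^-1.2)
  grid <- seq(0.80, 1.78, length.out = 10)
  expect_true(all(diff(lambda_grid(grid)) < 0))
})

test_that("warm-started paths match cold fits", {
  set.seed(8)
  A <- matrix(rnorm(49), 7)
  S <- crossprod(A) / 7 + diag(7) * 0.2
  lams <- lambda_grid(c(0.5, 1, 1.5))
  path <- glasso_path(S, lams, tol = 1e-8)
  for (k in seq_along(lams)) {
    cold <- glasso_fit(S, lams[k], tol = 1e-8)
    expect_equal(path[[k]]$theta, cold$theta, tolerance = 1e-5)
    expect_equal(as.data.frame(extract_network(path[[k]])),
                 as.data.frame(extract_network(cold)))
  }
})

test_that("tidy and glance expose edges and fit summaries", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  fit <- glasso_fit(S, 0.1)
  td <- tidy(fit)
  expect_equal(td$gene_a, "A")
  expect_equal(td$gene_b, "B")
  expect_lt(td$theta, 0)
  gl <- glance(fit)
  expect_equal(gl$n_edges, 1L)
  expect_true(gl$converged)
  expect_equal(gl$lambda, 0.1)
  expect_equal(gl$objective, penalized_objective(fit$theta, S, 0.1))
})
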