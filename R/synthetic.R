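#' Random network topology, optionally with a hub
#'
#' Draws a simple undirected graph with exactly `m` edges, uniformly over
#' all `m`-edge sets on `p` nodes. With `hub_degree` set, the first node is
#' forced to be a hub: it first receives exactly `hub_degree` uniformly
#' chosen incident edges, and the remaining `m - hub_degree` edges are drawn
#' uniformly among the non-hub node pairs. This emulates gold-standard
#' regulatory networks organised around one highly connected regulator
#' (e.g. a 16-gene network of 28 interactions with a degree-12 MYC hub).
#'
#' @param p Number of nodes.
#' @param m Number of edges, `0 <= m <= p(p-1)/2`.
#' @param hub_degree Optional exact degree of the first node; requires
#'   `hub_degree <= min(p - 1, m)` and `m - hub_degree <= (p-1)(p-2)/2`.
#' @param labels Node labels (default `g01`, `g02`, ...; the hub is
#'   `labels[1]`).
#' @param seed Optional integer for a reproducible draw.
#' @return A [gene_network()] with exactly `m` edges over all `p` nodes.
#' @examples
#' make_topology(16, 28, hub_degree = 12, seed = 1)
#' @export
make_topology <- function(p, m, hub_degree = NULL, labels = NULL, seed = NULL) {
  p <- check_count(p, "p", min = 1L)
  m <- check_count(m, "m")
  N <- p * (p - 1L) / 2L
  if (m > N) stop_(sprintf("m = %d exceeds the %d possible edges on %d nodes", m, N, p))
  if (is.null(labels)) labels <- sprintf("g%02d", seq_len(p))
  if (length(labels) != p || anyDuplicated(labels)) {
    stop_("`labels` must be ", p, " unique labels")
  }
  with_seed_(seed, {
    if (is.null(hub_degree)) {
      pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
      sel <- pairs[random_edge_indices_(N, m), , drop = FALSE]
      a <- labels[sel[, 1L]]
      b <- labels[sel[, 2L]]
    } else {
      hub_degree <- check_count(hub_degree, "hub_degree")
      if (hub_degree > min(p - 1L, m)) {
        stop_("`hub_degree` cannot exceed min(p - 1, m)")
      }
      rest_max <- (p - 1L) * (p - 2L) / 2L
      if (m - hub_degree > rest_max) {
        stop_(sprintf("infeasible: %d non-hub edges requested but only %d non-hub pairs exist",
                      m - hub_degree, rest_max))
      }
      nb <- sample(seq_len(p)[-1L], hub_degree)
      a <- labels[rep(1L, hub_degree)]
      b <- labels[nb]
      if (m - hub_degree > 0L) {
        sub <- diag(p - 1L)
        pairs <- which(upper.tri(sub), arr.ind = TRUE) + 1L  # indices into 2..p
        sel <- pairs[random_edge_indices_(rest_max, m - hub_degree), , drop = FALSE]
        a <- c(a, labels[sel[, 1L]])
        b <- c(b, labels[sel[, 2L]])
      }
    }
    gene_network(data.frame(from = a, to = b, stringsAsFactors = FALSE),
                 nodes = labels)
  })
}

# uniform sample of m of N possible edge slots; shared by make_topology,
# random_network and the null simulation so they draw from one model
random_edge_indices_ <- function(N, m) {
  sample.int(N, m, replace = FALSE)
}

#' Build a sparse precision matrix supported on a topology
#'
#' Off-diagonal `(i, j)` is set to `rho` with a random sign when `{i, j}` is
#' an edge of `g` and to exact zero otherwise; the diagonal is the row-wise
#' sum of absolute off-diagonals plus `delta`, making the matrix strictly
#' diagonally dominant and hence positive definite with smallest eigenvalue
#' at least `delta` (Gershgorin). The support therefore equals the edge set
#' exactly — no eigenvalue shifting that could leak mass into non-edges.
#'
#' @param g A gene network (the true conditional-dependence structure).
#' @param rho Off-diagonal magnitude (non-zero).
#' @param delta Diagonal dominance margin (> 0).
#' @param seed Optional integer seed for the random signs.
#' @return A symmetric positive-definite matrix with the network's node
#'   labels as dimnames.
#' @export
topology_to_precision <- function(g, rho, delta, seed = NULL) {
  g <- as_network_(g)
  if (!is.numeric(rho) || length(rho) != 1L || rho == 0) stop_("`rho` must be a single non-zero number")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) stop_("`delta` must be > 0")
  nodes <- network_nodes(g)
  p <- length(nodes)
  theta <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(g) > 0L) {
    i <- match(g$from, nodes)
    j <- match(g$to, nodes)
    signs <- with_seed_(seed, 2 * rbinom(nrow(g), 1L, 0.5) - 1)
    vals <- signs * abs(rho)
    theta[cbind(i, j)] <- vals
    theta[cbind(j, i)] <- vals
  }
  diag(theta) <- rowSums(abs(theta)) + delta
  theta
}

#' Synthetic Gaussian graphical model for a gene network
#'
#' Bundles a true network topology with a sparse precision matrix supported
#' on it ([topology_to_precision()]). Expression sampled from the model
#' ([sample_expression()]) is zero-mean multivariate Gaussian with
#' covariance `solve(theta)` — the data-generating assumption under which
#' the graphical lasso recovers the network.
#'
#' @param network The true gene network.
#' @param rho Off-diagonal precision magnitude (default 0.3, a moderate
#'   partial association).
#' @param delta Diagonal dominance margin (default 0.6).
#' @param seed Optional seed for the edge-sign draw.
#' @return An object of class `grn_model`: list with `network`, `theta`,
#'   `rho`, `delta`, `seed`.
#' @examples
#' mod <- synthetic_model(make_topology(8, 8, seed = 1), rho = 0.4, seed = 2)
#' x <- sample_expression(mod, n = 100, seed = 3)
#' @export
synthetic_model <- function(network, rho = 0.3, delta = 0.6, seed = NULL) {
  network <- as_network_(network, "network")
  theta <- topology_to_precision(network, rho = rho, delta = delta, seed = seed)
  structure(list(network = network, theta = theta, rho = rho, delta = delta,
                 seed = seed),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat(sprintf("Synthetic GGM: %d genes, %d true edges (rho = %g, delta = %g)\n",
              length(network_nodes(x$network)), n_edges(x$network), x$rho, x$delta))
  invisible(x)
}

#' Sample expression data from a synthetic model
#'
#' Draws `n` independent observations from the zero-mean multivariate
#' Gaussian with covariance `solve(theta)` and arranges them genes-by-samples.
#' The values are interpreted as already-normalised log2-scale expression.
#'
#' @param model A [synthetic_model()] (or a bare positive-definite precision
#'   matrix with dimnames).
#' @param n Number of samples (>= 2).
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   matrix on repeat.
#' @return A log2-scale expression matrix, `p` genes x `n` samples.
#' @export
sample_expression <- function(model, n, seed = NULL) {
  theta <- if (inherits(model, "grn_model")) model$theta else model
  check_symmetric(theta, "theta", tol = 1e-8)
  n <- check_count(n, "n", min = 2L)
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch)) stop_("the model's precision matrix must be positive definite")
  sigma <- chol2inv(ch)
  p <- ncol(theta)
  genes <- colnames(theta)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(p))
  x <- with_seed_(seed, MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma))
  v <- t(matrix(x, nrow = n))
  dimnames(v) <- list(genes, sprintf("s%02d", seq_len(n)))
  expr_matrix(v, scale = "log2")
}

#' Simulate a paired before/after expression study
#'
#' Generates a baseline (pre-treatment) matrix of positive linear-scale
#' intensities — per-gene levels drawn log-uniformly over a typical
#' microarray intensity range — and an after-treatment matrix equal to the
#' baseline scaled by the per-gene fold-change, both with multiplicative
#' log-normal noise. A fixture for testing preprocessing and fold-change
#' recovery: with `noise_sd = 0`, [compute_fold_changes()] returns the true
#' fold-changes exactly.
#'
#' @param gene_ids Gene labels.
#' @param fold_changes Positive per-gene linear fold-changes (recycled to
#'   the number of genes only if scalar).
#' @param n_samples Samples per condition.
#' @param noise_sd Standard deviation of the log-normal noise on the natural
#'   log scale (>= 0).
#' @param seed Optional integer seed.
#' @return A list with linear-scale expression matrices `before` and
#'   `after`.
#' @export
make_paired_study <- function(gene_ids, fold_changes, n_samples, noise_sd = 0.1,
                              seed = NULL) {
  gene_ids <- as.character(gene_ids)
  p <- length(gene_ids)
  if (p == 0L || anyDuplicated(gene_ids)) stop_("`gene_ids` must be unique and non-empty")
  if (length(fold_changes) == 1L) fold_changes <- rep(fold_changes, p)
  if (length(fold_changes) != p) stop_("`fold_changes` must have one value per gene")
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
    stop_("fold-changes must be positive and finite")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_("`noise_sd` must be >= 0")
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  with_seed_(seed, {
    base <- 2^runif(p, 6, 12)  # typical log2 intensity range
    noise <- function() {
      if (noise_sd == 0) 1 else exp(matrix(rnorm(p * n_samples, 0, noise_sd), p))
    }
    before <- base * noise()
    after <- (base * fold_changes) * noise()
    dn <- list(gene_ids, sprintf("s%02d", seq_len(n_samples)))
    before <- matrix(before, p, n_samples, dimnames = dn)
    after <- matrix(after, p, n_samples, dimnames = dn)
    list(before = expr_matrix(before, "linear"),
         after = expr_matrix(after, "linear"))
  })
}

#' Synthetic 16-gene radiation-response network fixture
#'
#' A synthetic stand-in for a curated radiation-response interaction
#' network: 16 radio-responsive genes, 28 edges, with MYC as a degree-12
#' hub. Only the gene labels and the summary statistics (node count, edge
#' count, hub degree) are taken from the biology; the edge list itself is a
#' seeded random draw from [make_topology()] and does not claim any
#' specific curated interaction.
#'
#' @param seed Seed for the topology draw (fixed default so the fixture is
#'   stable across sessions).
#' @return A [gene_network()] with 16 nodes and 28 edges, MYC degree 12.
#' @export
synthetic_radiation_network <- function(seed = 20140528) {
  labels <- c("MYC", "ATF3", "BAX", "BBC3", "BIRC5", "CCNB1", "CCNG1",
              "CDKN1A", "DDB2", "EI24", "GADD45A", "MDM2", "MMP9", "PCNA",
              "PLK3", "TNFRSF10B")
  make_topology(16L, 28L, hub_degree = 12L, labels = labels, seed = seed)
}
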