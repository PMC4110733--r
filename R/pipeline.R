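#' Regularisation-path sweep against a gold-standard network
#'
#' Runs the full evaluation for each penalty on a `-log10(lambda)` grid:
#' estimate the network from the expression matrix with the graphical lasso
#' (warm-started along the path), score it against the gold standard
#' ([compare_networks()]), and attach a Monte-Carlo p-value from the
#' random-network null ([simulate_null()]) with `edges_a = |gold|`,
#' `edges_b = |estimate|` and the row's own f-score as the observed value.
#' Random networks are drawn on the union of the gold-standard nodes and the
#' expression genes. Identical inputs and seed give an identical table.
#'
#' @param expr Expression matrix (samples in columns; typically log2-scale,
#'   quantile-normalized, restricted to the genes of interest).
#' @param gold Gold-standard gene network.
#' @param neglog10_grid Grid of `-log10(lambda)` values.
#' @param standardize Use the correlation matrix (see
#'   [empirical_covariance()]).
#' @param tol,max_outer,zero_eps Graphical lasso controls ([glasso_fit()]).
#' @param null_reps Monte-Carlo pairs per row (default 10,000).
#' @param seed Optional integer seed driving all per-row null simulations.
#' @return A tibble of class `grn_sweep`, one row per grid value:
#'   `neglog10_lambda`, `lambda`, `tp`, `fn`, `fp`, `n_edges` (= tp + fp),
#'   `precision`, `recall`, `fscore`, `pvalue`, `converged`, `outer_iters`.
#' @examples
#' net <- make_topology(8, 8, seed = 1)
#' mod <- synthetic_model(net, rho = 0.4, seed = 2)
#' x <- sample_expression(mod, n = 200, seed = 3)
#' run_sweep(x, net, c(0.5, 1, 1.5), null_reps = 200, seed = 4)
#' @export
run_sweep <- function(expr, gold, neglog10_grid, standardize = TRUE,
                      tol = 1e-4, max_outer = 100L, zero_eps = 1e-8,
                      null_reps = 10000L, seed = NULL) {
  expr <- as_expr_(expr, "expr")
  gold <- as_network_(gold, "gold")
  if (!is.numeric(neglog10_grid) || length(neglog10_grid) == 0L) {
    stop_("`neglog10_grid` must be a non-empty numeric vector")
  }
  S <- empirical_covariance(expr, standardize = standardize)
  lams <- lambda_grid(neglog10_grid)
  fits <- glasso_path(S, lams, tol = tol, max_outer = max_outer,
                      zero_eps = zero_eps)
  n_nodes <- length(union(network_nodes(gold), expr_genes(expr)))
  rows <- with_seed_(seed, {
    row_seeds <- sample.int(.Machine$integer.max, length(fits))
    lapply(seq_along(fits), function(k) {
      fit <- fits[[k]]
      est <- extract_network(fit)
      cmp <- compare_networks(gold, est)
      nr <- simulate_null(n_nodes, n_edges(gold), n_edges(est),
                          f_obs = cmp$fscore, reps = null_reps,
                          seed = row_seeds[k])
      tibble::tibble(
        neglog10_lambda = neglog10_grid[k], lambda = lams[k],
        tp = cmp$tp, fn = cmp$fn, fp = cmp$fp, n_edges = cmp$tp + cmp$fp,
        precision = cmp$precision, recall = cmp$recall, fscore = cmp$fscore,
        pvalue = nr$pvalue, converged = fit$converged,
        outer_iters = fit$outer_iters
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grn_sweep", class(out))
  attr(out, "n_nodes") <- n_nodes
  attr(out, "null_reps") <- null_reps
  out
}

#' Compare networks estimated from two expression datasets
#'
#' For each pair of penalties `(grid_a[k], grid_b[k])`, estimates one
#' network per dataset on their shared genes, counts the common edges,
#' computes the symmetric f-score ([fscore_between()]), and attaches a
#' random-network null p-value with the two estimated edge counts. High
#' f-scores between two independent datasets point to reproducible — and
#' possibly uncurated — gene–gene dependencies.
#'
#' @param expr_a,expr_b Expression matrices; their gene sets are intersected
#'   (an empty intersection is an error).
#' @param grid_a,grid_b Equal-length `-log10(lambda)` grids, paired row by
#'   row.
#' @inheritParams run_sweep
#' @return A tibble of class `grn_cross`, one row per pair:
#'   `neglog10_lambda_a`, `neglog10_lambda_b`, `edges_a`, `edges_b`,
#'   `common_edges`, `fscore`, `pvalue`.
#' @export
run_cross_comparison <- function(expr_a, expr_b, grid_a, grid_b,
                                 standardize = TRUE, tol = 1e-4,
                                 max_outer = 100L, zero_eps = 1e-8,
                                 null_reps = 10000L, seed = NULL) {
  expr_a <- as_expr_(expr_a, "expr_a")
  expr_b <- as_expr_(expr_b, "expr_b")
  if (length(grid_a) != length(grid_b) || length(grid_a) == 0L) {
    stop_("`grid_a` and `grid_b` must be non-empty and of equal length")
  }
  genes <- intersect(expr_genes(expr_a), expr_genes(expr_b))
  if (length(genes) == 0L) stop_("the two datasets share no genes")
  if (length(genes) < length(expr_genes(expr_a)) ||
      length(genes) < length(expr_genes(expr_b))) {
    message("restricting both datasets to ", length(genes), " shared gene(s)")
  }
  ea <- extract_submatrix(expr_a, genes = genes)
  eb <- extract_submatrix(expr_b, genes = genes)
  Sa <- empirical_covariance(ea, standardize = standardize)
  Sb <- empirical_covariance(eb, standardize = standardize)
  fits_a <- glasso_path(Sa, lambda_grid(grid_a), tol = tol,
                        max_outer = max_outer, zero_eps = zero_eps)
  fits_b <- glasso_path(Sb, lambda_grid(grid_b), tol = tol,
                        max_outer = max_outer, zero_eps = zero_eps)
  rows <- with_seed_(seed, {
    row_seeds <- sample.int(.Machine$integer.max, length(fits_a))
    lapply(seq_along(fits_a), function(k) {
      na <- extract_network(fits_a[[k]])
      nb <- extract_network(fits_b[[k]])
      common <- length(intersect(edge_keys_(na), edge_keys_(nb)))
      f <- fscore_between(na, nb)
      nr <- simulate_null(length(genes), n_edges(na), n_edges(nb),
                          f_obs = f, reps = null_reps, seed = row_seeds[k])
      tibble::tibble(
        neglog10_lambda_a = grid_a[k], neglog10_lambda_b = grid_b[k],
        edges_a = n_edges(na), edges_b = n_edges(nb),
        common_edges = common, fscore = f, pvalue = nr$pvalue
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grn_cross", class(out))
  attr(out, "n_nodes") <- length(genes)
  attr(out, "null_reps") <- null_reps
  out
}

#' Write a sweep / cross-comparison report as TSV
#'
#' Emits the rows with the ratio metrics (`precision`, `recall`, `fscore`,
#' `pvalue`) rounded to two decimals for display — the conventional table
#' layout — alongside `*_full` companion columns at full precision so the
#' file loses nothing. An empty input writes a header-only file.
#'
#' @param rows A `grn_sweep` or `grn_cross` tibble (any data frame works;
#'   only the metric columns present are rounded).
#' @param path Output file path.
#' @return The input rows, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows)) stop_("`rows` must be a data frame")
  out <- as.data.frame(rows)
  for (col in intersect(c("precision", "recall", "fscore", "pvalue"), names(out))) {
    out[[paste0(col, "_full")]] <- out[[col]]
    out[[col]] <- round(out[[col]], 2)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(rows)
}
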