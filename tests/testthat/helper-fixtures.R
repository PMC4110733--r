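# shared fixtures built in code

# small deterministic expression matrix
toy_expr <- function(scale = "linear") {
  v <- matrix(c(8, 1, 2, 4, 16, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expr_matrix(v, scale = scale)
}

# build two networks on `n_nodes` labelled nodes with prescribed overlap
# counts: tp shared edges, fn gold-only, fp estimate-only
networks_with_counts <- function(tp, fp, fn, n_nodes = 16) {
  stopifnot(tp + fp + fn <= choose(n_nodes, 2))
  labels <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(labels, 2))
  shared <- pairs[seq_len(tp), , drop = FALSE]
  gold_only <- pairs[tp + seq_len(fn), , drop = FALSE]
  est_only <- pairs[tp + fn + seq_len(fp), , drop = FALSE]
  list(
    gold = gene_network(rbind(shared, gold_only), nodes = labels),
    est = gene_network(rbind(shared, est_only), nodes = labels)
  )
}

# brute-force penalised objective via eigen-decomposition (independent of
# the chol-based implementation)
objective_eigen <- function(theta, S, lambda) {
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > 0))
  sum(log(ev)) - sum(diag(S %*% theta)) - lambda * sum(abs(theta))
}
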