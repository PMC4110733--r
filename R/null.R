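#' Uniform random network with a fixed edge count
#'
#' Draws exactly `n_edges` edges uniformly without replacement from the
#' `n_nodes * (n_nodes - 1) / 2` possible undirected pairs — the null model
#' for "two networks of these sizes share this many edges by chance".
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges.
#' @param labels Optional node labels (default `g01`, ...).
#' @param seed Optional integer seed.
#' @return A [gene_network()].
#' @export
random_network <- function(n_nodes, n_edges, labels = NULL, seed = NULL) {
  with_seed_(seed, make_topology(n_nodes, n_edges, labels = labels))
}

#' Monte-Carlo null distribution of the f-score between random networks
#'
#' Repeatedly draws an independent pair of uniform random networks on
#' `n_nodes` nodes with exactly `edges_a` and `edges_b` edges, computes the
#' symmetric f-score `2 |common| / (edges_a + edges_b)` for each pair, and
#' reports the fraction of pairs whose f-score *strictly exceeds* the
#' observed value `f_obs`. That fraction is the Monte-Carlo p-value of an
#' observed network agreement.
#'
#' Strictness matters: attainable f-scores are a lattice of values
#' `2c / (edges_a + edges_b)`, and the observed f-score is typically on the
#' lattice, so counting ties would change the p-value materially. Pass
#' `f_obs` at full precision (e.g. `2 * 12 / (27 + 30)`), not rounded to the
#' two decimals a report displays — with a rounded-down threshold the strict
#' count silently includes the observed overlap itself.
#'
#' @param n_nodes Nodes in each random network.
#' @param edges_a,edges_b Edge counts of the two networks.
#' @param f_obs Observed f-score to be exceeded.
#' @param reps Number of Monte-Carlo pairs (default 10,000).
#' @param seed Optional integer seed.
#' @return A one-row tibble of class `null_result`: `f_obs`, `exceed_count`,
#'   `reps`, `pvalue = exceed_count / reps`.
#' @examples
#' simulate_null(16, 28, 27, f_obs = 2 * 11 / (28 + 27), reps = 2000, seed = 1)
#' @export
simulate_null <- function(n_nodes, edges_a, edges_b, f_obs, reps = 10000L,
                          seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  edges_a <- check_count(edges_a, "edges_a")
  edges_b <- check_count(edges_b, "edges_b")
  reps <- check_count(reps, "reps", min = 1L)
  if (!is.numeric(f_obs) || length(f_obs) != 1L || is.na(f_obs)) {
    stop_("`f_obs` must be a single number")
  }
  N <- n_nodes * (n_nodes - 1L) / 2L
  if (edges_a > N || edges_b > N) {
    stop_(sprintf("edge counts must be <= %d possible edges on %d nodes", N, n_nodes))
  }
  tot <- edges_a + edges_b
  exceed <- with_seed_(seed, {
    cnt <- 0L
    for (r in seq_len(reps)) {
      a <- random_edge_indices_(N, edges_a)
      b <- random_edge_indices_(N, edges_b)
      cm <- length(intersect(a, b))
      f <- if (tot > 0L) 2 * cm / tot else 0
      if (f > f_obs) cnt <- cnt + 1L
    }
    cnt
  })
  out <- tibble::tibble(f_obs = f_obs, exceed_count = exceed, reps = reps,
                        pvalue = exceed / reps)
  class(out) <- c("null_result", class(out))
  out
}

#' Exact tail probability of the random-network f-score null
#'
#' For two independent uniform fixed-size edge sets on the same node set,
#' the overlap `C` is hypergeometric: `C ~ Hypergeometric(N, edges_a,
#' edges_b)` with `N = n_nodes (n_nodes - 1) / 2` possible edges. The exact
#' counterpart of [simulate_null()] is therefore
#' `P(2 C / (edges_a + edges_b) > f_obs)`, strict inequality evaluated on
#' the same floating-point lattice as the simulation.
#'
#' @inheritParams simulate_null
#' @return The exact tail probability (a single number).
#' @examples
#' exact_overlap_pvalue(16, 28, 27, f_obs = 2 * 11 / (28 + 27))
#' @export
exact_overlap_pvalue <- function(n_nodes, edges_a, edges_b, f_obs) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  edges_a <- check_count(edges_a, "edges_a")
  edges_b <- check_count(edges_b, "edges_b")
  N <- n_nodes * (n_nodes - 1L) / 2L
  if (edges_a > N || edges_b > N) {
    stop_(sprintf("edge counts must be <= %d possible edges on %d nodes", N, n_nodes))
  }
  tot <- edges_a + edges_b
  if (tot == 0L) return(as.numeric(0 > f_obs))
  cs <- 0:min(edges_a, edges_b)
  exceeds <- (2 * cs / tot) > f_obs  # same expression as the simulation
  sum(dhyper(cs[exceeds], edges_a, N - edges_a, edges_b))
}
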