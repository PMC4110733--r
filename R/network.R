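#' Undirected gene networks
#'
#' A gene network is a simple undirected graph over gene labels: edges are
#' unordered label pairs, self-loops are forbidden, duplicates collapse.
#' It is stored as an edge tibble with columns `from`/`to` in canonical order
#' (`from < to` lexicographically, rows sorted), plus a node set carried in
#' the `"nodes"` attribute so isolated genes are representable.
#'
#' @param edges `NULL` (no edges) or a two-column data frame / matrix /
#'   character pair giving one edge per row; extra columns are ignored.
#' @param nodes Optional character vector of node labels to include beyond
#'   the edge endpoints (isolated nodes).
#' @param self_loops What to do with a self-loop row: `"error"` (default) or
#'   `"drop"` with a warning.
#' @return A tibble of class `gene_network` with columns `from`, `to`.
#' @examples
#' g <- gene_network(data.frame(a = c("MYC", "BAX"), b = c("PCNA", "MYC")))
#' network_nodes(g)
#' n_edges(g)
#' @export
gene_network <- function(edges = NULL, nodes = NULL, self_loops = c("error", "drop")) {
  self_loops <- match.arg(self_loops)
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (is.matrix(edges) && nrow(edges) == 0L)) {
    a <- b <- character(0)
  } else {
    if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.character(edges) && length(edges) == 2L) {
      edges <- data.frame(from = edges[1L], to = edges[2L])
    }
    if (!is.data.frame(edges) || ncol(edges) < 2L) {
      stop_("`edges` must have at least two columns (edge endpoints)")
    }
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b))) {
      stop_("edge endpoints must be non-empty gene labels")
    }
    loops <- a == b
    if (any(loops)) {
      if (self_loops == "error") {
        stop_("self-loop(s) on: ", paste(unique(a[loops]), collapse = ", "))
      }
      warning("dropping ", sum(loops), " self-loop(s)", call. = FALSE)
      a <- a[!loops]; b <- b[!loops]
    }
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  ord <- order(lo[keep], hi[keep])
  out <- tibble::new_tibble(
    list(from = lo[keep][ord], to = hi[keep][ord]),
    nrow = sum(keep), class = "gene_network"
  )
  attr(out, "nodes") <- sort(unique(c(as.character(nodes), lo, hi)))
  out
}

as_network_ <- function(g, arg = "g") {
  if (!inherits(g, "gene_network")) {
    stop_(sprintf("`%s` must be a gene_network", arg))
  }
  g
}

#' @rdname gene_network
#' @param g A gene network.
#' @export
network_nodes <- function(g) attr(as_network_(g), "nodes")

#' @rdname gene_network
#' @export
n_edges <- function(g) nrow(as_network_(g))

edge_keys_ <- function(g) {
  if (nrow(g) == 0L) character(0) else paste(g$from, g$to, sep = "\r")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("# Gene network: %d nodes, %d edges\n",
              length(attr(x, "nodes")), nrow(x)))
  NextMethod()
}

#' Read / write gene networks as edge-list files
#'
#' The native format is a two-column TSV with header `gene_a<TAB>gene_b`,
#' one undirected edge per row. Files ending in `.sif` (or read with
#' `format = "sif"`) are parsed as simple interaction format — headerless
#' `source<TAB>relation<TAB>target` — with the relation column ignored.
#' On read, reciprocal/duplicate rows collapse to one undirected edge.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"sif"`.
#' @param self_loops Passed to [gene_network()]: `"error"` (default) or
#'   `"drop"` with a warning.
#' @return [read_network()] a gene network; [write_network()] the input,
#'   invisibly. [write_network()] emits edges in canonical lexicographic
#'   order, so write/read round-trips are exact.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif"),
                         self_loops = c("error", "drop")) {
  format <- match.arg(format)
  self_loops <- match.arg(self_loops)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "sif") {
    df <- readr::read_tsv(path, col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (ncol(df) < 3L) stop_("SIF file needs 3 columns: source, relation, target")
    edges <- df[, c(1L, 3L)]
  } else {
    edges <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
    if (ncol(edges) < 2L) stop_("edge-list TSV needs 2 columns")
  }
  gene_network(edges, self_loops = self_loops)
}

#' @rdname read_network
#' @param g A gene network.
#' @export
write_network <- function(g, path) {
  g <- as_network_(g)
  df <- data.frame(gene_a = g$from, gene_b = g$to, stringsAsFactors = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(g)
}

#' Collapse a directed / signed edge list to an undirected network
#'
#' Curated pathway databases export interactions with directions and signs
#' (activation, inhibition, unspecified). For comparison with the undirected
#' conditional-dependence networks estimated here, direction and sign are
#' discarded: reciprocal and parallel edges collapse to a single undirected
#' edge and self-loops are dropped with a warning.
#'
#' @param edges A data frame or matrix whose first two columns are source and
#'   target labels; any further columns (relation type, sign, direction) are
#'   ignored.
#' @param nodes Optional extra (isolated) node labels.
#' @return A gene network.
#' @examples
#' to_undirected(data.frame(src = c("MYC", "PCNA", "MYC"),
#'                          tgt = c("PCNA", "MYC", "BAX"),
#'                          sign = c("+", "-", "?")))
#' @export
to_undirected <- function(edges, nodes = NULL) {
  gene_network(edges, nodes = nodes, self_loops = "drop")
}

#' Precision / recall / f-score between metric counts
#'
#' Zero-denominator convention: a ratio with an empty denominator is 0
#' (keeps sweep tables total when either network is empty).
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative edge
#'   counts.
#' @return A one-row tibble of class `network_comparison` with columns `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `fscore`.
#' @export
comparison_metrics <- function(tp, fp, fn) {
  tp <- check_count(tp, "tp"); fp <- check_count(fp, "fp"); fn <- check_count(fn, "fn")
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  out <- tibble::tibble(tp = tp, fp = fp, fn = fn,
                        precision = precision, recall = recall, fscore = fscore)
  class(out) <- c("network_comparison", class(out))
  out
}

#' Compare an estimated network against a gold standard
#'
#' Edges are compared as unordered label pairs over the union of the two
#' node sets (the networks need not list identical nodes). A true positive
#' is an edge present in both; a false positive is estimated but not in the
#' gold standard; a false negative is in the gold standard but not
#' estimated. Precision = TP/(TP+FP), Recall = TP/(TP+FN), f-score is their
#' harmonic mean (zero-denominator convention as in [comparison_metrics()]).
#'
#' @param gold The gold-standard gene network.
#' @param est The estimated gene network.
#' @return A one-row `network_comparison` tibble.
#' @examples
#' gold <- gene_network(data.frame(a = c("A", "A"), b = c("B", "C")))
#' est <- gene_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' compare_networks(gold, est)
#' @export
compare_networks <- function(gold, est) {
  gold <- as_network_(gold, "gold")
  est <- as_network_(est, "est")
  kg <- edge_keys_(gold)
  ke <- edge_keys_(est)
  tp <- length(intersect(kg, ke))
  comparison_metrics(tp = tp, fp = length(ke) - tp, fn = length(kg) - tp)
}

#' Symmetric f-score between two networks
#'
#' `2 * |common edges| / (|a| + |b|)`: the f-score of either network scored
#' against the other as gold standard, symmetric in its arguments. Two empty
#' networks score 0 by convention.
#'
#' @param a,b Gene networks.
#' @return A single number in `[0, 1]`.
#' @export
fscore_between <- function(a, b) {
  a <- as_network_(a, "a")
  b <- as_network_(b, "b")
  na <- n_edges(a); nb <- n_edges(b)
  if (na + nb == 0L) return(0)
  2 * length(intersect(edge_keys_(a), edge_keys_(b))) / (na + nb)
}
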