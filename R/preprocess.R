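#' Log2-transform an expression matrix
#'
#' Replaces every linear-scale intensity by its base-2 logarithm and retags
#' the matrix as `log2`. This is the first preprocessing step for microarray
#' intensities, which are strictly positive and right-skewed on the linear
#' scale.
#'
#' @param m A linear-scale expression matrix.
#' @return The log2-scale expression matrix.
#' @examples
#' m <- expr_matrix(matrix(c(8, 1, 2, 4), 2, dimnames = list(c("A", "B"), NULL)))
#' expr_values(log2_transform(m))
#' @export
log2_transform <- function(m) {
  m <- as_expr_(m)
  if (expr_scale(m) != "linear") stop_("`m` is already on the log2 scale")
  v <- expr_values(m)
  if (any(v <= 0)) stop_("log2_transform requires strictly positive values")
  expr_matrix(log2(v), scale = "log2")
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample column to share one empirical distribution: within
#' each column the value of rank r is replaced by the mean, across columns,
#' of the rank-r order statistics; tied values receive the average of the
#' reference values at their tied ranks. Afterwards all column means are
#' equal and the within-column ranking is preserved.
#'
#' The heavy lifting is delegated to [limma::normalizeQuantiles()] (the
#' standard microarray implementation, `ties = TRUE`); the single-gene
#' degenerate case (every cell becomes the row mean) is handled directly.
#'
#' @param m An expression matrix (either scale; conventionally applied after
#'   [log2_transform()]).
#' @return The normalized expression matrix, same scale tag.
#' @export
quantile_normalize <- function(m) {
  m <- as_expr_(m)
  v <- expr_values(m)
  if (nrow(v) == 1L) {
    out <- matrix(mean(v), 1L, ncol(v), dimnames = dimnames(v))
  } else {
    out <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(out) <- dimnames(v)
  }
  expr_matrix(out, scale = expr_scale(m))
}

#' Restrict an expression matrix to selected genes and/or samples
#'
#' Rows and columns are restricted *and reordered* to the requested labels,
#' e.g. to pull the post-irradiation samples for the genes of a curated
#' network out of a full study matrix.
#'
#' @param m An expression matrix.
#' @param genes,samples Character vectors of labels to keep, in the desired
#'   order; `NULL` keeps all in current order. Unknown labels are an error.
#' @return The restricted expression matrix.
#' @export
extract_submatrix <- function(m, genes = NULL, samples = NULL) {
  m <- as_expr_(m)
  v <- expr_values(m)
  if (is.null(genes)) genes <- rownames(v)
  if (is.null(samples)) samples <- colnames(v)
  miss_g <- setdiff(genes, rownames(v))
  if (length(miss_g)) stop_("unknown gene label(s): ", paste(miss_g, collapse = ", "))
  miss_s <- setdiff(samples, colnames(v))
  if (length(miss_s)) stop_("unknown sample label(s): ", paste(miss_s, collapse = ", "))
  expr_matrix(v[genes, samples, drop = FALSE], scale = expr_scale(m))
}
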