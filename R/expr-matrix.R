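#' Expression matrices
#'
#' An expression matrix holds real-valued measurements for `p` genes (rows)
#' across `n` samples (columns), plus a scale tag saying whether the values
#' are raw linear intensities or log2-transformed. It is stored as a tibble
#' whose first column, `gene`, carries the gene labels and whose remaining
#' columns are one numeric column per sample, so it prints and pipes like any
#' other tidy table.
#'
#' Invariants enforced at construction: gene labels are unique and non-empty,
#' all measurement cells are finite numbers, and linear-scale values are
#' strictly positive (they are intensities).
#'
#' @param x A numeric matrix with genes as rows (rownames used as gene
#'   labels), or a data frame whose first column contains gene labels and
#'   whose remaining columns are numeric sample measurements.
#' @param scale Measurement scale, `"linear"` or `"log2"`.
#' @return A tibble of class `grn_expr` with a `gene` column and one column
#'   per sample; the scale is kept in the `"scale"` attribute (see
#'   [expr_scale()]).
#' @examples
#' m <- matrix(2^(1:6), nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
#' expr_matrix(m, scale = "linear")
#' @export
expr_matrix <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    genes <- rownames(x)
    if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(x)))
    samples <- colnames(x)
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(x)))
    values <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop_("expression data frame needs a gene column plus >= 1 sample column")
    genes <- as.character(x[[1L]])
    samples <- names(x)[-1L]
    values <- as.matrix(x[, -1L, drop = FALSE])
    if (!is.numeric(values)) stop_("all sample columns must be numeric")
  } else {
    stop_("`x` must be a numeric matrix or a data frame")
  }
  validate_expr_(genes, samples, values, scale)
  dimnames(values) <- NULL
  out <- tibble::tibble(gene = genes)
  for (k in seq_along(samples)) out[[samples[k]]] <- values[, k]
  new_expr_(out, scale)
}

new_expr_ <- function(df, scale) {
  out <- tibble::new_tibble(df, nrow = nrow(df), class = "grn_expr")
  attr(out, "scale") <- scale
  out
}

validate_expr_ <- function(genes, samples, values, scale) {
  if (length(genes) == 0L) stop_("expression matrix must contain at least one gene")
  if (anyNA(genes) || any(!nzchar(genes))) stop_("gene labels must be non-empty strings")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_("duplicate gene label(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(samples)) stop_("duplicate sample label(s)")
  if (!all(is.finite(values))) stop_("expression values must be finite (missing values are not supported)")
  if (scale == "linear" && any(values <= 0)) {
    stop_("linear-scale expression values must be strictly positive")
  }
  invisible(TRUE)
}

as_expr_ <- function(m, arg = "m") {
  if (!inherits(m, "grn_expr")) {
    stop_(sprintf("`%s` must be an expression matrix created with expr_matrix() or read_expression_matrix()", arg))
  }
  m
}

#' Accessors for expression matrices
#'
#' @param m An expression matrix (see [expr_matrix()]).
#' @return `expr_values()` the genes-by-samples numeric matrix (gene labels as
#'   rownames); `expr_genes()`/`expr_samples()` the label vectors;
#'   `expr_scale()` `"linear"` or `"log2"`.
#' @export
expr_values <- function(m) {
  m <- as_expr_(m)
  v <- as.matrix(as.data.frame(m[, -1L, drop = FALSE]))
  rownames(v) <- m$gene
  v
}

#' @rdname expr_values
#' @export
expr_genes <- function(m) as_expr_(m)$gene

#' @rdname expr_values
#' @export
expr_samples <- function(m) names(as_expr_(m))[-1L]

#' @rdname expr_values
#' @export
expr_scale <- function(m) attr(as_expr_(m), "scale")

#' Read / write expression matrices as TSV
#'
#' The file dialect is UTF-8 tab-separated text with a header row: the first
#' header cell is `gene`, the remaining cells are sample labels; each data row
#' is a gene label followed by one numeric value per sample ('.' decimal
#' separator, no quoting).
#'
#' @param path File path.
#' @param scale Scale tag to attach on read (the file itself is scale-less).
#' @return [read_expression_matrix()] an expression matrix;
#'   [write_expression_matrix()] the input, invisibly.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) stop_("expression TSV needs a gene column plus >= 1 sample column")
  genes <- raw[[1L]]
  samples <- names(raw)[-1L]
  values <- matrix(NA_real_, nrow(raw), length(samples))
  for (k in seq_along(samples)) {
    cell <- raw[[k + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop_(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                    cell[bad[1L]], genes[bad[1L]], samples[k], path))
    }
    values[, k] <- num
  }
  rownames(values) <- genes
  colnames(values) <- samples
  expr_matrix(values, scale = scale)
}

#' @rdname read_expression_matrix
#' @param m An expression matrix.
#' @export
write_expression_matrix <- function(m, path) {
  m <- as_expr_(m)
  df <- as.data.frame(m)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(m)
}

#' @export
print.grn_expr <- function(x, ...) {
  cat(sprintf("# Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x) - 1L, attr(x, "scale")))
  NextMethod()
}
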