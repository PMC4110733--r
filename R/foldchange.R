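#' Per-gene fold-changes between paired conditions
#'
#' For each gene, the fold-change is the ratio of its mean linear-scale
#' expression after treatment to its mean before treatment (ratio of group
#' means, the common microarray convention for a single value per gene from
#' grouped samples). A gene is classed `induced` when its fold-change is
#' `>= 1` (the boundary value 1 closes on the induced side, an arbitrary but
#' documented choice) and `repressed` otherwise.
#'
#' @param before,after Linear-scale expression matrices over the same genes;
#'   `after` is aligned to `before`'s gene order. Sample counts may differ.
#' @return A tibble of class `fold_change_summary` with columns `gene`,
#'   `fold_change` (positive linear ratio) and `direction`
#'   (`"induced"`/`"repressed"`).
#' @examples
#' st <- make_paired_study(c("A", "B"), fold_changes = c(2, 0.5),
#'                         n_samples = 4, noise_sd = 0, seed = 1)
#' compute_fold_changes(st$before, st$after)
#' @export
compute_fold_changes <- function(before, after) {
  before <- as_expr_(before, "before")
  after <- as_expr_(after, "after")
  if (expr_scale(before) != "linear" || expr_scale(after) != "linear") {
    stop_("fold-changes are defined on linear-scale matrices")
  }
  gb <- expr_genes(before)
  ga <- expr_genes(after)
  if (!setequal(gb, ga)) {
    stop_("`before` and `after` must cover the same genes (",
          length(setdiff(gb, ga)), " only in before, ",
          length(setdiff(ga, gb)), " only in after)")
  }
  mb <- rowMeans(expr_values(before))
  ma <- rowMeans(expr_values(after))[gb]
  if (any(mb == 0)) stop_("zero before-treatment mean; fold-change undefined")
  fc <- unname(ma / mb)
  out <- tibble::tibble(
    gene = gb,
    fold_change = fc,
    direction = ifelse(fc >= 1, "induced", "repressed")
  )
  class(out) <- c("fold_change_summary", class(out))
  out
}

#' Average fold-changes within the induced and repressed groups
#'
#' Reduces a per-gene fold-change table to the arithmetic mean linear
#' fold-change of the induced (`fold_change >= 1`) and repressed
#' (`fold_change < 1`) genes — the two headline numbers usually quoted for a
#' differential-expression gene list. A group with no genes yields `NA`.
#'
#' @param s A [compute_fold_changes()] result, or any data frame with a
#'   `fold_change` column (a `direction` column is recomputed from the
#'   values if absent).
#' @return A one-row tibble with `mean_induced`, `mean_repressed`,
#'   `n_induced`, `n_repressed`.
#' @examples
#' fc <- radiation_foldchanges()
#' summarize_fold_changes(fc[fc$dataset == "GSE1977", ])
#' @export
summarize_fold_changes <- function(s) {
  if (!is.data.frame(s) || is.null(s$fold_change)) {
    stop_("`s` must be a data frame with a `fold_change` column")
  }
  fc <- s$fold_change
  if (any(!is.finite(fc)) || any(fc <= 0)) stop_("fold-changes must be positive and finite")
  dir <- if (!is.null(s$direction)) s$direction else ifelse(fc >= 1, "induced", "repressed")
  ind <- fc[dir == "induced"]
  rep_ <- fc[dir == "repressed"]
  tibble::tibble(
    mean_induced = if (length(ind)) mean(ind) else NA_real_,
    mean_repressed = if (length(rep_)) mean(rep_) else NA_real_,
    n_induced = length(ind),
    n_repressed = length(rep_)
  )
}

#' Fold-changes of 21 radio-responsive genes from two public studies
#'
#' Published per-gene linear fold-changes and false-discovery rates for the
#' 21 genes found differentially expressed (FDR < 20%) in both of two public
#' irradiation microarray studies: GSE1977 (lymphoblastoid cell lines, 5 Gy)
#' and GSE23393 (patient blood, 1.25 Gy total body irradiation, 4 h). Sixteen
#' genes are induced and five repressed in both datasets. Used as a worked
#' input for [summarize_fold_changes()].
#'
#' @return A tibble with columns `gene`, `entrez`, `dataset`, `fold_change`,
#'   `fdr` (percent) and `direction`; 21 genes x 2 datasets = 42 rows.
#' @export
radiation_foldchanges <- function() {
  # gene, entrez, fc GSE1977, fdr GSE1977, fc GSE23393, fdr GSE23393
  rows <- list(
    list("ACTA2",     59L,    2.02,  0.00,  1.85,  0.00),
    list("ATF3",      467L,   3.05,  0.00,  1.40,  9.79),
    list("BAX",       581L,   1.53,  0.00,  1.80,  0.00),
    list("BBC3",      27113L, 4.00,  0.00,  1.48,  9.79),
    list("CCNG1",     900L,   1.72,  0.00,  1.51,  0.00),
    list("CD70",      970L,   2.07,  0.00,  4.85,  0.00),
    list("DDB2",      1643L,  2.38,  0.00,  5.33,  0.00),
    list("EI24",      9538L,  1.92,  0.00,  1.59,  3.20),
    list("FDXR",      2232L,  2.34,  0.00, 13.12,  0.00),
    list("GADD45A",   1647L,  4.50,  0.00,  2.34,  0.00),
    list("MMP9",      4318L,  2.94,  2.06,  1.85,  9.79),
    list("PCNA",      5111L,  2.04,  0.00,  3.54,  0.00),
    list("PLK2",      10769L, 11.54, 0.00,  3.63,  0.00),
    list("PLK3",      1263L,  1.47,  0.00,  1.54,  3.20),
    list("PPM1D",     8493L,  2.46,  0.00,  1.64,  0.00),
    list("TNFRSF10B", 8795L,  2.33,  0.00,  2.46,  0.00),
    list("BIRC5",     332L,   0.63, 16.09,  0.43,  3.52),
    list("CCNB1",     891L,   0.36,  0.00,  0.50,  0.00),
    list("HUS1",      3364L,  0.30, 16.09,  0.81, 16.52),
    list("MDC1",      9656L,  0.88, 16.68,  0.64,  3.52),
    list("MYC",       4609L,  0.50,  0.00,  0.65, 16.52)
  )
  gene <- vapply(rows, `[[`, "", 1L)
  entrez <- vapply(rows, `[[`, 1L, 2L)
  n <- length(gene)
  long <- tibble::tibble(
    gene = rep(gene, 2L),
    entrez = rep(entrez, 2L),
    dataset = rep(c("GSE1977", "GSE23393"), each = n),
    fold_change = c(vapply(rows, `[[`, 1, 3L), vapply(rows, `[[`, 1, 5L)),
    fdr = c(vapply(rows, `[[`, 1, 4L), vapply(rows, `[[`, 1, 6L))
  )
  long$direction <- ifelse(long$fold_change >= 1, "induced", "repressed")
  long
}
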