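#' Cell quality filtering
#'
#' Two criteria, both evaluated on the input matrix before any removal:
#' cells with fewer than \code{min_genes} detected genes (count > 0) are
#' removed, and cells whose log10 total UMI lies outside mean +/- \code{umi_sd}
#' standard deviations (denominator n-1) of all input cells' log10 totals are
#' removed. Boundaries are inclusive for keeping (exactly \code{min_genes}
#' detected genes is kept; exactly at mean +/- umi_sd * sd is kept). A removed
#' cell is attributed to its first failing criterion in the order
#' low_gene_cell, umi_outlier_cell.
#'
#' @param m a \code{CountMatrix}.
#' @param min_genes minimum detected genes per cell (default 500).
#' @param umi_sd width of the two-sided log10-UMI band (default 2).
#' @return list with \code{matrix} (filtered \code{CountMatrix}) and
#'   \code{report} (a \code{FilterReport} for the cell stage).
#' @export
filter_cells <- function(m, min_genes = 500, umi_sd = 2) {
  stopifnot(inherits(m, "CountMatrix"))
  v <- m$values
  detected <- Matrix::colSums(v > 0)
  totals <- Matrix::colSums(v)
  lt <- log10(totals)
  ok_tot <- is.finite(lt)
  mu <- mean(lt[ok_tot])
  sdev <- stats::sd(lt[ok_tot])
  if (!is.finite(sdev) || is.na(sdev)) sdev <- 0
  low_gene <- detected < min_genes
  umi_out <- !ok_tot | lt < mu - umi_sd * sdev | lt > mu + umi_sd * sdev
  removed_low <- low_gene
  removed_umi <- umi_out & !low_gene     # first failing criterion wins
  keep <- !(low_gene | umi_out)
  if (!any(keep)) stop("empty result: all cells removed by quality filters")
  report <- list(
    stage = "cells",
    cells_in = ncol(v), cells_out = sum(keep),
    removals = c(low_gene_cell = sum(removed_low),
                 umi_outlier_cell = sum(removed_umi)),
    removed_ids = list(low_gene_cell = m$cell_ids[removed_low],
                       umi_outlier_cell = m$cell_ids[removed_umi]),
    thresholds = c(min_genes = min_genes, umi_sd = umi_sd,
                   log10_umi_mean = mu, log10_umi_sd = sdev))
  class(report) <- "FilterReport"
  list(matrix = subset_counts(m, cells = which(keep)), report = report)
}

#' Gene quality filtering
#'
#' Removes mitochondrial genes (by annotation flag, falling back to a
#' case-insensitive "mt-" identifier prefix when no annotation is given) and
#' genes detected (count > 0) in fewer than \code{min_cells} of the current
#' cells — run this after \code{\link{filter_cells}} so prevalence is counted
#' on the final cell set. "At least \code{min_cells} cells" is inclusive.
#' A removed gene is attributed to low_cell_gene first, then mito_gene.
#'
#' @param m a \code{CountMatrix} (post cell filtering).
#' @param gene_annotation a GeneAnnotation data.frame covering all genes, or
#'   NULL to use the prefix fallback.
#' @param min_cells minimum number of cells a gene must be detected in
#'   (default 10).
#' @return list with \code{matrix} and \code{report} as in
#'   \code{\link{filter_cells}}.
#' @export
filter_genes <- function(m, gene_annotation = NULL, min_cells = 10) {
  stopifnot(inherits(m, "CountMatrix"))
  v <- m$values
  if (is.null(gene_annotation)) {
    is_mito <- grepl("^mt-", m$gene_ids, ignore.case = TRUE)
  } else {
    idx <- match(m$gene_ids, gene_annotation$gene_id)
    if (anyNA(idx))
      stop("gene annotation does not cover gene: ",
           m$gene_ids[which(is.na(idx))[1L]])
    is_mito <- gene_annotation$is_mitochondrial[idx]
  }
  prevalence <- Matrix::rowSums(v > 0)
  low_cell <- prevalence < min_cells
  removed_low <- low_cell
  removed_mito <- is_mito & !low_cell
  keep <- !(low_cell | is_mito)
  if (!any(keep)) stop("empty result: all genes removed by quality filters")
  report <- list(
    stage = "genes",
    genes_in = nrow(v), genes_out = sum(keep),
    removals = c(low_cell_gene = sum(removed_low),
                 mito_gene = sum(removed_mito)),
    removed_ids = list(low_cell_gene = m$gene_ids[removed_low],
                       mito_gene = m$gene_ids[removed_mito]),
    thresholds = c(min_cells = min_cells))
  class(report) <- "FilterReport"
  list(matrix = subset_counts(m, genes = which(keep)), report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport (", x$stage, "): ", sep = "")
  if (x$stage == "cells")
    cat(x$cells_in, "->", x$cells_out, "cells;")
  else cat(x$genes_in, "->", x$genes_out, "genes;")
  cat(" removals:", paste(names(x$removals), x$removals,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' TPM-like log normalization
#'
#' Per cell, each gene's UMI count is divided by the cell's total UMIs,
#' multiplied by the size factor (10,000), and natural-log transformed with a
#' pseudocount of 1: value = ln(1 + count/total * size_factor). Consequently
#' sum over genes of (exp(value) - 1) equals the size factor for every cell.
#'
#' @param m a \code{CountMatrix} with every cell total > 0.
#' @param size_factor scale of the count fraction (default 10000).
#' @return a \code{\link{normalized_matrix}}.
#' @export
normalize_counts <- function(m, size_factor = 10000) {
  stopifnot(inherits(m, "CountMatrix"))
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0))
    stop("cell with zero total UMIs (",
         m$cell_ids[which(totals == 0)[1L]],
         "); run filter_cells first")
  v <- dense_values(m)
  nv <- log1p(sweep(v, 2L, totals, "/") * size_factor)
  normalized_matrix(nv, m$gene_ids, m$cell_ids, size_factor = size_factor)
}

#' Relative log expression diagnostic on housekeeping genes
#'
#' For each housekeeping gene and cell, RLE = log2(expression / median of
#' that gene's expression over all cells), computed on the TPM-like pre-log
#' scale (exp(value) - 1). Housekeeping genes whose across-cell median is
#' zero are excluded with a warning; zero-expression entries (RLE -Inf) are
#' dropped from the pooled summaries and counted. Samples with no technical
#' batch structure have per-sample median RLE near 0.
#'
#' @param nm a \code{NormalizedMatrix}.
#' @param housekeeping character vector of housekeeping gene ids.
#' @param grouping named character vector or factor mapping each cell id to
#'   a sample label; default puts all cells in one sample.
#' @return data.frame with one row per sample: median and IQR of pooled RLE
#'   values, number of values pooled, number of zero entries dropped.
#' @export
rle_diagnostic <- function(nm, housekeeping, grouping = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  hk <- intersect(housekeeping, nm$gene_ids)
  if (length(hk) == 0L) stop("no housekeeping genes present in the matrix")
  if (length(hk) < 2L) stop("need >= 2 detected housekeeping genes")
  if (is.null(grouping))
    grouping <- stats::setNames(rep("all", length(nm$cell_ids)), nm$cell_ids)
  grouping <- grouping[nm$cell_ids]
  expr <- expm1(nm$values[hk, , drop = FALSE])
  med <- apply(expr, 1L, stats::median)
  zero_med <- med == 0
  if (any(zero_med)) {
    warning("excluding ", sum(zero_med),
            " housekeeping gene(s) with zero median expression")
    expr <- expr[!zero_med, , drop = FALSE]
    med <- med[!zero_med]
  }
  if (nrow(expr) == 0L) stop("all housekeeping genes have zero median")
  rle <- log2(expr / med)
  out <- lapply(split(seq_along(grouping), grouping), function(ci) {
    vals <- rle[, ci, drop = FALSE]
    finite <- vals[is.finite(vals)]
    data.frame(median_rle = stats::median(finite),
               iqr_rle = stats::IQR(finite),
               n_values = length(finite),
               n_zero_dropped = sum(!is.finite(vals)))
  })
  res <- do.call(rbind, out)
  res <- cbind(sample = names(out), res)
  rownames(res) <- NULL
  res
}

#' One-pass preprocessing: cell filter, gene filter, normalization
#'
#' @param m a \code{CountMatrix}.
#' @param gene_annotation optional GeneAnnotation (mito flags).
#' @param min_genes,umi_sd,min_cells,size_factor thresholds as in the
#'   individual steps.
#' @return list with \code{normalized}, \code{counts} (filtered),
#'   \code{cell_report}, \code{gene_report}.
#' @export
preprocess <- function(m, gene_annotation = NULL, min_genes = 500,
                       umi_sd = 2, min_cells = 10, size_factor = 10000) {
  fc <- filter_cells(m, min_genes = min_genes, umi_sd = umi_sd)
  fg <- filter_genes(fc$matrix, gene_annotation = gene_annotation,
                     min_cells = min_cells)
  nm <- normalize_counts(fg$matrix, size_factor = size_factor)
  list(normalized = nm, counts = fg$matrix,
       cell_report = fc$report, gene_report = fg$report)
}
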