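#' Cell-cell Pearson correlation matrix
#'
#' Correlation of every pair of cells across genes. Cells with zero variance
#' across genes are excluded (Pearson undefined) and reported rather than
#' propagated as NaN.
#'
#' @param nm a \code{NormalizedMatrix} with >= 2 cells and >= 2 genes.
#' @return list with \code{R} (symmetric matrix, unit diagonal, over the
#'   retained cells) and \code{excluded} (ids of zero-variance cells).
#' @export
cell_cell_correlation <- function(nm) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  v <- nm$values
  if (nrow(v) < 2L) stop("need >= 2 genes")
  vars <- matrixStats_colVars(v)
  excluded <- nm$cell_ids[vars == 0]
  keep <- vars > 0
  if (sum(keep) < 2L) stop("fewer than 2 usable cells (zero variance)")
  R <- stats::cor(v[, keep, drop = FALSE])
  list(R = R, excluded = excluded)
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlation of every pair of genes across cells; zero-variance genes are
#' excluded and reported.
#'
#' @param nm a \code{NormalizedMatrix} with >= 2 cells and >= 2 genes.
#' @return list with \code{R} and \code{excluded} (zero-variance gene ids).
#' @export
gene_gene_correlation <- function(nm) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  v <- nm$values
  if (ncol(v) < 2L) stop("need >= 2 cells")
  vars <- matrixStats_colVars(t(v))
  excluded <- nm$gene_ids[vars == 0]
  keep <- vars > 0
  if (sum(keep) < 2L) stop("fewer than 2 usable genes (zero variance)")
  R <- stats::cor(t(v[keep, , drop = FALSE]))
  list(R = R, excluded = excluded)
}

# column variances without extra dependencies
matrixStats_colVars <- function(v) {
  n <- nrow(v)
  if (n < 2L) return(rep(0, ncol(v)))
  mu <- colMeans(v)
  (colSums(v * v) - n * mu * mu) / (n - 1)
}

# mean over unordered distinct pairs of f(R); diagonal never included
offdiag_mean <- function(R, absolute = TRUE) {
  n <- nrow(R)
  if (n < 2L) return(NA_real_)
  tot <- if (absolute) sum(abs(R)) else sum(R)
  (tot - n) / (n * (n - 1))   # diagonal entries are exactly 1
}

#' Transition index I_C across a time course
#'
#' For each time point, the numerator is the mean over unordered distinct
#' gene pairs of |Pearson correlation| and the denominator the mean over
#' unordered distinct cell pairs of the Pearson correlation — by default its
#' absolute value (the Methods-text convention); \code{signed_cell_corr =
#' TRUE} uses signed cell-cell correlations instead. I_C(t) is their ratio.
#' The gene universe is identical across time points: the supplied
#' \code{gene_set} or the intersection of genes present, restricted to genes
#' with nonzero variance at every time point (exclusions are counted, never
#' silently NaN'd). Zero-variance cells are dropped per time point.
#'
#' @param nm_by_time named list of \code{NormalizedMatrix}, one per time
#'   point, in time order (>= 3 time points).
#' @param gene_set optional gene id subset.
#' @param signed_cell_corr use the signed cell-cell mean in the denominator.
#' @return a \code{TransitionSeries} data.frame with columns time_point,
#'   n_cells, n_genes, mean_cell_cell, mean_abs_gene_gene, ic,
#'   excluded_zero_variance_cells, ic_defined; attributes \code{gene_set},
#'   \code{argmax_ic}, \code{signed_cell_corr}, \code{excluded_genes}.
#' @export
transition_index <- function(nm_by_time, gene_set = NULL,
                             signed_cell_corr = FALSE) {
  if (length(nm_by_time) < 3L) stop("need >= 3 time points")
  if (is.null(names(nm_by_time)))
    names(nm_by_time) <- sprintf("t%d", seq_along(nm_by_time) - 1L)
  common <- Reduce(intersect, lapply(nm_by_time, function(x) x$gene_ids))
  if (!is.null(gene_set)) {
    miss <- setdiff(gene_set, common)
    if (length(miss))
      stop("gene_set member absent from some time point: ", miss[1L])
    common <- intersect(common, gene_set)
  }
  # genes must have nonzero variance at every time point to stay comparable
  usable <- Reduce(`&`, lapply(nm_by_time, function(x) {
    v <- x$values[common, , drop = FALSE]
    matrixStats_colVars(t(v)) > 0
  }))
  excluded_genes <- common[!usable]
  common <- common[usable]
  if (length(common) < 2L) stop("fewer than 2 genes usable at all time points")

  rows <- lapply(seq_along(nm_by_time), function(i) {
    nm <- subset_normalized(nm_by_time[[i]], genes = common)
    cc <- cell_cell_correlation(nm)
    gg <- gene_gene_correlation(nm)
    den <- offdiag_mean(cc$R, absolute = !signed_cell_corr)
    num <- offdiag_mean(abs(gg$R), absolute = TRUE)
    ic_defined <- is.finite(den) && den > 0
    data.frame(time_point = names(nm_by_time)[i],
               n_cells = nrow(cc$R), n_genes = nrow(gg$R),
               mean_cell_cell = den, mean_abs_gene_gene = num,
               ic = if (ic_defined) num / den else NA_real_,
               excluded_zero_variance_cells = length(cc$excluded),
               ic_defined = ic_defined,
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, rows)
  class(series) <- c("TransitionSeries", "data.frame")
  attr(series, "gene_set") <- common
  attr(series, "excluded_genes") <- excluded_genes
  attr(series, "signed_cell_corr") <- signed_cell_corr
  ok <- which(series$ic_defined)
  attr(series, "argmax_ic") <-
    if (length(ok)) series$time_point[ok[which.max(series$ic[ok])]] else NA
  if (any(!series$ic_defined))
    warning("ic undefined (non-positive cell-cell mean) at: ",
            paste(series$time_point[!series$ic_defined], collapse = ", "))
  series
}

#' Trend summary of a transition series
#'
#' Reports the positions of the cell-cell correlation minimum, the gene-gene
#' correlation maximum and the I_C maximum, plus the sign pattern of
#' successive differences for each statistic. A constant series is flagged
#' "flat" with no extremum.
#'
#' @param series a \code{TransitionSeries}.
#' @return list with per-statistic argmin/argmax (time-point labels, NA when
#'   flat) and sign patterns ("+", "-", "0" per step).
#' @export
correlation_trend_summary <- function(series) {
  stopifnot(inherits(series, "TransitionSeries"))
  tp <- series$time_point
  one <- function(x, find = c("min", "max")) {
    find <- match.arg(find)
    d <- diff(x)
    pattern <- ifelse(d > 0, "+", ifelse(d < 0, "-", "0"))
    if (all(d == 0))
      return(list(extremum = NA_character_, flat = TRUE, pattern = pattern))
    pos <- if (find == "min") which.min(x) else which.max(x)
    list(extremum = tp[pos], flat = FALSE, pattern = pattern)
  }
  list(cell_cell = one(series$mean_cell_cell, "min"),
       gene_gene = one(series$mean_abs_gene_gene, "max"),
       ic = one(series$ic, "max"))
}

#' Split a normalized matrix by time point
#'
#' @param nm a \code{NormalizedMatrix}.
#' @param cells a CellAnnotation covering all cells of \code{nm}.
#' @return named list of \code{NormalizedMatrix}, one per time-point level
#'   present, in level order.
#' @export
split_by_time <- function(nm, cells) {
  ann <- check_annotated(nm, cells)
  lv <- levels(ann$time_point)
  lv <- lv[lv %in% as.character(ann$time_point)]
  out <- lapply(lv, function(t)
    subset_normalized(nm, cells = which(as.character(ann$time_point) == t)))
  names(out) <- lv
  out
}
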