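#' Construct a CountMatrix
#'
#' The shared container for UMI counts: genes as rows, cells as columns.
#' Storage is sparse (\code{dgCMatrix}) when density < 50%, dense otherwise;
#' the two are value-identical for every downstream operation.
#'
#' @param values non-negative integer matrix (base or \pkg{Matrix} sparse),
#'   genes x cells.
#' @param gene_ids,cell_ids ordered unique identifier vectors matching the
#'   matrix dimensions. Defaults to the dimnames of \code{values}.
#' @return an object of class \code{CountMatrix} with fields \code{values},
#'   \code{gene_ids}, \code{cell_ids}.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or supply dimnames)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("row count (", nrow(values), ") != |gene_ids| (", length(gene_ids), ")")
  if (length(cell_ids) != ncol(values))
    stop("column count (", ncol(values), ") != |cell_ids| (", length(cell_ids), ")")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])
  dup <- cell_ids[duplicated(cell_ids)]
  if (length(dup)) stop("duplicate cell id: ", dup[1L])
  v <- check_counts(values)
  dimnames(v) <- list(gene_ids, cell_ids)
  structure(list(values = v, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "CountMatrix")
}

# validate non-negative integral entries; pick sparse/dense storage
check_counts <- function(values) {
  x <- if (methods::is(values, "sparseMatrix")) values@x else as.numeric(values)
  if (length(x)) {
    bad <- which(x < 0 | x != round(x) | !is.finite(x))
    if (length(bad))
      stop("negative or non-integer entry: value ", x[bad[1L]])
  }
  nnz <- if (methods::is(values, "sparseMatrix")) Matrix::nnzero(values) else
    sum(values != 0)
  dens <- nnz / max(1, prod(dim(values)))
  if (dens < 0.5) {
    methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  } else {
    v <- as.matrix(values)
    storage.mode(v) <- "double"   # value-identical to the sparse branch
    v
  }
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$values), "genes x", ncol(x$values), "cells;",
      if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense",
      "storage\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Subset a CountMatrix by gene and/or cell identifiers or indices
#'
#' @param m a \code{CountMatrix}.
#' @param genes,cells identifier vectors or integer/logical indices; NULL
#'   keeps the axis untouched.
#' @return a \code{CountMatrix}.
#' @export
subset_counts <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  gi <- resolve_idx(genes, m$gene_ids, "gene")
  ci <- resolve_idx(cells, m$cell_ids, "cell")
  count_matrix(m$values[gi, ci, drop = FALSE],
               m$gene_ids[gi], m$cell_ids[ci])
}

resolve_idx <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop("unknown ", what, " id: ", sel[which(is.na(idx))[1L]])
    return(idx)
  }
  if (is.logical(sel)) return(which(sel))
  as.integer(sel)
}

#' Construct a NormalizedMatrix
#'
#' Natural-log TPM-like expression with the same genes-x-cells shape contract
#' as \code{\link{count_matrix}}. Values are ln(1 + count/total * size_factor);
#' the constructor records the size factor and pseudocount convention but does
#' not re-derive values (see \code{\link{normalize_counts}}).
#'
#' @param values non-negative real matrix, genes x cells.
#' @param gene_ids,cell_ids identifiers as in \code{count_matrix}.
#' @param size_factor scale of the per-cell count fraction (default 10000).
#' @param pseudocount_convention string flag recording the zero-handling
#'   convention; only \code{"log1p"} is produced by this package.
#' @return an object of class \code{NormalizedMatrix}.
#' @export
normalized_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              size_factor = 10000,
                              pseudocount_convention = "log1p") {
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene id")
  if (anyDuplicated(cell_ids)) stop("duplicate cell id")
  if (any(values < 0)) stop("normalized values must be >= 0")
  v <- as.matrix(values)
  dimnames(v) <- list(gene_ids, cell_ids)
  structure(list(values = v, gene_ids = gene_ids, cell_ids = cell_ids,
                 size_factor = size_factor,
                 pseudocount_convention = pseudocount_convention),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "cells; size factor", x$size_factor,
      paste0("(", x$pseudocount_convention, ")\n"))
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' Subset a NormalizedMatrix
#' @inheritParams subset_counts
#' @param nm a \code{NormalizedMatrix}.
#' @export
subset_normalized <- function(nm, genes = NULL, cells = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  gi <- resolve_idx(genes, nm$gene_ids, "gene")
  ci <- resolve_idx(cells, nm$cell_ids, "cell")
  normalized_matrix(nm$values[gi, ci, drop = FALSE],
                    nm$gene_ids[gi], nm$cell_ids[ci],
                    size_factor = nm$size_factor,
                    pseudocount_convention = nm$pseudocount_convention)
}

# dense numeric view, used by correlation / testing code
dense_values <- function(m) {
  v <- m$values
  if (methods::is(v, "sparseMatrix")) v <- as.matrix(v)
  v
}

#' Check that every cell of a matrix is annotated
#'
#' Pipeline stages refuse matrices with unannotated cells: the join between
#' matrix and annotation must be total.
#'
#' @param m a \code{CountMatrix} or \code{NormalizedMatrix}.
#' @param ann a cell-annotation data.frame (see \code{\link{read_cell_annotation}}).
#' @return invisibly, \code{ann} reordered to the matrix's cells.
#' @export
check_annotated <- function(m, ann) {
  idx <- match(m$cell_ids, ann$cell_id)
  if (anyNA(idx))
    stop("unannotated cell: ", m$cell_ids[which(is.na(idx))[1L]])
  invisible(ann[idx, , drop = FALSE])
}
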